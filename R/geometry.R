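## Geodesic sphere construction and ray/mesh intersection.
##
## The sampling geometry is a Class-I geodesic subdivision of a vertex-up
## icosahedron: each of the 20 faces is divided into f^2 triangles
## (f = frequency) on the flat face and the lattice is projected radially to
## the unit sphere.  The full sphere has 10 f^2 + 2 vertices; with the
## icosahedron vertex-up and f even, 5 f of them land exactly on the equator,
## so the closed upper hemisphere carries 5 f^2 + 5 f / 2 + 1 directions
## (751 at f = 12).

# Vertex-up icosahedron with the mid-sagittal plane x = 0 as a mirror plane.
# Ring longitudes are chosen so the vertex set is symmetric under x -> -x;
# cospi/sinpi keep mirror pairs exactly negated in the x component.
icosahedron_vertex_up <- function() {
  c1 <- 1 / sqrt(5)    # |z| of the two pentagonal rings
  r1 <- 2 / sqrt(5)    # ring radius
  up_lon <- c(0.5, 0.9, 1.3, 1.7, 0.1)       # units of pi
  lo_lon <- up_lon + 0.2
  v <- rbind(
    c(0, 0, 1),
    cbind(r1 * cospi(up_lon), r1 * sinpi(up_lon), rep(c1, 5)),
    cbind(r1 * cospi(lo_lon), r1 * sinpi(lo_lon), rep(-c1, 5)),
    c(0, 0, -1)
  )
  # indices: 1 = north pole, 2:6 upper ring, 7:11 lower ring, 12 = south pole
  U <- 2:6; L <- 7:11; nxt <- c(2:5, 1)
  f <- rbind(
    cbind(1L, U, U[nxt]),                 # top cap
    cbind(U, L, U[nxt]),                  # upper middle band
    cbind(L, L[nxt], U[nxt]),             # lower middle band
    cbind(12L, L[nxt], L)                 # bottom cap
  )
  list(vertices = v, faces = f)
}

#' Geodesic sphere mesh
#'
#' Builds a Class-I geodesic subdivision of the icosahedron at the given
#' frequency, with all vertices projected to the unit sphere.  The result has
#' `10 * frequency^2 + 2` vertices and `20 * frequency^2` faces.  Shared edge
#' and corner lattice points are deduplicated combinatorially (no coordinate
#' tolerance), so the mesh is watertight by construction.
#'
#' @param frequency Positive integer subdivision frequency (1 returns the
#'   icosahedron itself).
#' @param radius Sphere radius applied to the unit vertices (default 1).
#' @return A `triangle_mesh`: list with `vertices` (n x 3 numeric matrix) and
#'   `faces` (m x 3 integer matrix, 1-based, outward-wound).
#' @examples
#' m <- icosphere_mesh(4)
#' nrow(m$vertices)  # 162
#' @export
icosphere_mesh <- function(frequency, radius = 1) {
  f <- as.integer(frequency)
  if (length(f) != 1L || is.na(f) || f < 1L) stop("frequency must be a positive integer")
  ico <- icosahedron_vertex_up()
  V <- ico$vertices
  nv <- 12L
  # grow-able vertex store; key -> index hash for shared lattice points
  coords <- vector("list", 12L + 30L * (f - 1L) + 20L * ((f - 1L) * (f - 2L)) %/% 2L)
  for (i in 1:12) coords[[i]] <- V[i, ]
  h <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in 1:12) assign(paste0("v", i), i, envir = h)
  n_used <- 12L

  point_index <- function(face_id, corners, i, j, k) {
    # barycentric lattice point (i, j, k)/f on face `corners`; canonical key so
    # shared corners/edges resolve to a single vertex id
    if (i == f) return(corners[1]); if (j == f) return(corners[2]); if (k == f) return(corners[3])
    if (k == 0L || j == 0L || i == 0L) {
      if (k == 0L) { a <- corners[1]; b <- corners[2]; t <- j }
      else if (j == 0L) { a <- corners[1]; b <- corners[3]; t <- k }
      else { a <- corners[2]; b <- corners[3]; t <- k }
      if (a > b) { tmp <- a; a <- b; b <- tmp; t <- f - t }
      key <- paste0("e", a, "_", b, "_", t)
      idx <- h[[key]]
      if (!is.null(idx)) return(idx)
      p <- ((f - t) * V[a, ] + t * V[b, ]) / f
    } else {
      key <- paste0("f", face_id, "_", i, "_", j)
      idx <- h[[key]]
      if (!is.null(idx)) return(idx)
      p <- (i * V[corners[1], ] + j * V[corners[2], ] + k * V[corners[3], ]) / f
    }
    n_used <<- n_used + 1L
    coords[[n_used]] <<- p
    assign(key, n_used, envir = h)
    n_used
  }

  faces_out <- matrix(0L, nrow = 20L * f * f, ncol = 3L)
  nf <- 0L
  for (fc in seq_len(nrow(ico$faces))) {
    corners <- ico$faces[fc, ]
    # index the whole lattice of this face: idx[[a]][b] with a = weight on
    # corner 2, b = weight on corner 3 (0-based)
    idx <- matrix(NA_integer_, nrow = f + 1L, ncol = f + 1L)
    for (a in 0:f) for (b in 0:(f - a)) {
      idx[a + 1L, b + 1L] <- point_index(fc, corners, f - a - b, a, b)
    }
    for (a in 0:(f - 1L)) for (b in 0:(f - 1L - a)) {
      nf <- nf + 1L
      faces_out[nf, ] <- c(idx[a + 1L, b + 1L], idx[a + 2L, b + 1L], idx[a + 1L, b + 2L])
      if (a + b <= f - 2L) {
        nf <- nf + 1L
        faces_out[nf, ] <- c(idx[a + 2L, b + 1L], idx[a + 2L, b + 2L], idx[a + 1L, b + 2L])
      }
    }
  }
  vm <- do.call(rbind, coords[seq_len(n_used)])
  vm <- vm / sqrt(rowSums(vm^2))
  triangle_mesh(vm * radius, faces_out[seq_len(nf), , drop = FALSE])
}

#' Construct a triangle mesh
#'
#' Light-weight container for a triangulated surface: vertex coordinates in
#' millimetres and 1-based face indices.  Meshes in the head coordinate frame
#' have the sella turcica at the origin, +z superior, +y anterior, and x = 0
#' as the mid-sagittal plane.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) == 0L) stop("mesh has no vertices")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Signed volume of a closed triangle mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed, outward-wound surface.
#'
#' @param mesh A `triangle_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Hemisphere of sampling directions
#'
#' Builds the set of unit ray directions used for raycast sampling of the
#' head surface: the closed upper hemisphere (z >= 0, equatorial ring
#' included) of a Class-I geodesic sphere at the given frequency, together
#' with the mid-sagittal mirror permutation.  The frequency must be even so
#' that a ring of vertices lies exactly on the equator; at the default
#' frequency 12 the hemisphere has 751 directions.
#'
#' Directions are returned in a canonical deterministic order (z descending,
#' then azimuth in \[0, 2*pi)), so the direction list — and therefore any
#' descriptor or trained model built on it — is stable across runs.
#'
#' @param frequency Even positive integer (default 12).
#' @param n_expected Optional expected direction count; an error is raised if
#'   the construction yields a different number.
#' @return An object of class `sampling_sphere` with elements `directions`
#'   (n x 3 unit vectors), `mirror_perm` (integer permutation such that
#'   `directions[mirror_perm[i], ]` is `directions[i, ]` with x negated),
#'   `n`, `frequency`, and `neighbors` (adjacency list on the hemisphere,
#'   used by the `fill` miss policy).
#' @examples
#' sph <- build_hemisphere(12)
#' sph$n  # 751
#' @export
build_hemisphere <- function(frequency = 12, n_expected = NULL) {
  f <- as.integer(frequency)
  if (length(f) != 1L || is.na(f) || f < 2L || f %% 2L != 0L)
    stop("no equatorial ring: frequency must be an even integer >= 2")
  sphere <- icosphere_mesh(f)
  keep <- which(sphere$vertices[, 3] >= -1e-9)
  dirs <- sphere$vertices[keep, , drop = FALSE]
  az <- atan2(dirs[, 2], dirs[, 1])
  az <- ifelse(az < 0, az + 2 * pi, az)
  ord <- order(-dirs[, 3], az)
  dirs <- dirs[ord, , drop = FALSE]
  n <- nrow(dirs)
  if (!is.null(n_expected) && n != as.integer(n_expected))
    stop("hemisphere has ", n, " directions but n_expected = ", n_expected)
  # adjacency among kept vertices, from the sphere triangulation
  old2new <- integer(nrow(sphere$vertices))
  old2new[keep[ord]] <- seq_len(n)
  nb <- vector("list", n)
  fc <- sphere$faces
  for (e in list(fc[, 1:2], fc[, 2:3], fc[, c(3, 1)])) {
    a <- old2new[e[, 1]]; b <- old2new[e[, 2]]
    ok <- a > 0L & b > 0L
    for (i in which(ok)) {
      nb[[a[i]]] <- c(nb[[a[i]]], b[i])
      nb[[b[i]]] <- c(nb[[b[i]]], a[i])
    }
  }
  nb <- lapply(nb, function(x) sort(unique(x)))
  structure(list(directions = dirs,
                 mirror_perm = compute_mirror_permutation(dirs),
                 n = n, frequency = f, neighbors = nb),
            class = "sampling_sphere")
}

#' @export
print.sampling_sphere <- function(x, ...) {
  cat("sampling_sphere:", x$n, "unit directions (geodesic frequency",
      paste0(x$frequency, ");"),
      sum(x$mirror_perm == seq_len(x$n)), "on the mid-sagittal plane\n")
  invisible(x)
}

#' Mid-sagittal mirror permutation of a direction set
#'
#' For a direction set symmetric under x -> -x, returns the permutation
#' `perm` with `directions[perm[i], ] == (-x_i, y_i, z_i)`.  Directions lying
#' on the mirror plane (|x| < tol) map to themselves.  The permutation is an
#' involution; applying it to a ray-length vector realizes mirroring of the
#' head across the mid-sagittal plane without re-casting any rays.
#'
#' @param directions n x 3 matrix of unit direction vectors.
#' @param tol Matching tolerance (default 1e-6).
#' @return Integer permutation vector of length n.
#' @export
compute_mirror_permutation <- function(directions, tol = 1e-6) {
  d <- as.matrix(directions)
  n <- nrow(d)
  perm <- integer(n)
  # order-based matching: sort both the set and its reflection
  key <- function(m) order(round(m[, 3] / tol), round(m[, 2] / tol), round(m[, 1] / tol))
  refl <- d; refl[, 1] <- -refl[, 1]
  o1 <- key(d); o2 <- key(refl)
  perm[o2] <- o1
  err <- sqrt(rowSums((refl - d[perm, , drop = FALSE])^2))
  if (any(err > tol)) {
    bad <- which(err > tol)
    stop("direction(s) without a mirror partner within tolerance: index ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(perm[perm] != seq_len(n))) stop("mirror pairing is not an involution")
  perm
}

#' Ray/mesh intersection distance
#'
#' Casts a ray from `origin` along `direction` and returns the distance to the
#' farthest triangle intersection (the outer surface of the head), or `NA` if
#' the ray misses the mesh.  Intersections closer than 1e-9 mm are ignored and
#' degenerate (zero-area) triangles are skipped.
#'
#' @param mesh A `triangle_mesh`.
#' @param origin Numeric 3-vector, ray origin (mm).
#' @param direction Unit-norm numeric 3-vector.
#' @return Distance in mm, or `NA_real_` on a miss.
#' @export
ray_mesh_intersect <- function(mesh, origin, direction) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) stop("direction must be unit norm")
  r <- cpp_raycast(mesh$vertices, mesh$faces - 1L, as.numeric(origin),
                   matrix(direction, nrow = 1))
  t <- r$t[1]
  if (is.nan(t) || t < 0) NA_real_ else t
}

## Batch raycast: lengths (and deduplicated crossing counts) for every
## direction of a sampling sphere.  Used by sample_mesh and the watertightness
## parity check.
raycast_all <- function(mesh, directions, origin = c(0, 0, 0)) {
  r <- cpp_raycast(mesh$vertices, mesh$faces - 1L, as.numeric(origin),
                   as.matrix(directions))
  r$t[r$t < 0] <- NA_real_
  list(lengths = r$t, hits = r$hits)
}

#' Export a sampling sphere as an ASCII PLY point cloud
#'
#' Writes the direction vertices (no faces) for inspection in external mesh
#' viewers.
#'
#' @param sphere A `sampling_sphere`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_sphere <- function(sphere, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", sphere$n),
               "property double x", "property double y", "property double z",
               "element face 0",
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(sphere$directions, 1, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  invisible(path)
}
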