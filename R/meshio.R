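## Triangle-mesh readers and writers: PLY (ascii + binary little-endian),
## Wavefront OBJ (v/f records), STL (ascii + binary).  Coordinates are always
## interpreted as millimetres; none of these formats carries reliable unit
## metadata, so none is trusted.

#' Read a triangle mesh
#'
#' Reads PLY (ascii or binary little-endian), Wavefront OBJ, or STL (ascii or
#' binary), dispatching on the file extension.  Quad faces are triangulated by
#' fan split.  STL files, which store three independent vertices per facet,
#' have duplicate vertices merged within 1e-9 mm.
#'
#' @param path Path to a `.ply`, `.obj` or `.stl` file.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stop("unsupported mesh extension '", ext, "' (supported: ply, obj, stl)")
  )
  if (nrow(m$vertices) == 0L) stop("empty mesh in ", path)
  m
}

#' Write a triangle mesh
#'
#' @param mesh A [triangle_mesh()] with at least one face.
#' @param path Output file path.
#' @param format One of `"ply"`, `"obj"`, `"stl"`; defaults to the file
#'   extension.
#' @param binary Write the binary variant where the format has one (PLY
#'   binary little-endian, binary STL).  OBJ is always text.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = tolower(tools::file_ext(path)),
                       binary = FALSE) {
  if (!inherits(mesh, "triangle_mesh")) mesh <- triangle_mesh(mesh$vertices, mesh$faces)
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  switch(format,
    ply = write_ply(mesh, path, binary),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path, binary),
    stop("unsupported mesh format '", format, "' (supported: ply, obj, stl)")
  )
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in ", path)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000L) stop("PLY header not terminated in ", path)
  }
  if (!identical(trimws(header[1]), "ply")) stop("not a PLY file (bad magic) in ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY missing format line in ", path)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  elements <- list()  # name -> list(count, props = data.frame(type, name))
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props <- c(elements[[cur]]$props, list(tok[-1]))
    }
  }
  if (is.null(elements$vertex)) stop("PLY has no vertex element in ", path)
  nv <- elements$vertex$count
  nf <- if (!is.null(elements$face)) elements$face$count else 0L

  ply_rsize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar <- function(type, n = 1L) {
    sz <- ply_rsize[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4L && grepl("^u", type)))
  }

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nv + nf) stop("truncated PLY body in ", path)
    vprops <- vapply(elements$vertex$props, function(p) p[2], "")
    vm <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      vals <- as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]])
      vm[i, ] <- vals[match(c("x", "y", "z"), vprops)]
    }
    fm <- matrix(integer(0), 0, 3)
    if (nf > 0L) {
      fl <- vector("list", nf)
      for (i in seq_len(nf)) {
        vals <- as.integer(strsplit(trimws(txt[nv + i]), "\\s+")[[1]])
        idx <- vals[seq_len(vals[1]) + 1L] + 1L
        fl[[i]] <- fan_triangulate(idx)
      }
      fm <- do.call(rbind, fl)
    }
  } else if (fmt == "binary_little_endian") {
    vprops <- elements$vertex$props
    vm <- matrix(NA_real_, nv, 3)
    pnames <- vapply(vprops, function(p) p[length(p)], "")
    for (i in seq_len(nv)) {
      row <- numeric(length(vprops))
      for (j in seq_along(vprops)) row[j] <- read_scalar(vprops[[j]][1])
      vm[i, ] <- row[match(c("x", "y", "z"), pnames)]
    }
    fm <- matrix(integer(0), 0, 3)
    if (nf > 0L) {
      fp <- elements$face$props[[1]]  # ("list", count_type, index_type, name)
      fl <- vector("list", nf)
      for (i in seq_len(nf)) {
        k <- read_scalar(fp[2])
        idx <- read_scalar(fp[3], n = k) + 1L
        fl[[i]] <- fan_triangulate(idx)
      }
      fm <- do.call(rbind, fl)
    }
  } else {
    stop("unsupported PLY format '", fmt, "' in ", path,
         " (ascii and binary_little_endian supported)")
  }
  if (anyNA(vm)) stop("PLY vertex records missing x/y/z in ", path)
  triangle_mesh(vm, fm)
}

fan_triangulate <- function(idx) {
  if (length(idx) < 3L) stop("face with fewer than 3 vertices")
  cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
}

## ---- OBJ ----

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vtx <- txt[startsWith(txt, "v ")]
  fct <- txt[startsWith(txt, "f ")]
  if (!length(vtx)) stop("OBJ has no vertices in ", path)
  vm <- t(vapply(strsplit(trimws(vtx), "\\s+"),
                 function(tok) as.numeric(tok[2:4]), numeric(3)))
  fl <- lapply(strsplit(trimws(fct), "\\s+"), function(tok) {
    idx <- as.integer(vapply(strsplit(tok[-1], "/", fixed = TRUE), `[`, "", 1L))
    if (any(idx < 0)) idx <- nrow(vm) + idx + 1L  # negative = relative indexing
    fan_triangulate(idx)
  })
  fm <- if (length(fl)) do.call(rbind, fl) else matrix(integer(0), 0, 3)
  triangle_mesh(vm, fm)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(v)
    paste("v", paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "))), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

## ---- STL ----

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50 bytes/facet.  A file
  # starting with "solid" may still be binary; check the size arithmetic.
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    nf <- readBin(con, "integer", size = 4L, endian = "little")
    if (!is.na(nf) && nf >= 0 && sz == 84 + 50 * as.numeric(nf)) is_binary <- TRUE
  }
  if (is_binary) {
    on.exit(close(con))
    tri <- matrix(NA_real_, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)  # attribute byte count
      tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    }
    close(con); on.exit()
    stl_assemble(tri, path)
  } else {
    close(con)
    txt <- readLines(path, warn = FALSE)
    if (!grepl("^\\s*solid", txt[1]))
      stop("not an STL file (no 'solid' keyword, bad binary size) in ", path)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl)) stop("ASCII STL with no vertex records in ", path)
    tri <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(tok) as.numeric(tok[2:4]), numeric(3)))
    if (nrow(tri) %% 3L != 0L) stop("ASCII STL vertex count not a multiple of 3 in ", path)
    stl_assemble(tri, path)
  }
}

# merge per-facet vertices within 1e-9 mm and build the index mesh
stl_assemble <- function(tri, path) {
  if (anyNA(tri)) stop("malformed STL facet records in ", path)
  key <- paste(round(tri[, 1] / 1e-9), round(tri[, 2] / 1e-9), round(tri[, 3] / 1e-9))
  first <- !duplicated(key)
  ids <- match(key, key[first])
  vm <- tri[first, , drop = FALSE]
  fm <- matrix(ids, ncol = 3L, byrow = TRUE)
  triangle_mesh(vm, fm)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.17g %.17g %.17g", a[i, 1], a[i, 2], a[i, 3]),
                   sprintf("      vertex %.17g %.17g %.17g", b[i, 1], b[i, 2], b[i, 3]),
                   sprintf("      vertex %.17g %.17g %.17g", c_[i, 1], c_[i, 2], c_[i, 3]),
                   "    endloop",
                   "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
}
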