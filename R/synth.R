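## Synthetic cranial surface generator.
##
## Heads are modelled as a superellipsoid (exponent 2.5 — flatter-sided than
## an ellipsoid, closer to an infant calvarium) sampled on a geodesic sphere
## lattice, with each diagnostic class expressed as a smooth radial
## deformation field of adjustable severity, smooth Gaussian surface bumps as
## noise, and a per-subject global scale emulating the head-size spread of
## 3-6-month-old infants.  Meshes are closed and watertight by construction
## and are positioned in the head frame (sella origin inside, +z superior,
## +y anterior, x = 0 mid-sagittal).

#' Parameters for one synthetic head
#'
#' @param class_label One of `"healthy"`, `"scaphocephaly"`,
#'   `"trigonocephaly"`, `"plagiocephaly"`.
#' @param severity Deformation severity, >= 0; 0 reproduces the healthy shape.
#' @param scale_mm Head half-width in mm (default drawn uniformly in 55-75 by
#'   [generate_cohort()]).
#' @param noise_amp_mm Amplitude of the smooth surface bumps (default 1 mm).
#' @param seed Integer seed for the bump field.
#' @param frequency Geodesic base resolution (default 16: 2562 vertices).
#' @param deform Named list of deformation magnitudes at severity 1:
#'   `scapho_y` (anteroposterior elongation, default 0.25), `scapho_x`
#'   (narrowing, 0.15), `trigono` (frontal wedge compression, 0.35),
#'   `plagio` (unilateral frontal flattening depth, 0.35).
#' @return A list of class `subtype_params`.
#' @export
subtype_params <- function(class_label, severity = 0, scale_mm = 65,
                           noise_amp_mm = 1, seed = 1L, frequency = 16L,
                           deform = list()) {
  class_label <- match.arg(class_label, CRANIO_CLASSES)
  if (severity < 0) stop("severity must be >= 0")
  if (scale_mm <= 0) stop("scale_mm must be > 0")
  d <- utils::modifyList(list(scapho_y = 0.25, scapho_x = 0.15,
                              trigono = 0.35, plagio = 0.35), deform)
  structure(list(class_label = class_label, severity = severity,
                 scale_mm = scale_mm, noise_amp_mm = noise_amp_mm,
                 seed = as.integer(seed), frequency = as.integer(frequency),
                 deform = d),
            class = "subtype_params")
}

# smooth 0->1 ramp: 0 for x <= 0, 1 for x >= w, cosine-tapered between
cos_ramp <- function(x, w) {
  y <- pmin(pmax(x / w, 0), 1)
  0.5 * (1 - cos(pi * y))
}

#' Generate one synthetic head mesh
#'
#' @param params A [subtype_params()] (or arguments forwarded to it).
#' @param ... Passed to [subtype_params()] when `params` is a class label.
#' @return A [triangle_mesh()] in the head frame, millimetre units.
#' @examples
#' m <- generate_head(subtype_params("scaphocephaly", severity = 1, seed = 7))
#' @export
generate_head <- function(params, ...) {
  if (is.character(params)) params <- subtype_params(params, ...)
  stopifnot(inherits(params, "subtype_params"))
  base <- icosphere_mesh(params$frequency)
  u <- base$vertices                      # unit directions
  s <- params$severity

  # superellipsoid radius along each unit direction: relative semi-axes
  # (width, length, height) = (1, 1.25, 1.15), exponent 2.5
  p <- 2.5
  ax <- c(1, 1.25, 1.15)
  r0 <- (abs(u[, 1] / ax[1])^p + abs(u[, 2] / ax[2])^p +
           abs(u[, 3] / ax[3])^p)^(-1 / p)
  v <- u * r0

  # class deformation of the clean base shape
  if (s > 0) {
    d <- params$deform
    if (params$class_label == "scaphocephaly") {
      v[, 2] <- v[, 2] * (1 + d$scapho_y * s)
      v[, 1] <- v[, 1] * (1 - d$scapho_x * s)
    } else if (params$class_label == "trigonocephaly") {
      y_max <- max(v[, 2])
      z_max <- max(v[, 3])
      w <- cos_ramp(v[, 2] / y_max, 0.35) * cos_ramp(v[, 3] / z_max, 0.25)
      v[, 1] <- v[, 1] * (1 - d$trigono * s * w * (v[, 2] / y_max))
    } else if (params$class_label == "plagiocephaly") {
      r <- sqrt(rowSums(v^2))
      wx <- cos_ramp(v[, 1] / max(v[, 1]), 0.3)
      wy <- cos_ramp(v[, 2] / max(v[, 2]), 0.3)
      wz <- cos_ramp(v[, 3] / max(v[, 3]), 0.3)
      v <- v * (1 - d$plagio * s * wx * wy * wz)
    }
  }

  # smooth surface bumps: 20 Gaussian bumps on the sphere, radial displacement,
  # in relative units (amplitude converted from mm via scale_mm)
  bump <- with_seed(params$seed, {
    nb <- 20L
    centers <- matrix(rnorm(3 * nb), nb, 3)
    centers <- centers / sqrt(rowSums(centers^2))
    signs <- sample(c(-1, 1), nb, replace = TRUE)
    widths <- runif(nb, 0.25, 0.45)         # angular sigma, radians
    list(centers = centers, signs = signs, widths = widths)
  })
  ang <- acos(pmin(pmax(u %*% t(bump$centers), -1), 1))      # n x 20
  disp <- as.vector(exp(-(ang^2) %*% diag(1 / (2 * bump$widths^2))) %*% bump$signs)
  v <- v * (1 + (params$noise_amp_mm / params$scale_mm) * disp)

  v <- v * params$scale_mm
  # place the sella origin inside, below centre (skull base): shift up by 15%
  v[, 3] <- v[, 3] + 0.15 * params$scale_mm
  triangle_mesh(v, base$faces)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the study cohort: 53 healthy, 76 scaphocephaly, 40
#' trigonocephaly and 27 anterior plagiocephaly subjects; patient severities
#' drawn uniformly from \[0.5, 1\], healthy severity 0; head half-widths
#' uniform in 55-75 mm.
#'
#' @param counts Named integer vector of per-class subject counts in the
#'   fixed class order.
#' @param severity_range Length-2 numeric, uniform severity range for patient
#'   classes.
#' @param scale_range_mm Length-2 numeric, uniform head half-width range (mm).
#' @param noise_amp_mm Surface bump amplitude (mm).
#' @param seed Master seed; per-subject seeds are `seed * 10000 + index`.
#' @param frequency Geodesic base resolution of each mesh.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(counts = c(healthy = 53, scaphocephaly = 76,
                                   trigonocephaly = 40, plagiocephaly = 27),
                        severity_range = c(0.5, 1),
                        scale_range_mm = c(55, 75),
                        noise_amp_mm = 1, seed = 1L, frequency = 16L) {
  if (is.null(names(counts))) names(counts) <- CRANIO_CLASSES
  counts <- counts[CRANIO_CLASSES]
  counts[is.na(counts)] <- 0L
  names(counts) <- CRANIO_CLASSES
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(counts = as.integer(counts), severity_range = severity_range,
                 scale_range_mm = scale_range_mm, noise_amp_mm = noise_amp_mm,
                 seed = as.integer(seed), frequency = as.integer(frequency)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Deterministic given the master seed: subject `i` uses seed
#' `seed * 10000 + i`, so individual heads can be regenerated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @param meshes If `FALSE`, return only the manifest (severities, scales,
#'   seeds) without building the meshes.
#' @return A list with `meshes` (list of `triangle_mesh`, or `NULL`) and
#'   `manifest` (data.frame: subject_id, class, severity, scale_mm, seed).
#' @export
generate_cohort <- function(spec = cohort_spec(), meshes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$counts)
  cls <- rep(CRANIO_CLASSES, times = spec$counts)
  draws <- with_seed(spec$seed, {
    sev <- runif(n, spec$severity_range[1], spec$severity_range[2])
    scl <- runif(n, spec$scale_range_mm[1], spec$scale_range_mm[2])
    list(sev = sev, scl = scl)
  })
  sev <- ifelse(cls == "healthy", 0, draws$sev)
  manifest <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    class = cls,
    severity = sev,
    scale_mm = draws$scl,
    seed = spec$seed * 10000 + seq_len(n),
    stringsAsFactors = FALSE
  )
  mesh_list <- NULL
  if (meshes) {
    mesh_list <- lapply(seq_len(n), function(i) {
      generate_head(subtype_params(cls[i], severity = sev[i],
                                   scale_mm = draws$scl[i],
                                   noise_amp_mm = spec$noise_amp_mm,
                                   seed = manifest$seed[i],
                                   frequency = spec$frequency))
    })
    names(mesh_list) <- manifest$subject_id
  }
  list(meshes = mesh_list, manifest = manifest)
}
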