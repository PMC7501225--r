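## Ray-cast shape descriptors: sampling a mesh into per-direction ray
## lengths, mid-sagittal mirroring as an index permutation, and per-ray
## z-score standardization.

#' Sample a head mesh into a ray-length descriptor
#'
#' Casts one ray per sampling-sphere direction from `origin` (the sella
#' turcica in the head frame) and records the distance to the outer surface.
#'
#' @param mesh A [triangle_mesh()] in the head frame.
#' @param sphere A [build_hemisphere()] sampling sphere.
#' @param origin Ray origin, default the frame origin `c(0, 0, 0)`.
#' @param subject_id,class_label Carried into the returned sample.
#' @param miss Policy for rays that do not hit the mesh: `"error"` (default;
#'   aborts naming the ray index), `"fill"` (average over the sphere-adjacent
#'   rays' lengths, iterated until all holes are filled), or `"na"`.
#' @return An object of class `shape_sample`: list with `subject_id`,
#'   `class_label`, `lengths` (numeric, length `sphere$n`, mm) and `mirrored`
#'   (FALSE).
#' @export
sample_mesh <- function(mesh, sphere, origin = c(0, 0, 0),
                        subject_id = "subject", class_label = NA_character_,
                        miss = c("error", "fill", "na")) {
  miss <- match.arg(miss)
  stopifnot(inherits(sphere, "sampling_sphere"))
  lengths <- raycast_all(mesh, sphere$directions, origin)$lengths
  if (anyNA(lengths)) {
    bad <- which(is.na(lengths))
    if (miss == "error") {
      stop("ray(s) missed the mesh at index ", paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
    } else if (miss == "fill") {
      for (iter in 1:100) {
        if (!anyNA(lengths)) break
        bad <- which(is.na(lengths))
        fill <- vapply(bad, function(i) {
          nb <- lengths[sphere$neighbors[[i]]]
          nb <- nb[!is.na(nb)]
          if (length(nb)) mean(nb) else NA_real_
        }, numeric(1))
        if (all(is.na(fill))) stop("cannot fill ray misses: no hit neighbors")
        lengths[bad] <- fill
      }
      if (anyNA(lengths)) stop("cannot fill ray misses within iteration limit")
    }
  }
  shape_sample(subject_id, class_label, lengths, mirrored = FALSE)
}

#' @rdname sample_mesh
#' @param lengths Numeric vector of ray lengths (mm).
#' @param mirrored Logical flag: is this the mirrored orientation?
#' @export
shape_sample <- function(subject_id, class_label, lengths, mirrored = FALSE) {
  lengths <- as.numeric(lengths)
  if (any(!is.na(lengths) & lengths <= 0)) stop("ray lengths must be positive")
  structure(list(subject_id = as.character(subject_id),
                 class_label = class_label,
                 lengths = lengths, mirrored = isTRUE(mirrored)),
            class = "shape_sample")
}

#' @export
print.shape_sample <- function(x, ...) {
  cat(sprintf("shape_sample '%s' (%s%s): %d rays, %.1f-%.1f mm\n",
              x$subject_id, x$class_label %||% "?",
              if (x$mirrored) ", mirrored" else "",
              length(x$lengths), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Mirror a sample across the mid-sagittal plane
#'
#' Mirroring a head across x = 0 permutes ray indices rather than changing
#' any length, so the mirrored descriptor is `lengths[mirror_perm]`.  The
#' subject id and class label are preserved (the pair stays linked), and the
#' `mirrored` flag is toggled; mirroring twice restores the original exactly.
#'
#' @param s A `shape_sample`.
#' @param sphere The `sampling_sphere` the sample was cast with.
#' @return The mirrored `shape_sample`.
#' @export
mirror_sample <- function(s, sphere) {
  stopifnot(inherits(s, "shape_sample"), inherits(sphere, "sampling_sphere"))
  if (length(s$lengths) != sphere$n)
    stop("sample has ", length(s$lengths), " rays but sphere has ", sphere$n)
  shape_sample(s$subject_id, s$class_label, s$lengths[sphere$mirror_perm],
               mirrored = !s$mirrored)
}

samples_to_matrix <- function(samples) {
  if (is.matrix(samples)) return(samples)
  if (inherits(samples, "shape_sample")) samples <- list(samples)
  if (is.numeric(samples)) return(matrix(samples, nrow = 1))
  do.call(rbind, lapply(samples, function(s)
    if (inherits(s, "shape_sample")) s$lengths else as.numeric(s)))
}

#' Fit a per-ray standardization scaler
#'
#' Computes the per-ray mean and population (divide-by-N) standard deviation
#' over the given samples.  Which samples form the population is the
#' caller's choice: the cross-validation driver fits on the training fold
#' only by default (see [crossvalidate()]), with an option to reproduce
#' all-subject scaling.
#'
#' @param samples A list of `shape_sample`s, or a numeric matrix with one row
#'   per sample.
#' @return An object of class `scaler_stats` with `mean` and `sd` vectors.
#'   Standard deviations below 1e-12 are clamped to 1e-12 with a warning.
#' @export
fit_scaler <- function(samples) {
  x <- samples_to_matrix(samples)
  if (is.null(x) || nrow(x) < 2L) stop("need at least 2 samples to fit a scaler")
  mu <- colMeans(x)
  sdev <- sqrt(pmax(colMeans(sweep(x, 2, mu, "-")^2), 0))
  if (any(sdev < 1e-12)) {
    warning(sum(sdev < 1e-12), " ray(s) with (near-)zero variance; sd clamped to 1e-12")
    sdev <- pmax(sdev, 1e-12)
  }
  structure(list(mean = mu, sd = sdev), class = "scaler_stats")
}

#' Apply (or invert) a fitted scaler
#'
#' `apply_scaler` maps lengths to z-scores `(x - mean) / sd` per ray;
#' `invert_scaler` maps z-scores back to millimetres.
#'
#' @param x A `shape_sample`, numeric vector, or matrix (rows = samples).
#' @param stats A `scaler_stats` from [fit_scaler()].
#' @return Numeric vector or matrix of standardized features (or lengths for
#'   the inverse).
#' @export
apply_scaler <- function(x, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  m <- samples_to_matrix(if (is.matrix(x)) x else list(x))
  if (is.matrix(x)) m <- x
  if (ncol(m) != length(stats$mean))
    stop("feature size ", ncol(m), " does not match scaler size ", length(stats$mean))
  out <- sweep(sweep(m, 2, stats$mean, "-"), 2, stats$sd, "/")
  if (!is.matrix(x) && nrow(out) == 1L) drop(out) else out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(x, stats) {
  stopifnot(inherits(stats, "scaler_stats"))
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (ncol(m) != length(stats$mean))
    stop("feature size ", ncol(m), " does not match scaler size ", length(stats$mean))
  out <- sweep(sweep(m, 2, stats$sd, "*"), 2, stats$mean, "+")
  if (!is.matrix(x)) drop(out) else out
}

#' Build the descriptor table for a cohort
#'
#' Samples every mesh of a cohort and appends the mirrored counterpart of
#' each subject, yielding the feature table used for training: one original
#' and one mirrored row per subject, linked by `subject_id`.
#'
#' @param cohort Result of [generate_cohort()] (needs `meshes` + `manifest`),
#'   or a list of meshes plus a `manifest` data.frame.
#' @param sphere A [build_hemisphere()] sphere.
#' @param miss Miss policy, see [sample_mesh()].
#' @param mirror Include mirrored rows (default TRUE).
#' @return A list with `lengths` (matrix, one row per sample), `subject_id`,
#'   `class_label`, `mirrored` (vectors aligned with rows).
#' @export
cohort_features <- function(cohort, sphere, miss = "error", mirror = TRUE) {
  manifest <- cohort$manifest
  meshes <- cohort$meshes
  stopifnot(!is.null(meshes), nrow(manifest) == length(meshes))
  orig <- lapply(seq_along(meshes), function(i)
    sample_mesh(meshes[[i]], sphere,
                subject_id = manifest$subject_id[i],
                class_label = manifest$class[i], miss = miss))
  samples <- orig
  if (mirror) samples <- c(samples, lapply(orig, mirror_sample, sphere = sphere))
  list(lengths = samples_to_matrix(samples),
       subject_id = vapply(samples, `[[`, "", "subject_id"),
       class_label = vapply(samples, `[[`, "", "class_label"),
       mirrored = vapply(samples, `[[`, TRUE, "mirrored"))
}

#' Write / read a feature table as CSV
#'
#' Columns: subject_id, class, mirrored, then one column per ray (`ray0001`,
#' ...).
#'
#' @param features Result of [cohort_features()].
#' @param path CSV file path.
#' @return `write_features`: invisibly `path`; `read_features`: a feature
#'   list as from [cohort_features()].
#' @export
write_features <- function(features, path) {
  m <- as.data.frame(features$lengths)
  names(m) <- sprintf("ray%04d", seq_len(ncol(m)))
  df <- cbind(data.frame(subject_id = features$subject_id,
                         class = features$class_label,
                         mirrored = features$mirrored,
                         stringsAsFactors = FALSE), m)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ray_cols <- grep("^ray[0-9]+$", names(df))
  list(lengths = as.matrix(df[, ray_cols]),
       subject_id = df$subject_id,
       class_label = df$class,
       mirrored = as.logical(df$mirrored))
}

#' Save / load scaler statistics as JSON
#'
#' @param stats A `scaler_stats` from [fit_scaler()].
#' @param path JSON file path.
#' @return `write_scaler`: invisibly `path`; `read_scaler`: a `scaler_stats`.
#' @export
write_scaler <- function(stats, path) {
  stopifnot(inherits(stats, "scaler_stats"))
  jsonlite::write_json(list(mean = unname(stats$mean), sd = unname(stats$sd)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean), sd = as.numeric(obj$sd)),
            class = "scaler_stats")
}
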