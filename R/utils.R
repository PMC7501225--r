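#' @keywords internal
#' @useDynLib craniorays, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict rnorm runif sd
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

## Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
## caller's .Random.seed afterwards.  All stochastic code in the package goes
## through this so that user-level RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## The fixed class-label order used throughout: descriptor columns, one-hot
## encodings, softmax outputs and confusion matrices all follow it.
CRANIO_CLASSES <- c("healthy", "scaphocephaly", "trigonocephaly", "plagiocephaly")

#' Diagnostic class labels in their fixed order
#'
#' All multi-class structures in the package (one-hot label matrices, softmax
#' outputs, confusion matrices) use the same fixed class order:
#' healthy, scaphocephaly, trigonocephaly, plagiocephaly.
#'
#' @return Character vector of the four class labels.
#' @export
cranio_classes <- function() CRANIO_CLASSES

as_cranio_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), CRANIO_CLASSES)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(CRANIO_CLASSES, collapse = ", "))
  factor(x, levels = CRANIO_CLASSES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
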