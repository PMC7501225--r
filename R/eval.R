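## Linked stratified k-fold cross-validation and confusion-matrix metrics.
##
## Folds are assigned at the subject level, stratified on class, so a
## subject's original and mirrored descriptors can never straddle the
## train/test split ("linked" cross-validation).

#' Stratified subject-level fold assignment
#'
#' Assigns each subject to one of `k` folds, stratified on class label:
#' within every class the per-fold counts differ by at most one.
#' Deterministic given `seed`.  Because assignment is per subject, any
#' derived samples (the mirrored copies) inherit the subject's fold.
#'
#' @param labels Class label per subject (character or factor); names or
#'   `subject_ids` give the subject ids.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param subject_ids Optional subject ids (default `names(labels)` or
#'   1-based indices).
#' @return An integer vector of fold indices in `1..k`, named by subject id,
#'   of class `fold_assignment`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L, subject_ids = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  ids <- subject_ids %||% names(labels) %||% as.character(seq_len(n))
  folds <- integer(n)
  with_seed(seed, {
    # rotate the fold sequence between classes so small classes do not all
    # pile their remainder subjects into fold 1
    offset <- 0L
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      seq_f <- ((seq_along(members) - 1L + offset) %% k) + 1L
      folds[members] <- seq_f
      offset <- (offset + length(members)) %% k
    }
  })
  names(folds) <- ids
  structure(folds, k = k, seed = seed, class = "fold_assignment")
}

#' Confusion matrix from true and predicted labels
#'
#' Rows are true classes, columns predicted, both in the fixed class order.
#'
#' @param truth,pred Label vectors over [cranio_classes()].
#' @param classes Class order.
#' @return A k x k integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, classes = cranio_classes()) {
  t_ <- factor(as.character(truth), levels = classes)
  p_ <- factor(as.character(pred), levels = classes)
  m <- table(truth = t_, predicted = p_)
  structure(unclass(m), class = "confusion_matrix")
}

#' One-vs-rest metrics of a confusion matrix
#'
#' For each class: recall/sensitivity TP/(TP+FN), precision TP/(TP+FP) and
#' specificity TN/(TN+FP); plus overall accuracy trace/total.  A metric with
#' a zero denominator is reported as `NaN` (undefined), never as 0.
#'
#' @param m A square count matrix (rows = true, columns = predicted).
#' @return A list of class `confusion_metrics` with `per_class` (data.frame:
#'   class, recall, precision, specificity) and `accuracy` (proportion).
#' @examples
#' m <- diag(c(53, 76, 40, 26))
#' m[4, 1] <- 1   # one plagiocephaly subject predicted healthy
#' confusion_metrics(m)
#' @export
confusion_metrics <- function(m) {
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("negative counts")
  total <- sum(m)
  if (total == 0) stop("all-zero confusion matrix")
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b == 0, NaN, a / b)
  per_class <- data.frame(class = classes,
                          recall = safe_div(tp, tp + fn),
                          precision = safe_div(tp, tp + fp),
                          specificity = safe_div(tn, tn + fp),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_class = per_class, accuracy = sum(tp) / total,
                 n = total), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("overall accuracy: %.*f%% (%d/%d)\n", digits,
              100 * x$accuracy, round(x$accuracy * x$n), x$n))
  df <- x$per_class
  for (col in c("recall", "precision", "specificity"))
    df[[col]] <- sprintf("%.*f%%", digits, 100 * df[[col]])
  print(df, row.names = FALSE)
  invisible(x)
}

## inner stratified split of the training subjects for early stopping:
## returns logical vector (TRUE = validation) per subject, linked
inner_val_split <- function(labels, frac = 0.1, seed = 1L) {
  n <- length(labels)
  val <- logical(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      n_val <- max(1L, round(frac * length(members)))
      if (n_val >= length(members)) n_val <- length(members) - 1L
      if (n_val >= 1L) val[sample(members, n_val)] <- TRUE
    }
  })
  val
}

#' Linked stratified k-fold cross-validation of the classifier
#'
#' For each fold: a per-ray scaler is fitted (by default on the training-fold
#' samples only — original plus mirrored — and applied unchanged to the test
#' fold), the network is trained with early stopping on an inner stratified
#' 10% validation split of the training subjects, and the held-out fold is
#' predicted.  Every subject contributes exactly one entry to the aggregated
#' confusion matrix: by default the prediction of its original-orientation
#' descriptor (`eval_mode = "original"`); `"mirror-average"` instead takes the
#' argmax of the averaged softmax of the original and mirrored descriptors.
#'
#' `scaling = "all"` reproduces the historical preprocessing in which the
#' per-ray statistics are computed over all subjects before splitting
#' (leaking test statistics into training); `validation = "test-fold"` additionally
#' uses the held-out fold itself as the early-stopping validation set.  Both
#' are provided for replication; neither is the default.
#'
#' @param features Feature list from [cohort_features()] (original + mirrored
#'   rows), or compatible list with `lengths`, `subject_id`, `class_label`,
#'   `mirrored`.
#' @param config A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and inner splits; fold `i` trains
#'   with `config$seed + i`.
#' @param scaling `"fold"` (default) or `"all"`.
#' @param eval_mode `"original"` (default) or `"mirror-average"`.
#' @param validation `"inner"` (default: stratified 10% split of the training
#'   subjects) or `"test-fold"`: use the held-out fold as validation set for
#'   stopping (replication mode).
#' @param verbose Report per-fold progress.
#' @return An object of class `cranio_cv`: `confusion` (aggregated
#'   `confusion_matrix`), `per_fold` (list of per-fold matrices), `metrics`
#'   ([confusion_metrics()]), `predictions` (data.frame per subject: truth,
#'   fold, pred_original, pred_mirrored, pred), `folds`, `histories`, and the
#'   options used.
#' @export
crossvalidate <- function(features, config = classifier_config(), k = 10L,
                          seed = 1L, scaling = c("fold", "all"),
                          eval_mode = c("original", "mirror-average"),
                          validation = c("inner", "test-fold"), verbose = FALSE) {
  scaling <- match.arg(scaling)
  eval_mode <- match.arg(eval_mode)
  validation <- match.arg(validation)
  X <- features$lengths
  sid <- features$subject_id
  cls <- features$class_label
  mirrored <- features$mirrored
  subjects <- unique(sid)
  sub_class <- cls[match(subjects, sid)]
  if (!all(table(sid) == 2L))
    stop("features must contain exactly one original and one mirrored sample per subject")
  folds <- stratified_folds(sub_class, k = k, seed = seed, subject_ids = subjects)
  row_fold <- folds[match(sid, subjects)]

  scaler_all <- if (scaling == "all") fit_scaler(X) else NULL
  per_fold <- vector("list", k)
  histories <- vector("list", k)
  pred_orig <- pred_mirr <- character(length(subjects))
  prob_sum <- matrix(0, length(subjects), config$n_classes,
                     dimnames = list(subjects, cranio_classes()))

  for (f in seq_len(k)) {
    test_rows <- which(row_fold == f)
    train_rows <- which(row_fold != f)
    scaler <- scaler_all %||% fit_scaler(X[train_rows, , drop = FALSE])
    Xs_train <- apply_scaler(X[train_rows, , drop = FALSE], scaler)
    Xs_test <- apply_scaler(X[test_rows, , drop = FALSE], scaler)
    cfg <- config
    cfg$seed <- config$seed + f
    if (validation == "test-fold") {
      tr_x <- Xs_train; tr_y <- cls[train_rows]
      va_x <- Xs_test; va_y <- cls[test_rows]
    } else {
      tr_subj <- unique(sid[train_rows])
      val_subj <- tr_subj[inner_val_split(sub_class[match(tr_subj, subjects)],
                                          frac = 0.1, seed = seed + f)]
      is_val <- sid[train_rows] %in% val_subj
      tr_x <- Xs_train[!is_val, , drop = FALSE]; tr_y <- cls[train_rows][!is_val]
      va_x <- Xs_train[is_val, , drop = FALSE]; va_y <- cls[train_rows][is_val]
    }
    fit <- cranionet(tr_x, tr_y, va_x, va_y, cfg)
    histories[[f]] <- fit$history
    probs <- predict(fit, Xs_test, type = "prob")
    pred <- predict(fit, Xs_test, type = "class")
    ti <- match(sid[test_rows], subjects)
    orig_sel <- !mirrored[test_rows]
    pred_orig[ti[orig_sel]] <- as.character(pred[orig_sel])
    pred_mirr[ti[!orig_sel]] <- as.character(pred[!orig_sel])
    for (j in seq_along(test_rows)) prob_sum[ti[j], ] <- prob_sum[ti[j], ] + probs[j, ]
    if (verbose)
      message(sprintf("fold %2d/%d: %d train / %d test rows, stopped at epoch %d",
                      f, k, nrow(tr_x), length(test_rows), fit$stopped_epoch))
  }

  pred_final <- if (eval_mode == "original") pred_orig else
    cranio_classes()[apply(prob_sum, 1, which.max)]
  conf <- confusion_matrix(sub_class, pred_final)
  for (f in seq_len(k)) {
    in_f <- folds == f
    per_fold[[f]] <- confusion_matrix(sub_class[in_f], pred_final[in_f])
  }
  structure(list(confusion = conf, per_fold = per_fold,
                 metrics = confusion_metrics(conf),
                 predictions = data.frame(subject_id = subjects,
                                          truth = sub_class,
                                          fold = as.integer(folds),
                                          pred_original = pred_orig,
                                          pred_mirrored = pred_mirr,
                                          pred = as.character(pred_final),
                                          stringsAsFactors = FALSE),
                 folds = folds, histories = histories,
                 k = k, seed = seed, scaling = scaling,
                 eval_mode = eval_mode, validation = validation,
                 config = config),
            class = "cranio_cv")
}

#' @export
print.cranio_cv <- function(x, ...) {
  cat(sprintf("linked stratified %d-fold cross-validation (%d subjects%s%s)\n",
              x$k, nrow(x$predictions),
              if (x$scaling == "all") "; ALL-SUBJECT SCALING (replication mode)" else "",
              if (x$validation == "test-fold") "; TEST-FOLD VALIDATION (replication mode)" else ""))
  print(unclass(x$confusion))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.cranio_cv <- function(object, ...) {
  print(object)
  cat("\nper-fold accuracies:\n")
  acc <- vapply(object$per_fold, function(m) sum(diag(m)) / sum(m), numeric(1))
  print(round(acc, 3))
  invisible(object)
}
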