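#' Classifier configuration
#'
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost regularization constant C.
#' @param convention metric convention reported in the `sensitivity` /
#'   `specificity` slots: `"standard"` (true-positive / true-negative rates)
#'   or `"predictive_value"` (positive / negative predictive values).
#' @param positive_class label treated as positive (default `"MD"`).
#' @param balance_classes weight each class inversely to its training-fold
#'   frequency (default TRUE). Leave-one-out folds are inherently imbalanced
#'   (the held-out subject's class is one short), which otherwise biases
#'   chance-level accuracy below 50%.
#' @return list of classifier settings.
#' @export
classifier_config <- function(kernel = c("linear", "radial"), cost = 1,
                              convention = c("standard", "predictive_value"),
                              positive_class = "MD", balance_classes = TRUE) {
  list(kernel = match.arg(kernel), cost = cost,
       convention = match.arg(convention), positive_class = positive_class,
       balance_classes = balance_classes)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is always `100 * (tp + tn) / total`. Under the `"standard"`
#' convention sensitivity is `100 * tp / (tp + fn)` and specificity
#' `100 * tn / (tn + fp)`; under `"predictive_value"` the two slots carry the
#' positive predictive value `100 * tp / (tp + fp)` and negative predictive
#' value `100 * tn / (tn + fn)` instead. Zero denominators yield `NA` with
#' `undefined = TRUE`.
#'
#' @param tp,fn,fp,tn confusion counts (positive class = MD).
#' @param convention `"standard"` or `"predictive_value"`.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   `convention`, `undefined`.
#' @export
compute_metrics <- function(tp, fn, fp, tn,
                            convention = c("standard", "predictive_value")) {
  convention <- match.arg(convention)
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  total <- tp + fn + fp + tn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- switch(convention,
                 standard = rate(tp, tp + fn),
                 predictive_value = rate(tp, tp + fp))
  spec <- switch(convention,
                 standard = rate(tn, tn + fp),
                 predictive_value = rate(tn, tn + fn))
  list(accuracy = 100 * (tp + tn) / total,
       sensitivity = sens, specificity = spec,
       convention = convention,
       undefined = is.na(sens) || is.na(spec))
}

validate_table <- function(table, subset) {
  if (is.null(table$label)) stop("table must have a 'label' column", call. = FALSE)
  missing_cols <- setdiff(subset, colnames(table))
  if (length(missing_cols))
    stop("validation error: unknown feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, subset, drop = FALSE])
  if (any(!is.finite(X))) stop("missing values in selected features", call. = FALSE)
  X
}

#' Leave-one-out cross-validated SVM evaluation of a feature subset
#'
#' For each of the `n` subjects an SVM is trained on the remaining `n - 1`
#' (features z-scored with training-fold statistics only; zero-variance
#' features map to 0) and the held-out subject is predicted. Metrics are
#' aggregated over all folds. Training folds that collapse to a single class
#' are flagged and skipped with a warning.
#'
#' @param table labeled feature table: data.frame with `label` plus numeric
#'   feature columns (>= 2 subjects per class).
#' @param subset character vector of feature columns to use.
#' @param config a [classifier_config()].
#' @return An `eval_result`: list with `accuracy`, `sensitivity`,
#'   `specificity` (under `config$convention`), `metrics_standard`,
#'   `metrics_predictive`, `confusion` (tp, fn, fp, tn), `predictions`,
#'   `subset`, `config`, `n_folds`, `skipped_folds`.
#' @export
loocv_evaluate <- function(table, subset, config = classifier_config()) {
  X <- validate_table(table, subset)
  y <- as.character(table$label)
  n <- nrow(X)
  if (n < 4L) stop("need n >= 4 subjects", call. = FALSE)
  pos <- config$positive_class
  if (!pos %in% y) pos <- sort(unique(y))[1]
  lev <- c(pos, setdiff(sort(unique(y)), pos))
  pred <- character(n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    if (length(unique(yt)) < 2L) { skipped <- c(skipped, i); pred[i] <- NA; next }
    mu <- colMeans(Xt)
    sg <- apply(Xt, 2L, stats::sd)
    if (all(sg <= 0)) {
      # zero-information fold (every selected feature constant in training):
      # fall back to the majority class rather than an SVM tie-break
      tb <- table(factor(yt, levels = lev))
      pred[i] <- names(tb)[which.max(tb)]
      next
    }
    sg[sg <= 0] <- 1                               # constant feature -> centered zeros
    Zt <- sweep(sweep(Xt, 2L, mu), 2L, sg, "/")
    zi <- (X[i, ] - mu) / sg
    cw <- NULL
    if (isTRUE(config$balance_classes)) {
      tb <- table(factor(yt, levels = lev))
      cw <- stats::setNames(as.numeric(sum(tb) / (length(tb) * tb)), names(tb))
    }
    fit <- e1071::svm(Zt, factor(yt, levels = lev), kernel = config$kernel,
                      cost = config$cost, scale = FALSE, class.weights = cw)
    pred[i] <- as.character(stats::predict(fit, matrix(zi, nrow = 1L)))
  }
  if (length(skipped))
    warning(length(skipped), " fold(s) had single-class training data; skipped")
  use <- !is.na(pred)
  tp <- sum(use & pred == pos & y == pos)
  fn <- sum(use & pred != pos & y == pos)
  fp <- sum(use & pred == pos & y != pos)
  tn <- sum(use & pred != pos & y != pos)
  ms <- compute_metrics(tp, fn, fp, tn, "standard")
  mp <- compute_metrics(tp, fn, fp, tn, "predictive_value")
  m <- if (config$convention == "standard") ms else mp
  structure(
    list(accuracy = m$accuracy, sensitivity = m$sensitivity,
         specificity = m$specificity, convention = config$convention,
         metrics_standard = ms, metrics_predictive = mp,
         confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
         predictions = pred, subset = subset, config = config,
         n_folds = n, skipped_folds = skipped),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("LOOCV [%s]: Accu %.1f  Sens %.1f  Spec %.1f  (%s convention, %d folds)\n",
              paste(x$subset, collapse = "-"), x$accuracy, x$sensitivity,
              x$specificity, x$convention, x$n_folds))
  invisible(x)
}

#' Exhaustive feature-subset search under LOOCV
#'
#' Evaluates every non-empty subset of the feature columns (`2^K - 1`
#' subsets) with [loocv_evaluate()] and reports, for each subset size, the
#' subset with the highest accuracy. Ties are broken in favor of the subset
#' that comes first in lexicographic canonical feature order.
#'
#' @param table labeled feature table.
#' @param config a [classifier_config()].
#' @param features feature columns to search over (default: canonical names
#'   present in the table); at most 20.
#' @param keep_all if TRUE, the full per-subset results table is attached as
#'   attribute `"all_subsets"`.
#' @return data.frame (class `subset_search`) with one row per subset size:
#'   `size`, `features`, `accuracy`, `sensitivity`, `specificity` (both
#'   conventions as extra columns `sens_pv`, `spec_pv`); attribute
#'   `"n_evaluated"` records the number of subsets evaluated.
#' @export
exhaustive_subset_search <- function(table, config = classifier_config(),
                                     features = NULL, keep_all = FALSE) {
  if (is.null(features)) features <- intersect(feature_names, colnames(table))
  K <- length(features)
  if (K < 1L || K > 20L) stop("need 1..20 features to enumerate", call. = FALSE)
  n_eval <- 0L
  best <- vector("list", K)
  all_rows <- if (keep_all) vector("list", 2^K - 1L) else NULL
  for (s in seq_len(K)) {
    combos <- utils::combn(features, s, simplify = FALSE)
    acc_best <- -Inf; res_best <- NULL
    for (cm in combos) {
      r <- loocv_evaluate(table, cm, config)
      n_eval <- n_eval + 1L
      if (keep_all) all_rows[[n_eval]] <- data.frame(
        size = s, features = paste(cm, collapse = "-"),
        accuracy = r$accuracy,
        sensitivity = r$metrics_standard$sensitivity,
        specificity = r$metrics_standard$specificity)
      if (r$accuracy > acc_best) { acc_best <- r$accuracy; res_best <- r }
    }
    best[[s]] <- data.frame(
      size = s,
      features = paste(res_best$subset, collapse = "-"),
      accuracy = res_best$accuracy,
      sensitivity = res_best$metrics_standard$sensitivity,
      specificity = res_best$metrics_standard$specificity,
      sens_pv = res_best$metrics_predictive$sensitivity,
      spec_pv = res_best$metrics_predictive$specificity)
  }
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- n_eval
  if (keep_all) attr(out, "all_subsets") <- do.call(rbind, all_rows)
  class(out) <- c("subset_search", "data.frame")
  out
}
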