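#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sided statistic `D = sup_t |Fx(t) - Fy(t)|` over the
#' pooled sample points and a p-value either exactly (lattice-path counting
#' over all `choose(n+m, n)` equally likely orderings under the null) or by
#' the classical asymptotic series
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2)` with
#' `lambda = D * sqrt(nm/(n+m))`. `method = "auto"` uses the exact p-value
#' when `n + m <= 30`.
#'
#' @param x,y numeric samples (finite, length >= 1).
#' @param method `"exact"`, `"asymptotic"`, or `"auto"`.
#' @param alpha significance level for the rejection flag `h`.
#' @return A `ks_result`: list with `D`, `p_value`, `h` (`p_value < alpha`),
#'   `n`, `m`, `method`, `alpha`.
#' @export
ks_two_sample <- function(x, y, method = c("auto", "exact", "asymptotic"),
                          alpha = 0.05) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("degenerate input: empty sample", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  n <- length(x); m <- length(y)
  D <- ks_statistic(x, y)
  if (method == "auto") method <- if (n + m <= 30L) "exact" else "asymptotic"
  p <- switch(method,
              exact = ks_exact_p(D, n, m),
              asymptotic = ks_asymptotic_p(D, n, m))
  structure(list(D = D, p_value = p, h = p < alpha, n = n, m = m,
                 method = method, alpha = alpha),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (%s, n = %d, m = %d)%s\n",
              x$D, x$p_value, x$method, x$n, x$m,
              if (x$h) " *" else ""))
  invisible(x)
}

## Two-sided KS statistic; evaluating the ECDF difference at every pooled
## point covers ties correctly (both one-sided sups are attained at jumps).
ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pts)
  fy <- stats::ecdf(y)(pts)
  max(abs(fx - fy))
}

## Exact null probability P(D* >= d): count monotone lattice paths from (0,0)
## to (n,m) that keep |i/n - j/m| < d throughout; p = 1 - count / C(n+m, n).
ks_exact_p <- function(d, n, m) {
  if (d <= 0) return(1)
  h <- d * n * m - 1e-7                     # strict inequality with tolerance
  ok <- function(i, j) abs(i * m - j * n) < h
  # DP over the grid in units of C(n+m,n): use doubles (n+m <= 30 in practice)
  A <- matrix(0, n + 1L, m + 1L)
  A[1L, 1L] <- if (ok(0L, 0L)) 1 else 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0L && j == 0L) next
    if (!ok(i, j)) next
    A[i + 1L, j + 1L] <- (if (i > 0L) A[i, j + 1L] else 0) +
                         (if (j > 0L) A[i + 1L, j] else 0)
  }
  p <- 1 - A[n + 1L, m + 1L] / choose(n + m, n)
  min(max(p, 0), 1)
}

## Asymptotic two-sided p via the Kolmogorov series, truncated when terms
## drop below 1e-12.
ks_asymptotic_p <- function(d, n, m) {
  lambda <- d * sqrt(n * m / (n + m))
  if (lambda <= 0) return(1)
  s <- 0
  for (k in 1:1000) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-12) break
  }
  min(max(2 * s, 0), 1)
}

#' Rank features by between-group KS significance
#'
#' Runs [ks_two_sample()] on each feature column of a labeled feature table
#' and ranks features by ascending p-value (rank 1 = most significant); ties
#' are broken by the canonical feature order ([feature_names]).
#'
#' @param table data.frame with a `label` column (two groups) and numeric
#'   feature columns.
#' @param alpha significance level.
#' @param method p-value method passed to [ks_two_sample()].
#' @param features which columns to test; defaults to the intersection of
#'   [feature_names] with the table's columns.
#' @return data.frame `feature, D, p, h, rank, tier` sorted by rank, of class
#'   `ks_ranking`.
#' @export
rank_features <- function(table, alpha = 0.05,
                          method = c("auto", "exact", "asymptotic"),
                          features = NULL) {
  method <- match.arg(method)
  if (is.null(table$label)) stop("table must have a 'label' column", call. = FALSE)
  groups <- unique(as.character(table$label))
  if (length(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  if (is.null(features)) features <- intersect(feature_names, colnames(table))
  if (!length(features)) stop("no feature columns found", call. = FALSE)
  if (min(table(as.character(table$label))) < 2L)
    stop("need >= 2 rows per group", call. = FALSE)
  res <- lapply(features, function(f) {
    k <- ks_two_sample(table[[f]][table$label == groups[1]],
                       table[[f]][table$label == groups[2]],
                       method = method, alpha = alpha)
    data.frame(feature = f, D = k$D, p = k$p_value, h = as.integer(k$h))
  })
  out <- do.call(rbind, res)
  ord <- order(out$p, match(out$feature, feature_names))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- significance_tier(out$p)
  rownames(out) <- NULL
  class(out) <- c("ks_ranking", "data.frame")
  out
}

significance_tier <- function(p) {
  ifelse(p < 0.05, "SIG", ifelse(p < 0.5, "PSIG", "NSIG"))
}

#' Partition ranked features into significance tiers
#'
#' `SIG`: p < 0.05; `PSIG`: 0.05 <= p < 0.5; `NSIG`: p >= 0.5. The three sets
#' partition the feature list.
#'
#' @param ranked a `ks_ranking` from [rank_features()].
#' @return list with character vectors `SIG`, `PSIG`, `NSIG`.
#' @export
group_significance <- function(ranked) {
  if (!nrow(ranked)) stop("empty ranking", call. = FALSE)
  tier <- significance_tier(ranked$p)
  list(SIG = ranked$feature[tier == "SIG"],
       PSIG = ranked$feature[tier == "PSIG"],
       NSIG = ranked$feature[tier == "NSIG"])
}

#' Write a feature ranking report as delimited text
#'
#' Columns mirror a standard KS report: feature, D, p, h, rank, tier.
#'
#' @param ranked a `ks_ranking`.
#' @param path output path.
#' @export
write_ranking <- function(ranked, path) {
  utils::write.csv(as.data.frame(ranked), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
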