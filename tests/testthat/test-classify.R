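test_that("metrics follow both conventions on the same confusion matrix", {
  ms <- compute_metrics(9, 1, 2, 8, "standard")
  expect_equal(ms$accuracy, 85)
  expect_equal(ms$sensitivity, 90)
  expect_equal(ms$specificity, 80)
  mp <- compute_metrics(9, 1, 2, 8, "predictive_value")
  expect_equal(mp$accuracy, 85)
  expect_equal(mp$sensitivity, 100 * 9 / 11, tolerance = 1e-12)   # 81.8
  expect_equal(mp$specificity, 100 * 8 / 9, tolerance = 1e-12)    # 88.9
  perf <- compute_metrics(10, 0, 0, 10, "predictive_value")
  expect_true(all(unlist(perf[c("accuracy", "sensitivity", "specificity")]) == 100))
  worst <- compute_metrics(0, 10, 0, 10, "standard")
  expect_equal(worst$accuracy, 50)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 100)
  und <- compute_metrics(0, 0, 2, 8, "standard")
  expect_true(und$undefined)
  expect_true(is.na(und$sensitivity))
})

test_that("only one 10-vs-10 confusion matrix matches Accu 85.0 / 81.8 / 88.8", {
  # search all matrices with tp+fn = tn+fp = 10 for the predictive-value triple
  hits <- list()
  for (tp in 0:10) for (fp in 0:10) {
    fn <- 10 - tp; tn <- 10 - fp
    m <- compute_metrics(tp, fn, fp, tn, "predictive_value")
    if (!m$undefined &&
        round(m$accuracy, 1) == 85.0 &&
        round(m$sensitivity, 1) == 81.8 &&
        abs(m$specificity - 88.8) < 0.15)   # table prints 88.8, 8/9 = 88.9
      hits[[length(hits) + 1]] <- c(tp, fn, fp, tn)
  }
  expect_equal(length(hits), 1)
  expect_equal(hits[[1]], c(9, 1, 2, 8))
})

test_that("LOOCV separates distant clouds perfectly with n folds of n-1", {
  set.seed(61)
  n <- 10
  tab <- data.frame(label = rep(c("MD", "non-MD"), each = n),
                    F1 = c(rnorm(n, 10), rnorm(n, 0)),
                    F2 = c(rnorm(n, -10), rnorm(n, 0)))
  ev <- loocv_evaluate(tab, c("F1", "F2"))
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$n_folds, 20)
  expect_equal(length(ev$predictions), 20)
  expect_equal(length(ev$skipped_folds), 0)
})

test_that("a subject's LOOCV prediction is independent of the others' order", {
  tab <- make_noise_table(8, 3, seed = 62)
  tab$subject_id <- seq_len(nrow(tab))
  ev1 <- loocv_evaluate(tab, c("F1", "F2", "F3"))
  set.seed(63)
  perm <- sample(nrow(tab))
  ev2 <- loocv_evaluate(tab[perm, ], c("F1", "F2", "F3"))
  expect_equal(ev1$predictions[tab$subject_id[perm]], ev2$predictions)
})

test_that("with balanced classes, standard accuracy = (Sens + Spec) / 2", {
  tab <- make_noise_table(12, 4, seed = 64)
  ev <- loocv_evaluate(tab, paste0("F", 1:4))
  expect_equal(ev$metrics_standard$accuracy,
               (ev$metrics_standard$sensitivity + ev$metrics_standard$specificity) / 2)
})

test_that("LOOCV is deterministic", {
  tab <- make_noise_table(10, 4, seed = 65)
  e1 <- loocv_evaluate(tab, paste0("F", 1:4))
  e2 <- loocv_evaluate(tab, paste0("F", 1:4))
  expect_identical(e1, e2)
})

test_that("exhaustive search enumerates 2^K - 1 subsets and finds planted signal", {
  tab <- make_noise_table(10, 3, seed = 66)
  out <- exhaustive_subset_search(tab, features = paste0("F", 1:3))
  expect_equal(attr(out, "n_evaluated"), 7L)
  expect_equal(nrow(out), 3)
  hits <- 0
  for (r in 1:5) {
    tab2 <- make_noise_table(10, 4, seed = 70 + r)
    tab2$F2 <- tab2$F2 + ifelse(tab2$label == "MD", 4, 0)
    out2 <- exhaustive_subset_search(tab2, features = paste0("F", 1:4))
    if (out2$features[out2$size == 1] == "F2") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("input validation catches unknown features and missing values", {
  tab <- make_noise_table(5, 2, seed = 67)
  expect_error(loocv_evaluate(tab, c("F1", "NOPE")), "unknown feature")
  tab$F1[3] <- NA
  expect_error(loocv_evaluate(tab, c("F1", "F2")), "missing values")
  expect_error(loocv_evaluate(tab[1:3, ], "F2"), "n >= 4")
})
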