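test_that("confusion counts partition the sample", {
  cc <- confusion_counts(c("binding", "non-binding"),
                         c("binding", "non-binding"))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))

  truth <- c("binding", "non-binding")
  cc2 <- confusion_counts(truth, rev(truth))
  expect_equal(cc2$TP + cc2$TN, 0L)

  set.seed(12)
  t20 <- sample(c("binding", "non-binding"), 20L, TRUE)
  p20 <- sample(c("binding", "non-binding"), 20L, TRUE)
  cc3 <- confusion_counts(t20, p20)
  # manual tally oracle
  expect_equal(cc3$TP, sum(t20 == "binding" & p20 == "binding"))
  expect_equal(cc3$FN, sum(t20 == "binding" & p20 == "non-binding"))
  expect_equal(cc3$TP + cc3$TN + cc3$FP + cc3$FN, 20L)
  expect_error(confusion_counts(t20, p20[1:5]), "length")
})

test_that("metric formulas match direct evaluation", {
  perfect <- structure(list(TP = 50L, TN = 50L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  m <- binding_metrics(perfect)
  expect_equal(c(m$SN, m$SP, m$ST, m$ACC, m$MCC), c(1, 1, 1, 1, 1))

  chance <- structure(list(TP = 25L, TN = 25L, FP = 25L, FN = 25L),
                      class = "confusion_counts")
  mc <- binding_metrics(chance)
  expect_equal(mc$ACC, 0.5)
  expect_equal(mc$MCC, 0)

  cc <- structure(list(TP = 34L, TN = 240L, FP = 24L, FN = 5L),
                  class = "confusion_counts")
  md <- binding_metrics(cc)
  expect_equal(100 * md$SN, 87.18, tolerance = 1e-2)
  expect_equal(100 * md$SP, 90.91, tolerance = 1e-2)
  expect_equal(100 * md$ACC, 90.43, tolerance = 1e-2)
  expect_equal(md$MCC, (34 * 240 - 24 * 5) /
                 sqrt(prod(c(39, 58, 264, 245))), tolerance = 1e-12)
  expect_equal(md$MCC, 0.665, tolerance = 1e-3)
  expect_equal(md$ST, (md$SN + md$SP) / 2)
})

test_that("undefined metrics are NA with warning, never zero", {
  cc <- structure(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L),
                  class = "confusion_counts")
  w <- capture_warnings(m <- binding_metrics(cc))
  expect_match(w, "SN undefined", all = FALSE)
  expect_match(w, "MCC undefined", all = FALSE)   # TP+FP = 0 here too
  expect_true(is.na(m$SN))
  expect_true(is.na(m$MCC))
})

test_that("MCC bounds and sign-flip property hold", {
  for (s in 1:20) {
    set.seed(s)
    truth <- sample(c("binding", "non-binding"), 40L, TRUE)
    pred <- sample(c("binding", "non-binding"), 40L, TRUE)
    flip <- ifelse(pred == "binding", "non-binding", "binding")
    m <- suppressWarnings(binding_metrics(confusion_counts(truth, pred)))
    mf <- suppressWarnings(binding_metrics(confusion_counts(truth, flip)))
    if (!is.na(m$MCC)) {
      expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
      expect_equal(m$MCC, -mf$MCC, tolerance = 1e-12)
    }
  }
})

test_that("ROC endpoints, known AUC values and error cases", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("binding", "binding", "non-binding", "non-binding"))
  expect_equal(sep$auc, 1)
  expect_equal(sep$points$fpr[1L], 0)
  expect_equal(utils::tail(sep$points$tpr, 1L), 1)

  inv <- roc_curve(c(0.1, 0.2, 0.8, 0.9),
                   c("binding", "binding", "non-binding", "non-binding"))
  expect_equal(inv$auc, 0)

  half <- roc_curve(c(0.9, 0.1, 0.8, 0.2),
                    c("binding", "binding", "non-binding", "non-binding"))
  expect_equal(half$auc, 0.5)   # 2 of 4 positive-negative pairs win

  expect_error(roc_curve(1:3, rep("binding", 3L)), "both classes")
})

test_that("trapezoidal AUC equals the rank-comparison formulation", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 60L
    truth <- c(rep("binding", 20L), rep("non-binding", 40L))
    scores <- round(runif(n), 2)   # force ties
    auc <- roc_curve(scores, truth)$auc
    pos <- scores[1:20]; neg <- scores[21:60]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
    expect_equal(roc_curve(-scores, truth)$auc, 1 - auc, tolerance = 1e-12)
    expect_equal(roc_curve(exp(3 * scores), truth)$auc, auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  truth <- sample(c("binding", "non-binding"), 80L, TRUE)
  scores <- rnorm(80L) + (truth == "binding")
  ours <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                        predictor = scores,
                                        levels = c("non-binding", "binding"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("chain folds are disjoint, covering and deterministic", {
  ids <- sprintf("c%02d", 1:10)
  f <- chain_folds(ids, k = 5L, seed = 3L)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(2L, 5L))
  expect_identical(f, chain_folds(ids, 5L, 3L))
  expect_error(chain_folds(ids[1:3], 5L), "fewer chains")
  for (k in 2:4) {
    fk <- chain_folds(ids, k, seed = k)
    expect_length(fk, 10L)
    expect_true(all(fk %in% seq_len(k)))
  }
})

test_that("cross-validation pools confusion counts over folds", {
  ds <- small_dataset(seed = 33L, n_chains = 8L)
  cv <- kfold_cv(ds, fast_config(seed = 2L, window = 5L), k = 4L, seed = 2L)
  expect_length(cv$per_fold, 4L)
  # pooled counts = sum of per-fold counts = metrics of concatenation
  tot <- Reduce(`+`, lapply(cv$per_fold, function(m) unlist(m$counts)))
  expect_equal(unlist(cv$pooled$counts), tot)
  expect_equal(nrow(cv$predictions),
               sum(vapply(ds$chains, `[[`, 0L, "length")))
  expect_true(cv$roc$auc >= 0 && cv$roc$auc <= 1)

  rpt_dir <- tempfile()
  rpt <- write_report(cv, rpt_dir, seed = 2L)
  expect_true(file.exists(file.path(rpt_dir, "report.json")))
  back <- jsonlite::read_json(file.path(rpt_dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$pooled$AUC, cv$roc$auc, tolerance = 1e-12)
})

test_that("window sweep prefers small windows for short-range signal", {
  ds <- gen_labeled_dataset(n_chains = 14L, length_range = c(40L, 60L),
                            spec = signal_spec(delta = 6, context_width = 1L),
                            seed = 8L)
  sw <- sweep_window(ds, ws = c(3L, 5L, 11L), seed = 8L)
  expect_equal(nrow(sw$table), 3L)
  expect_lte(sw$best_w, 5L)
  sw2 <- sweep_window(ds, ws = c(3L, 5L, 11L), seed = 8L)
  expect_identical(sw$table, sw2$table)

  single <- sweep_window(ds, ws = 5L, seed = 1L)
  expect_equal(single$best_w, 5L)
  expect_error(sweep_window(ds, ws = c(3L, 4L)), "odd")
})

test_that("Wilcoxon comparison matches exact small-sample distribution", {
  expect_warning(p_id <- compare_methods(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(p_id, 1)

  a <- c(0.80, 0.82, 0.84, 0.86, 0.88, 0.90)
  b <- a - c(0.010, 0.021, 0.032, 0.043, 0.054, 0.065)
  expect_equal(compare_methods(a, b), 2 / 64, tolerance = 1e-12)
  expect_equal(compare_methods(b, a), compare_methods(a, b))
  expect_error(compare_methods(1, 2), ">= 2")
})
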