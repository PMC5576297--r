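# Confusion-based metrics, ROC/AUC, k-fold cross-validation,
# window-size sweep, paired significance testing.

#' Confusion counts for binary binding predictions
#'
#' @param truth,predicted equal-length label vectors
#'   (`"binding"`/`"non-binding"`, logical, or factors).
#' @return object of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_label_factor(truth)
  predicted <- as_label_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  if (anyNA(truth) || anyNA(predicted)) stop("labels must be binary")
  structure(list(TP = sum(truth == "binding" & predicted == "binding"),
                 TN = sum(truth == "non-binding" & predicted == "non-binding"),
                 FP = sum(truth == "non-binding" & predicted == "binding"),
                 FN = sum(truth == "binding" & predicted == "non-binding")),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), strength
#' ST = (SN+SP)/2, accuracy ACC = (TP+TN)/N, and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` with a
#' warning, never silently as 0.
#'
#' @param cc a [confusion_counts()] object.
#' @return object of class `metric_set`: `SN`, `SP`, `ST`, `ACC` as
#'   fractions in \[0, 1\] and `MCC` in \[-1, 1\].
#' @export
binding_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0L) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  sn <- safe_div(cc$TP, cc$TP + cc$FN, "SN")
  sp <- safe_div(cc$TN, cc$TN + cc$FP, "SP")
  mcc_den <- sqrt(prod(c(cc$TP + cc$FN, cc$TP + cc$FP,
                         cc$TN + cc$FP, cc$TN + cc$FN)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator)")
    NA_real_
  } else (cc$TP * cc$TN - cc$FP * cc$FN) / mcc_den
  structure(list(SN = sn, SP = sp, ST = (sn + sp) / 2, ACC = (cc$TP + cc$TN) / n,
                 MCC = mcc, counts = cc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  cat(sprintf("SN = %.*f%%  SP = %.*f%%  ST = %.*f%%  ACC = %.*f%%  MCC = %.3f\n",
              digits, 100 * x$SN, digits, 100 * x$SP, digits, 100 * x$ST,
              digits, 100 * x$ACC, x$MCC))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a decision threshold (predict binding
#' when score >= threshold), collects (FPR, TPR) points from (0,0) to
#' (1,1), and integrates by the trapezoidal rule. The result equals the
#' probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores numeric scores, larger = more binding-like.
#' @param truth labels as in [confusion_counts()].
#' @return object of class `roc_curve`: `points` (data frame fpr, tpr,
#'   threshold) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as_label_factor(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  pos <- truth == "binding"
  if (!any(pos) || all(pos)) stop("ROC needs both classes")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / sum(pos), 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / sum(!pos), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Write ROC points as TSV
#'
#' @param roc a [roc_curve()] result.
#' @param path output TSV path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Chain-level k-fold assignment
#'
#' @param chain_ids character vector of chain ids.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold per chain (named).
#' @export
chain_folds <- function(chain_ids, k = 5L, seed = 1L) {
  if (length(chain_ids) < k) stop("fewer chains than folds")
  shuffled <- with_seed(seed, sample(chain_ids))
  fold <- rep(seq_len(k), length.out = length(shuffled))
  stats::setNames(fold[match(chain_ids, shuffled)], chain_ids)
}

#' k-fold cross-validation of the full pipeline
#'
#' Chain-level folds (all residues of a chain stay in one fold, so
#' near-identical windows never straddle the train/test split). Each
#' fold trains a full ensemble on the remaining chains and predicts
#' the held-out chains. Pooled metrics are computed from the summed
#' confusion counts across folds (micro average); per-fold metric sets
#' are retained for paired significance tests.
#'
#' @param dataset list with `chains`, `pssms` (raw or normalized),
#'   `labels` (named per-chain label vectors), as produced by
#'   [gen_labeled_dataset()] or assembled from files.
#' @param config a [run_config()].
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed (training seeds derive from it).
#' @return list: `per_fold` (list of `metric_set`), `pooled`
#'   (`metric_set` over summed counts), `roc` (pooled [roc_curve()]),
#'   `folds` (chain assignment), `predictions` (data frame).
#' @export
kfold_cv <- function(dataset, config = run_config(), k = 5L, seed = 1L) {
  ids <- names(dataset$chains)
  folds <- chain_folds(ids, k, seed)
  preds <- list()
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- ids[folds == f]
    train_ids <- ids[folds != f]
    fold_cfg <- config
    fold_cfg$seed <- (seed * 97L + f) %% .Machine$integer.max
    model <- run_train(subset_dataset(dataset, train_ids), fold_cfg)
    p <- run_predict(model, dataset$chains[test_ids], dataset$pssms[test_ids],
                     ss_tracks = dataset$ss_tracks[test_ids],
                     acc_tracks = dataset$acc_tracks[test_ids])
    p$truth <- unlist(dataset$labels[test_ids], use.names = FALSE)
    p$fold <- f
    per_fold[[f]] <- binding_metrics(confusion_counts(p$truth, p$label == "+"))
    preds[[f]] <- p
  }
  preds <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  pooled <- binding_metrics(confusion_counts(preds$truth, preds$label == "+"))
  roc <- roc_curve(preds$score, preds$truth)
  list(per_fold = per_fold, pooled = pooled, roc = roc, folds = folds,
       predictions = preds)
}

#' Window-size sweep
#'
#' Trains and evaluates a single balanced SVM on the PSSM-RT block for
#' each candidate window size, on a seeded chain-level holdout split,
#' and returns the ST (average of sensitivity and specificity) per w.
#' The selected w maximizes ST; ties go to the smaller window.
#'
#' @param dataset as in [kfold_cv()].
#' @param ws odd candidate window sizes.
#' @param seed split/undersampling seed.
#' @param holdout fraction of chains held out for evaluation
#'   (default 0.3).
#' @param cost_grid,gamma_grid SVM grid, see [train_base_predictors()].
#' @return list: `table` (data frame w, ST), `best_w`.
#' @export
sweep_window <- function(dataset, ws = seq(3L, 15L, 2L), seed = 1L,
                         holdout = 0.3, cost_grid = 1, gamma_grid = NULL) {
  if (any(ws %% 2L != 1L)) stop("all window sizes must be odd")
  ids <- names(dataset$chains)
  n_test <- max(1L, round(holdout * length(ids)))
  test_ids <- with_seed(seed, sample(ids, n_test))
  train_ids <- setdiff(ids, test_ids)
  npssms <- normalize_all(dataset$pssms)
  st <- vapply(ws, function(w) {
    tr <- encode_chains(dataset$chains[train_ids], npssms[train_ids], w,
                        blocks = "pssm_rt")
    te <- encode_chains(dataset$chains[test_ids], npssms[test_ids], w,
                        blocks = "pssm_rt")
    y_tr <- as_label_factor(unlist(dataset$labels[train_ids],
                                   use.names = FALSE))
    y_te <- unlist(dataset$labels[test_ids], use.names = FALSE)
    pos <- which(y_tr == "binding")
    neg <- which(y_tr == "non-binding")
    neg_keep <- with_seed(seed + w,
                          sample(neg, min(length(neg), length(pos))))
    keep <- c(pos, neg_keep)
    gam <- if (is.null(gamma_grid)) 1 / ncol(tr$pssm_rt) else gamma_grid
    best <- tune_svm(tr$pssm_rt[keep, ], y_tr[keep], cost_grid, gam,
                     seed = seed)
    fit <- fit_svm(tr$pssm_rt[keep, ], y_tr[keep], best$cost, best$gamma)
    m <- binding_metrics(confusion_counts(y_te, stats::predict(fit,
                                                               te$pssm_rt)))
    m$ST
  }, 0)
  tab <- data.frame(w = ws, ST = st)
  list(table = tab, best_w = ws[order(-st, ws)][1L])
}

#' Paired comparison of two methods
#'
#' Exact two-sided Wilcoxon signed-rank test on paired per-fold metric
#' values.
#'
#' @param metric_a,metric_b equal-length numeric vectors of paired
#'   observations (>= 2 pairs).
#' @return two-sided p-value.
#' @export
compare_methods <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop("unpaired input")
  if (length(metric_a) < 2L) stop("need >= 2 paired observations")
  d <- metric_a - metric_b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  stats::wilcox.test(metric_a, metric_b, paired = TRUE, exact = TRUE)$p.value
}

#' Write an evaluation report
#'
#' @param cv a [kfold_cv()] result.
#' @param dir output directory; writes `report.json`,
#'   `predictions.tsv` and `roc.tsv`.
#' @param seed seed to record in the report.
#' @export
write_report <- function(cv, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(m) m[c("SN", "SP", "ST", "ACC", "MCC")]
  report <- list(seed = seed, pooled = c(strip(cv$pooled), AUC = cv$roc$auc),
                 per_fold = lapply(cv$per_fold, strip),
                 folds = as.list(cv$folds))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cv$predictions, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_roc_tsv(cv$roc, file.path(dir, "roc.tsv"))
  invisible(report)
}
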