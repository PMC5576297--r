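# Imbalance-aware ensemble: balanced negative partitioning, SVM/RF base
# predictors per feature block, diversity-based dynamic selection,
# majority vote.

LABEL_LEVELS <- c("non-binding", "binding")

as_label_factor <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "binding", "non-binding")
  factor(as.character(x), levels = LABEL_LEVELS)
}

#' Partition negative instances into balanced subsets
#'
#' Splits the majority (non-binding) class into
#' `n = max(1, round(|neg| / positive_count))` disjoint subsets of
#' near-equal size (within one of each other), after a deterministic
#' seeded shuffle.
#'
#' @param negative_ids vector of negative instance ids.
#' @param positive_count number of positive instances (>= 1).
#' @param seed integer seed for the shuffle.
#' @return object of class `balanced_partition`: `n`, `subsets` (list
#'   of id vectors), `seed`.
#' @export
partition_negatives <- function(negative_ids, positive_count, seed = 1L) {
  if (positive_count < 1L) stop("positive_count must be >= 1")
  if (length(negative_ids) < 1L) stop("no negative instances")
  n <- max(1L, as.integer(round(length(negative_ids) / positive_count)))
  ids <- with_seed(seed, sample(negative_ids))
  groups <- rep(seq_len(n), length.out = length(ids))
  # contiguous split: first ceil(|neg|/n) ids to subset 1, etc.
  sizes <- tabulate(groups, n)
  subsets <- split(ids, rep(seq_len(n), times = sizes))
  names(subsets) <- NULL
  structure(list(n = n, subsets = subsets, seed = seed),
            class = "balanced_partition")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Build the n balanced training sets
#'
#' Each training set pairs all positive instances with one negative
#' subset, so every negative is used exactly once across the ensemble
#' while positives recur in every set.
#'
#' @param partition a [partition_negatives()] result.
#' @param positive_ids vector of positive instance ids.
#' @return list of `n` id vectors (positives first).
#' @export
build_balanced_sets <- function(partition, positive_ids) {
  stopifnot(inherits(partition, "balanced_partition"))
  clash <- intersect(positive_ids, unlist(partition$subsets))
  if (length(clash) > 0L)
    stop("id(s) present in both classes: ",
         paste(utils::head(clash, 5L), collapse = ", "))
  lapply(partition$subsets, function(s) c(positive_ids, s))
}

# e1071::svm with feature standardization; constant columns (e.g. the
# all-zero sub-blocks of absent prediction tracks) are left unscaled
# without the per-fit warning
fit_svm <- function(x, y, cost, gamma) {
  withCallingHandlers(
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = TRUE),
    warning = function(w) {
      if (grepl("Cannot scale data", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

tune_svm <- function(x, y, costs, gammas, folds = 3L, seed = 1L) {
  combos <- expand.grid(cost = costs, gamma = gammas)
  if (nrow(combos) == 1L) return(combos[1L, ])
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  acc <- vapply(seq_len(nrow(combos)), function(ci) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) next
      m <- fit_svm(x[tr, , drop = FALSE], y[tr],
                   combos$cost[ci], combos$gamma[ci])
      correct <- correct + sum(stats::predict(m, x[!tr, , drop = FALSE]) ==
                                 y[!tr])
    }
    correct / nrow(x)
  }, 0)
  combos[which.max(acc), ]
}

#' Train the pool of base predictors
#'
#' Trains one predictor per (algorithm x feature block x balanced set):
#' `2 * n_blocks * n` in total (6n with the three standard blocks). SVMs
#' use the radial-basis kernel with cost/width chosen by grid search
#' under internal cross-validation on each training set; random forests
#' are seeded for determinism.
#'
#' @param sets list of instance-id vectors from [build_balanced_sets()].
#' @param features named list of feature matrices (one per block; rows
#'   indexed by instance id).
#' @param labels vector of instance labels
#'   (`"binding"`/`"non-binding"`), length = total instances.
#' @param cost_grid,gamma_grid SVM grid; `gamma_grid = NULL` means the
#'   1/d default width.
#' @param num_trees random-forest size (default 151; odd, so binary
#'   tree votes cannot tie).
#' @param svm_folds internal CV folds for the SVM grid (default 3).
#' @param seed master seed; per-predictor seeds are derived from it.
#' @return list of `base_predictor` objects (`id`, `algorithm`,
#'   `block`, `subset`, `train_ids`, `fit`).
#' @export
train_base_predictors <- function(sets, features, labels,
                                  cost_grid = c(1, 10), gamma_grid = NULL,
                                  num_trees = 151L, svm_folds = 3L,
                                  seed = 1L) {
  if (length(cost_grid) < 1L) stop("empty hyperparameter grid")
  labels <- as_label_factor(labels)
  pool <- list()
  for (b in names(features)) {
    gam <- if (is.null(gamma_grid)) 1 / ncol(features[[b]]) else gamma_grid
    for (k in seq_along(sets)) {
      ids <- sets[[k]]
      x <- features[[b]][ids, , drop = FALSE]
      y <- labels[ids]
      if (length(unique(y)) < 2L)
        stop(sprintf("training set %d has a single class", k))
      sub_seed <- (seed * 131L + k * 7L) %% .Machine$integer.max
      best <- tune_svm(x, y, cost_grid, gam, svm_folds, sub_seed)
      svm_fit <- fit_svm(x, y, best$cost, best$gamma)
      pool[[length(pool) + 1L]] <- structure(
        list(id = sprintf("svm_%s_s%02d", b, k), algorithm = "svm",
             block = b, subset = k, train_ids = ids, fit = svm_fit,
             hyper = as.list(best)),
        class = "base_predictor")
      rf_fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                               seed = sub_seed, num.threads = 1L,
                               verbose = FALSE)
      pool[[length(pool) + 1L]] <- structure(
        list(id = sprintf("rf_%s_s%02d", b, k), algorithm = "rf",
             block = b, subset = k, train_ids = ids, fit = rf_fit,
             hyper = list(num_trees = num_trees)),
        class = "base_predictor")
    }
  }
  pool[order(vapply(pool, `[[`, "", "id"))]
}

#' Predict labels with one base predictor
#'
#' @param predictor a `base_predictor`.
#' @param features named list of feature matrices (only the predictor's
#'   block is used), or a single matrix of that block.
#' @return factor of labels (`non-binding`/`binding`).
#' @export
predict_base <- function(predictor, features) {
  stopifnot(inherits(predictor, "base_predictor"))
  x <- if (is.list(features)) features[[predictor$block]] else features
  if (is.null(x)) stop("features lack block ", predictor$block)
  if (predictor$algorithm == "svm") {
    stats::predict(predictor$fit, x)
  } else {
    # fixed seed: ranger breaks tied tree votes randomly at predict time
    stats::predict(predictor$fit, data = x, num.threads = 1L,
                   seed = 1L)$predictions
  }
}

#' Disagreement rate between two label vectors
#'
#' The proportion of positions at which the two predictors assign
#' different labels; 0 for identical vectors, 1 for complete
#' disagreement.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric in \[0, 1\].
#' @export
diversity <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  mean(as.character(labels_a) != as.character(labels_b))
}

mean_pairwise_diversity <- function(pred_mat, idx) {
  if (length(idx) < 2L) return(0)
  pairs <- utils::combn(idx, 2L)
  mean(vapply(seq_len(ncol(pairs)), function(p)
    diversity(pred_mat[, pairs[1L, p]], pred_mat[, pairs[2L, p]]), 0))
}

#' Diversity-based dynamic selection of base predictors
#'
#' Starts from one seeded-random predictor; each iteration ranks the
#' unselected predictors by their mean diversity against the selected
#' set and adds the most diverse (ties broken by predictor id). The
#' iteration stops when the best candidate's diversity gain falls
#' below `epsilon`, or the pool is exhausted. The gain of a candidate
#' is its mean diversity against the current members — equivalently,
#' the increase in the total pairwise diversity of the selected set
#' divided by the number of pairs the addition creates — so selection
#' stops once every remaining predictor is an epsilon-near clone of
#' the selected committee.
#'
#' @param pool list of `base_predictor`s.
#' @param val_features named list of feature matrices for the
#'   validation set.
#' @param epsilon stopping threshold on the diversity gain
#'   (default 0.01).
#' @param seed seed for the initial random pick.
#' @param val_predictions optional precomputed n_val x n_pool label
#'   matrix (columns in pool order), bypassing `val_features`.
#' @return object of class `ensemble_model`: `predictors` (selected
#'   `base_predictor`s), `predictor_ids`, `epsilon`, `seed`, `trace`
#'   (data frame: step, id, mean_diversity, gain), `pool_ids`.
#' @export
select_predictors <- function(pool, val_features = NULL, epsilon = 0.01,
                              seed = 1L, val_predictions = NULL) {
  if (length(pool) == 0L) stop("empty predictor pool")
  ids <- vapply(pool, `[[`, "", "id")
  if (is.null(val_predictions)) {
    val_predictions <- vapply(pool, function(p)
      as.character(predict_base(p, val_features)),
      character(nrow(val_features[[pool[[1L]]$block]])))
    if (is.null(dim(val_predictions)))
      val_predictions <- matrix(val_predictions, nrow = 1L)
  }
  colnames(val_predictions) <- ids
  first <- with_seed(seed, sample(length(pool), 1L))
  selected <- first
  trace <- data.frame(step = 1L, id = ids[first], mean_diversity = NA_real_,
                      gain = NA_real_, stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(seq_along(pool), selected)
    if (length(remaining) == 0L) break
    mean_div <- vapply(remaining, function(c)
      mean(vapply(selected, function(s)
        diversity(val_predictions[, c], val_predictions[, s]), 0)), 0)
    best_pos <- order(-mean_div, ids[remaining])[1L]
    best <- remaining[best_pos]
    gain <- mean_div[best_pos]
    if (gain < epsilon) break
    selected <- c(selected, best)
    trace <- rbind(trace, data.frame(step = length(selected), id = ids[best],
                                     mean_diversity = gain,
                                     gain = gain, stringsAsFactors = FALSE))
  }
  structure(list(predictors = pool[selected], predictor_ids = ids[selected],
                 epsilon = epsilon, seed = seed, trace = trace,
                 pool_ids = ids),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model:", length(x$predictors), "of", length(x$pool_ids),
      "base predictors selected (epsilon =", x$epsilon, ")\n")
  cat(" ", paste(x$predictor_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Majority-vote prediction
#'
#' Each selected base predictor casts one label vote; the reported
#' score is the fraction of binding votes (used as the ROC score) and
#' the label is the majority class, with exact ties resolved to
#' binding.
#'
#' @param model an `ensemble_model`.
#' @param features named list of feature matrices for the instances to
#'   predict.
#' @return list with `labels` (factor) and `score` (numeric in
#'   \[0, 1\]).
#' @export
vote_predict <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  votes <- vapply(model$predictors, function(p)
    as.character(predict_base(p, features)) == "binding",
    logical(nrow(features[[model$predictors[[1L]]$block]])))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  tally_votes(votes)
}

# votes: logical matrix, instances x predictors (TRUE = binding vote);
# exact tie resolves to binding to favour the rare class
tally_votes <- function(votes) {
  score <- rowMeans(votes)
  list(labels = as_label_factor(score >= 0.5), score = score)
}
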