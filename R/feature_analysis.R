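# Discriminant-weight feature analysis: W = A^T M and the ranking of
# pair-relationship features.

#' Per-instance classification weights from a trained ensemble
#'
#' Default strategy (`"svm_dual"`): for every selected SVM base
#' predictor, each support vector contributes its signed dual
#' coefficient (alpha * y, oriented toward the binding class) to the
#' training instance it came from; contributions are summed across
#' predictors. Instances that are not support vectors of any selected
#' SVM — or never appear in a selected predictor's balanced set — get
#' weight 0.
#'
#' @param model an `ensemble_model` (or `el_pssm_rt` fit).
#' @param n_instances total number of training instances (rows of the
#'   feature matrix the weights will be applied to).
#' @param strategy weight-extraction strategy; only `"svm_dual"` is
#'   built in.
#' @return object of class `classification_weights`: numeric `a` of
#'   length `n_instances` and the `strategy` tag.
#' @export
extract_classification_weights <- function(model, n_instances,
                                           strategy = "svm_dual") {
  if (inherits(model, "el_pssm_rt")) model <- model$ensemble
  stopifnot(inherits(model, "ensemble_model"))
  strategy <- match.arg(strategy)
  svms <- Filter(function(p) p$algorithm == "svm", model$predictors)
  if (length(svms) == 0L)
    stop("no SVM base predictor in the selected ensemble; ",
         "the svm_dual strategy does not apply")
  a <- numeric(n_instances)
  for (p in svms) {
    fit <- p$fit
    # e1071 orients the decision value toward the class seen first in
    # the training data (fit$labels order), not the factor level order
    sign <- if (fit$levels[fit$labels[1L]] == "binding") 1 else -1
    global <- p$train_ids[fit$index]
    a[global] <- a[global] + sign * as.numeric(fit$coefs)
  }
  structure(list(a = a, strategy = strategy),
            class = "classification_weights")
}

#' Discriminant weight vector
#'
#' W = A^T M: the length-d vector obtained by weighting each training
#' instance's feature vector by its classification weight and summing.
#' Feature slots with large positive weight push toward the binding
#' class.
#'
#' @param A a [extract_classification_weights()] result, or a bare
#'   numeric vector of per-instance weights.
#' @param M n x d training feature matrix (named columns align the
#'   weights with the feature schema).
#' @return object of class `discriminant_weights`: named numeric `w` of
#'   length d and the `strategy` tag.
#' @export
discriminant_weights <- function(A, M) {
  strategy <- NA_character_
  if (inherits(A, "classification_weights")) {
    strategy <- A$strategy
    A <- A$a
  }
  M <- as.matrix(M)
  if (length(A) != nrow(M))
    stop(sprintf("weight length (%d) != feature matrix rows (%d)",
                 length(A), nrow(M)))
  w <- drop(crossprod(A, M))
  names(w) <- colnames(M)
  structure(list(w = w, strategy = strategy),
            class = "discriminant_weights")
}

#' Rank pair-relationship features by discriminant weight
#'
#' Extracts the 400 `pair_<r1>_<r2>` slots, sorts them by weight
#' (descending; ties broken lexicographically by (r1, r2)), and lays
#' the weights out as a 20 x 20 grid (rows r1 = context residue,
#' columns r2 = target residue) for heat-map plotting.
#'
#' @param W a [discriminant_weights()] result (or a named numeric
#'   vector containing `pair_*` entries).
#' @param absolute rank by absolute weight instead of signed weight.
#' @return list: `ranking` (data frame rank, r1, r2, weight) and `grid`
#'   (20 x 20 matrix).
#' @export
rank_pair_relationships <- function(W, absolute = FALSE) {
  w <- if (inherits(W, "discriminant_weights")) W$w else W
  pair_idx <- grep("^pair_", names(w))
  if (length(pair_idx) == 0L) stop("feature schema lacks a pair block")
  pw <- w[pair_idx]
  parts <- do.call(rbind, strsplit(sub("^pair_", "", names(pw)), "_"))
  key <- if (absolute) -abs(pw) else -pw
  ord <- order(key, parts[, 1L], parts[, 2L])
  ranking <- data.frame(rank = seq_along(ord), r1 = parts[ord, 1L],
                        r2 = parts[ord, 2L], weight = unname(pw[ord]),
                        stringsAsFactors = FALSE)
  grid <- matrix(NA_real_, 20L, 20L,
                 dimnames = list(r1 = PSSM_COLUMNS, r2 = PSSM_COLUMNS))
  grid[cbind(parts[, 1L], parts[, 2L])] <- pw
  list(ranking = ranking, grid = grid)
}

#' Write the 20 x 20 pair-weight grid as TSV
#'
#' @param ranked a [rank_pair_relationships()] result.
#' @param path output TSV path.
#' @export
write_pair_grid_tsv <- function(ranked, path) {
  utils::write.table(cbind(r1 = rownames(ranked$grid),
                           as.data.frame(ranked$grid)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
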