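# End-to-end workflows: train, predict, evaluate; model persistence.

#' Pipeline configuration
#'
#' @param window odd sliding-window size (default 13, the size at
#'   which prediction strength peaks for this encoding).
#' @param cutoff binding-distance cutoff in Angstrom (default 3.5).
#' @param epsilon diversity-gain stopping threshold for base-predictor
#'   selection (default 0.01).
#' @param seed master seed; all derived randomness (partition shuffle,
#'   validation split, forest seeds, initial selection pick) flows
#'   from it.
#' @param folds cross-validation folds (default 5).
#' @param blocks feature blocks to use.
#' @param validation_fraction fraction of training chains held out
#'   (chain-level) for diversity selection (default 0.1).
#' @param cost_grid,gamma_grid SVM hyperparameter grid
#'   (`gamma_grid = NULL` = 1/d).
#' @param num_trees random-forest size (default 151).
#' @param svm_folds internal CV folds for the SVM grid (default 3).
#' @return object of class `run_config`.
#' @export
run_config <- function(window = 13L, cutoff = 3.5, epsilon = 0.01,
                       seed = 1L, folds = 5L,
                       blocks = c("pssm_rt", "sequence", "physicochemical"),
                       validation_fraction = 0.1, cost_grid = c(1, 10),
                       gamma_grid = NULL, num_trees = 151L, svm_folds = 3L) {
  if (window %% 2L != 1L || window < 3L) stop("window must be odd and >= 3")
  blocks <- match.arg(blocks, several.ok = TRUE)
  structure(list(window = as.integer(window), cutoff = cutoff,
                 epsilon = epsilon, seed = as.integer(seed),
                 folds = as.integer(folds), blocks = blocks,
                 validation_fraction = validation_fraction,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 num_trees = as.integer(num_trees),
                 svm_folds = as.integer(svm_folds)),
            class = "run_config")
}

#' Restrict a dataset to a subset of chains
#'
#' Keeps the named chains (and their PSSMs, labels and optional
#' prediction tracks); useful for holdout splits.
#'
#' @param dataset as in [run_train()].
#' @param ids chain ids to keep.
#' @return the restricted dataset list.
#' @export
subset_dataset <- function(dataset, ids) {
  out <- dataset
  for (f in c("chains", "pssms", "labels", "ss_tracks", "acc_tracks"))
    if (!is.null(dataset[[f]])) out[[f]] <- dataset[[f]][ids]
  out
}

#' Train the full ensemble predictor
#'
#' Runs the four construction steps: hold out a chain-level validation
#' split, encode the feature blocks, partition the non-binding
#' residues into n balanced subsets, train the 2 x blocks x n base
#' predictors, and prune the pool by diversity-based dynamic selection
#' on the validation split.
#'
#' @param dataset list with named `chains`, `pssms` (raw or
#'   normalized) and `labels` (per-chain vectors), plus optional
#'   `ss_tracks`/`acc_tracks`.
#' @param config a [run_config()].
#' @return object of class `el_pssm_rt`: the selected `ensemble`
#'   (an `ensemble_model`), `config`, `schema` (feature names per
#'   block), `partition` summary, `validation_chains`, `n`.
#' @export
run_train <- function(dataset, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ids <- names(dataset$chains)
  if (is.null(ids) || length(ids) < 2L)
    stop("need at least 2 named chains")
  missing_pssm <- ids[vapply(ids, function(i) is.null(dataset$pssms[[i]]),
                             TRUE)]
  if (length(missing_pssm) > 0L)
    stop("missing PSSM for chain(s): ", paste(missing_pssm, collapse = ", "))
  if (is.null(dataset$labels)) stop("missing labels")

  n_val <- max(1L, round(config$validation_fraction * length(ids)))
  val_ids <- character(0)
  for (try in 0:9) {
    val_ids <- with_seed(config$seed + try, sample(ids, n_val))
    if (length(unique(unlist(dataset$labels[val_ids]))) == 2L) break
  }
  train_ids <- setdiff(ids, val_ids)

  npssms <- normalize_all(dataset$pssms)
  table <- if ("physicochemical" %in% config$blocks) aa_property_table()
  enc_tr <- encode_chains(dataset$chains[train_ids], npssms[train_ids],
                          config$window, config$blocks,
                          dataset$ss_tracks[train_ids],
                          dataset$acc_tracks[train_ids], table)
  enc_val <- encode_chains(dataset$chains[val_ids], npssms[val_ids],
                           config$window, config$blocks,
                           dataset$ss_tracks[val_ids],
                           dataset$acc_tracks[val_ids], table)
  y_tr <- unlist(dataset$labels[train_ids], use.names = FALSE)
  pos <- which(y_tr == "binding")
  neg <- which(y_tr != "binding")
  if (length(pos) == 0L) stop("training data has no binding residues")
  partition <- partition_negatives(neg, length(pos), config$seed)
  sets <- build_balanced_sets(partition, pos)
  feats <- enc_tr[config$blocks]
  pool <- train_base_predictors(sets, feats, y_tr,
                                cost_grid = config$cost_grid,
                                gamma_grid = config$gamma_grid,
                                num_trees = config$num_trees,
                                svm_folds = config$svm_folds,
                                seed = config$seed)
  ensemble <- select_predictors(pool, enc_val[config$blocks],
                                epsilon = config$epsilon, seed = config$seed)
  structure(list(ensemble = ensemble, config = config,
                 schema = lapply(feats, colnames),
                 n = partition$n,
                 partition_sizes = lengths(partition$subsets),
                 n_pool = length(pool),
                 validation_chains = val_ids,
                 train_chains = train_ids,
                 train_labels = y_tr,
                 train_features = feats),
            class = "el_pssm_rt")
}

#' @export
print.el_pssm_rt <- function(x, ...) {
  cat("el_pssm_rt model: w =", x$config$window, "| n =", x$n,
      "balanced sets |", x$n_pool, "base predictors,",
      length(x$ensemble$predictors), "selected\n")
  invisible(x)
}

#' Predict binding residues for new chains
#'
#' @param model an `el_pssm_rt` fit.
#' @param chains named list of [protein_chain()]s.
#' @param pssms named list of matching `pssm` objects.
#' @param ss_tracks,acc_tracks optional named prediction tracks.
#' @return data frame: `chain_id`, `position`, `residue`, `label`
#'   (`"+"` binding / `"-"` non-binding), `score` (binding vote
#'   fraction in \[0, 1\]).
#' @export
run_predict <- function(model, chains, pssms, ss_tracks = NULL,
                        acc_tracks = NULL) {
  stopifnot(inherits(model, "el_pssm_rt"))
  missing_pssm <- setdiff(names(chains), names(pssms))
  if (length(missing_pssm) > 0L)
    stop("missing PSSM for chain(s): ", paste(missing_pssm, collapse = ", "))
  table <- if ("physicochemical" %in% model$config$blocks) aa_property_table()
  enc <- encode_chains(chains, normalize_all(pssms), model$config$window,
                       model$config$blocks, ss_tracks, acc_tracks, table)
  for (b in model$config$blocks)
    if (!identical(colnames(enc[[b]]), model$schema[[b]]))
      stop("feature schema mismatch between model and encoder for block ", b)
  v <- vote_predict(model$ensemble, enc[model$config$blocks])
  data.frame(chain_id = enc$meta$chain_id, position = enc$meta$position,
             residue = enc$meta$residue,
             label = ifelse(v$labels == "binding", "+", "-"),
             score = v$score, stringsAsFactors = FALSE)
}

#' @export
predict.el_pssm_rt <- function(object, chains, pssms, ...) {
  run_predict(object, chains, pssms, ...)
}

#' Cross-validated evaluation of the pipeline
#'
#' Thin wrapper around [kfold_cv()] that also writes a JSON/TSV report
#' when `out_dir` is given.
#'
#' @param dataset as in [run_train()].
#' @param config a [run_config()].
#' @param out_dir optional report directory.
#' @return the [kfold_cv()] result.
#' @export
run_evaluate <- function(dataset, config = run_config(), out_dir = NULL) {
  labs <- unlist(dataset$labels, use.names = FALSE)
  if (length(unique(labs)) < 2L) stop("dataset has a single class")
  cv <- kfold_cv(dataset, config, k = config$folds, seed = config$seed)
  if (!is.null(out_dir)) write_report(cv, out_dir, seed = config$seed)
  cv
}

#' Persist a trained model
#'
#' Writes per-predictor serialized state plus a JSON manifest with the
#' selection trace, configuration, seeds and feature schema.
#'
#' @param model an `el_pssm_rt` fit.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "el_pssm_rt"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in model$ensemble$predictors)
    saveRDS(p, file.path(dir, paste0(p$id, ".rds")))
  manifest <- list(
    predictor_ids = model$ensemble$predictor_ids,
    pool_ids = model$ensemble$pool_ids,
    trace = model$ensemble$trace,
    epsilon = model$ensemble$epsilon,
    selection_seed = model$ensemble$seed,
    config = unclass(model$config),
    schema = model$schema,
    n = model$n, n_pool = model$n_pool,
    partition_sizes = model$partition_sizes,
    validation_chains = model$validation_chains)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a persisted model
#'
#' @param dir directory written by [save_model()].
#' @return an `el_pssm_rt` model (without retained training features).
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  predictors <- lapply(manifest$predictor_ids, function(id)
    readRDS(file.path(dir, paste0(id, ".rds"))))
  ensemble <- structure(list(predictors = predictors,
                             predictor_ids = manifest$predictor_ids,
                             epsilon = manifest$epsilon,
                             seed = manifest$selection_seed,
                             trace = manifest$trace,
                             pool_ids = manifest$pool_ids),
                        class = "ensemble_model")
  config <- do.call(run_config, manifest$config[
    setdiff(names(manifest$config), character(0))])
  structure(list(ensemble = ensemble, config = config,
                 schema = manifest$schema, n = manifest$n,
                 n_pool = manifest$n_pool,
                 partition_sizes = manifest$partition_sizes,
                 validation_chains = manifest$validation_chains),
            class = "el_pssm_rt")
}
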