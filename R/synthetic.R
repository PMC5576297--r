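# Seed-deterministic synthetic data: PSSMs with planted pair-
# relationship signal, imbalanced residue labels, toy protein-DNA
# complexes.

#' Specification of the planted signal
#'
#' Describes the synthetic study conditions: how strongly binding
#' positions shift the evolutionary profile, which amino-acid pair
#' carries the planted pair-relationship, and how imbalanced the
#' labels are.
#'
#' @param delta raw-score shift added at binding positions (default 6):
#'   `+delta` on the target row's `r2` column and on the context rows'
#'   `r1` column.
#' @param r1 context residue type of the planted pair (default "K").
#' @param r2 target residue type of the planted pair (default "R").
#' @param rho imbalance ratio: expected negatives per positive
#'   (default 5, within the 5-14 range typical of protein-DNA
#'   interface datasets).
#' @param noise_sd standard deviation of the background integer scores
#'   (default 3).
#' @param context_width how many positions on each side of a binding
#'   residue receive the context shift (default 3).
#' @param seq_enrich probability that a binding position's residue
#'   identity is forced to `r2` (and its context biased toward `r1`),
#'   mimicking the K/R/S compositional enrichment of real DNA-binding
#'   interfaces; defaults to 0.4 when `delta > 0` and 0 for a fully
#'   null dataset.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(delta = 6, r1 = "K", r2 = "R", rho = 5,
                        noise_sd = 3, context_width = 3L,
                        seq_enrich = NULL) {
  stopifnot(delta >= 0, rho >= 1, noise_sd >= 0,
            r1 %in% PSSM_COLUMNS, r2 %in% PSSM_COLUMNS)
  if (is.null(seq_enrich)) seq_enrich <- if (delta > 0) 0.4 else 0
  structure(list(delta = delta, r1 = r1, r2 = r2, rho = rho,
                 noise_sd = noise_sd, context_width = as.integer(context_width),
                 seq_enrich = seq_enrich),
            class = "signal_spec")
}

#' Generate a background PSSM
#'
#' Integer log-odds scores drawn from a discretized normal (mean 0, sd
#' `noise_sd`), clipped to `clip`.
#'
#' @param L chain length.
#' @param seed RNG seed.
#' @param noise_sd background score standard deviation (default 3).
#' @param clip score clipping bounds (default c(-10, 10)).
#' @param sequence optional residue letters; random uniform when NULL.
#' @param chain_id id for the generated chain.
#' @return a `pssm` object.
#' @export
gen_pssm <- function(L, seed = 1L, noise_sd = 3, clip = c(-10, 10),
                     sequence = NULL, chain_id = "synth_A") {
  stopifnot(L >= 1)
  with_seed(seed, {
    scores <- matrix(as.integer(pmin(pmax(round(stats::rnorm(L * 20,
                                                             sd = noise_sd)),
                                          clip[1L]), clip[2L])),
                     L, 20L, dimnames = list(NULL, PSSM_COLUMNS))
    if (is.null(sequence))
      sequence <- paste(sample(PSSM_COLUMNS, L, replace = TRUE),
                        collapse = "")
    structure(list(chain_id = chain_id, scores = scores,
                   residue_column = strsplit(sequence, "")[[1]]),
              class = "pssm")
  })
}

#' Generate a labeled synthetic dataset
#'
#' Chains with random sequences and background PSSMs; each residue is
#' a binding residue with probability 1/(rho+1). At a binding position
#' i the raw score of column `r2` in row i and of column `r1` in the
#' context rows within `context_width` of i are shifted by `+delta`,
#' so the planted signal is carried by the (r1, r2) pair-relationship
#' features. Binding positions are additionally enriched for the
#' planted residue identities (see [signal_spec()]).
#'
#' @param n_chains number of chains (default 30).
#' @param length_range min/max chain length (default c(60, 120)).
#' @param spec a [signal_spec()].
#' @param seed master RNG seed.
#' @param clip final score clipping bounds (default c(-12, 12)).
#' @return list: `chains`, `pssms`, `labels` (named per-chain character
#'   vectors), `spec`, `seed`, `truth` (planted pair).
#' @export
gen_labeled_dataset <- function(n_chains = 30L, length_range = c(60L, 120L),
                                spec = signal_spec(), seed = 1L,
                                clip = c(-12, 12)) {
  stopifnot(inherits(spec, "signal_spec"))
  if (max(length_range) < 3L) stop("length range too small for any window")
  chains <- list(); pssms <- list(); labels <- list()
  r1i <- match(spec$r1, PSSM_COLUMNS)
  r2i <- match(spec$r2, PSSM_COLUMNS)
  with_seed(seed, {
    for (c_idx in seq_len(n_chains)) {
      id <- sprintf("synth_%03d", c_idx)
      len_choices <- seq.int(length_range[1L], length_range[2L])
      L <- len_choices[sample.int(length(len_choices), 1L)]
      seq_chars <- sample(PSSM_COLUMNS, L, replace = TRUE)
      bind <- stats::runif(L) < 1 / (spec$rho + 1)
      scores <- matrix(round(stats::rnorm(L * 20, sd = spec$noise_sd)),
                       L, 20L, dimnames = list(NULL, PSSM_COLUMNS))
      for (i in which(bind)) {
        scores[i, r2i] <- scores[i, r2i] + spec$delta
        ctx <- setdiff(max(1L, i - spec$context_width):
                         min(L, i + spec$context_width), i)
        scores[ctx, r1i] <- scores[ctx, r1i] + spec$delta
        if (spec$seq_enrich > 0) {
          if (stats::runif(1) < spec$seq_enrich) seq_chars[i] <- spec$r2
          enrich_ctx <- ctx[stats::runif(length(ctx)) < spec$seq_enrich / 2]
          seq_chars[enrich_ctx] <- spec$r1
        }
      }
      scores[] <- as.integer(pmin(pmax(scores, clip[1L]), clip[2L]))
      sequence <- paste(seq_chars, collapse = "")
      chains[[id]] <- protein_chain(id, sequence)
      pssms[[id]] <- structure(list(chain_id = id, scores = scores,
                                    residue_column = seq_chars),
                               class = "pssm")
      labels[[id]] <- ifelse(bind, "binding", "non-binding")
    }
  })
  list(chains = chains, pssms = pssms, labels = labels, spec = spec,
       seed = seed, truth = list(pair = c(r1 = spec$r1, r2 = spec$r2)))
}

AA1TO3 <- stats::setNames(names(AA3), unname(AA3))

#' Write a toy protein-DNA complex as a PDB file
#'
#' One protein chain (A) with a single CA atom per residue and one DNA
#' chain (B) with one phosphorus atom per requested residue, placed so
#' each residue's minimum distance to the DNA equals the requested
#' value (residues are spaced 8 Angstrom apart along x, the DNA atom
#' sits at the requested distance along z).
#'
#' @param geometry data frame with columns `residue` (one-letter amino
#'   acid) and `distance` (Angstrom >= 0).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
gen_toy_complex <- function(geometry, path) {
  stopifnot(is.data.frame(geometry),
            all(c("residue", "distance") %in% names(geometry)))
  if (any(geometry$distance < 0)) stop("distances must be >= 0")
  bad <- setdiff(geometry$residue, names(AA1TO3))
  if (length(bad) > 0L)
    stop("invalid residue code(s): ", paste(bad, collapse = ", "))
  spacing <- 8
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(geometry))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, AA1TO3[geometry$residue[i]], i, spacing * i, 0, 0))
  }
  for (i in seq_len(nrow(geometry))) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  P    DA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      serial, i, spacing * i, 0, geometry$distance[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Normalize a list of PSSMs (raw or already normalized)
#'
#' @param pssms named list of `pssm` or `normalized_pssm` objects.
#' @return named list of `normalized_pssm` objects.
#' @export
normalize_all <- function(pssms) {
  lapply(pssms, function(p)
    if (inherits(p, "normalized_pssm")) p else normalize_pssm(p))
}

#' Write dataset fixture files
#'
#' Writes FASTA, per-chain ASCII PSSM files, a labels TSV and a JSON
#' manifest recording the seed and the planted ground truth.
#'
#' @param dataset a [gen_labeled_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_fixtures <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(dataset$chains)
  fasta <- unlist(lapply(ids, function(id) {
    s <- dataset$chains[[id]]$sequence
    c(paste0(">", id),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(60L, nchar(s) + 59L, 60L), nchar(s))))
  }))
  writeLines(fasta, file.path(dir, "chains.fasta"))
  for (id in ids)
    write_pssm(dataset$pssms[[id]], file.path(dir, paste0(id, ".pssm")))
  lab <- do.call(rbind, lapply(ids, function(id)
    data.frame(chain_id = id,
               position = seq_along(dataset$labels[[id]]),
               label = dataset$labels[[id]], stringsAsFactors = FALSE)))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = dataset$seed,
                            spec = unclass(dataset$spec),
                            truth = dataset$truth),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
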