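# In-code fixtures shared across test files.

# residue instance with every window entry equal to `value`
uniform_instance <- function(w, value, chain_id = "fix_A") {
  structure(list(chain_id = chain_id, target_position = 1L, window_size = w,
                 window = matrix(value, w, 20L,
                                 dimnames = list(NULL, PSSM_COLUMNS)),
                 pad_mask = rep(FALSE, w), window_residues = NULL),
            class = "residue_instance")
}

# random instance via the real extraction path (seeded)
random_instance <- function(w, seed, L = 2L * w) {
  p <- gen_pssm(L, seed = seed)
  i <- pssmrt:::with_seed(seed + 1L, sample(seq_len(L), 1L))
  extract_window(normalize_pssm(p), i, w,
                 protein_chain(p$chain_id, paste(p$residue_column,
                                                 collapse = "")))
}

# serialize a score matrix as PSI-BLAST ASCII text
pssm_text <- function(scores, residues = rep("A", nrow(scores))) {
  p <- structure(list(chain_id = "txt_A", scores = scores,
                      residue_column = residues), class = "pssm")
  f <- tempfile(fileext = ".pssm")
  write_pssm(p, f)
  readLines(f)
}

# brute-force pair-relationship oracle: triple loop over (j, r1, r2)
pair_oracle <- function(inst) {
  w <- inst$window_size
  mid <- (w - 1L) %/% 2L + 1L
  out <- matrix(0, 20L, 20L, dimnames = list(PSSM_COLUMNS, PSSM_COLUMNS))
  for (j in setdiff(seq_len(w), mid))
    for (r1 in 1:20)
      for (r2 in 1:20)
        out[r1, r2] <- out[r1, r2] + inst$window[mid, r2] * inst$window[j, r1]
  as.vector(t(out))
}

# small planted-signal dataset for ensemble/workflow tests
small_dataset <- function(seed = 42L, n_chains = 10L, delta = 6) {
  gen_labeled_dataset(n_chains = n_chains, length_range = c(40L, 60L),
                      spec = signal_spec(delta = delta), seed = seed)
}

fast_config <- function(seed = 7L, window = 9L) {
  run_config(window = window, seed = seed, num_trees = 50L, cost_grid = 1)
}
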