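# PSI-BLAST ASCII PSSM parsing, logistic normalization, window extraction.

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the first (log-odds) 20-column block of the standard ASCII PSSM
#' layout emitted by `psiblast -out_ascii_pssm`. The second block
#' (weighted percentages) and the trailing information-content columns
#' are ignored. Data rows are recognized as lines starting with a
#' 1-based position index followed by a residue letter and at least 20
#' integers.
#'
#' @param lines character vector of file lines (or a single string with
#'   embedded newlines).
#' @param chain a [protein_chain()]; the parsed matrix must have exactly
#'   `chain$length` rows and matching residue letters ('X' in the chain
#'   matches any letter).
#' @param column_order override for the amino-acid column ordering of a
#'   non-standard dialect; default is the PSI-BLAST order
#'   [PSSM_COLUMNS]. Scores are re-ordered to [PSSM_COLUMNS] on return.
#' @return object of class `pssm`: list with `chain_id`, integer matrix
#'   `scores` (L x 20, columns [PSSM_COLUMNS]), `residue_column`.
#' @export
parse_pssm <- function(lines, chain, column_order = PSSM_COLUMNS) {
  stopifnot(inherits(chain, "protein_chain"))
  if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  if (!setequal(column_order, PSSM_COLUMNS) || length(column_order) != 20L)
    stop("column_order must be a permutation of the 20 standard amino acids")

  is_data <- grepl("^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d", lines)
  data_lines <- lines[is_data]
  if (length(data_lines) == 0L)
    stop("no PSSM data rows found for chain ", chain$chain_id)
  if (length(data_lines) != chain$length)
    stop(sprintf("PSSM row count (%d) != chain length (%d) for %s",
                 length(data_lines), chain$length, chain$chain_id))

  n <- length(data_lines)
  scores <- matrix(NA_integer_, n, 20L, dimnames = list(NULL, column_order))
  residue_column <- character(n)
  line_no <- which(is_data)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(data_lines[k]), "\\s+")[[1]]
    if (length(tok) < 22L)
      stop(sprintf("unparseable PSSM row at line %d (%d fields, need >= 22)",
                   line_no[k], length(tok)))
    pos <- suppressWarnings(as.integer(tok[1]))
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (is.na(pos) || anyNA(vals))
      stop(sprintf("unparseable PSSM row at line %d", line_no[k]))
    residue_column[k] <- toupper(tok[2])
    scores[k, ] <- vals
  }

  chain_res <- strsplit(chain$sequence, "", fixed = TRUE)[[1]]
  file_res <- canonicalize_sequence(paste(residue_column, collapse = ""))
  file_res <- strsplit(file_res, "", fixed = TRUE)[[1]]
  bad <- which(chain_res != file_res & chain_res != "X" & file_res != "X")
  if (length(bad) > 0L)
    stop(sprintf("residue mismatch between PSSM and chain %s at position(s) %s",
                 chain$chain_id, paste(utils::head(bad, 10L), collapse = ", ")))

  scores <- scores[, PSSM_COLUMNS, drop = FALSE]
  structure(list(chain_id = chain$chain_id, scores = scores,
                 residue_column = residue_column),
            class = "pssm")
}

#' Read a PSSM file for one chain
#'
#' @param path file in PSI-BLAST ASCII PSSM format (conventionally
#'   `<chain_id>.pssm`).
#' @inheritParams parse_pssm
#' @return a `pssm` object; see [parse_pssm()].
#' @export
read_pssm <- function(path, chain, column_order = PSSM_COLUMNS) {
  parse_pssm(readLines(path, warn = FALSE), chain, column_order)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Serializes the log-odds block in the standard layout (the percentage
#' block is written as zeros). [parse_pssm()] round-trips the score
#' matrix exactly.
#'
#' @param pssm a `pssm` object.
#' @param path output file.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste(" ", paste(sprintf("%3s", c(PSSM_COLUMNS, PSSM_COLUMNS)),
                            collapse = "")))
  rows <- vapply(seq_len(nrow(pssm$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, pssm$residue_column[i]),
           paste(sprintf("%3d", pssm$scores[i, ]), collapse = " "), " ",
           paste(sprintf("%3d", integer(20L)), collapse = " "),
           "  0.00 0.00")
  }, "")
  writeLines(c(hdr, rows, ""), path)
}

#' Logistic normalization of PSSM scores
#'
#' Maps each raw log-odds score S to 1 / (1 + exp(-S)), so scores lie in
#' (0, 1) with 0 mapping to exactly 0.5.
#'
#' @param pssm a `pssm` object.
#' @return object of class `normalized_pssm`: `chain_id` and numeric
#'   matrix `values` (same shape as the input scores).
#' @export
normalize_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  if (any(!is.finite(pssm$scores))) {
    bad <- which(!is.finite(pssm$scores), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite PSSM score at position %d, column %s",
                 bad[1L], PSSM_COLUMNS[bad[2L]]))
  }
  structure(list(chain_id = pssm$chain_id,
                 values = 1 / (1 + exp(-pssm$scores))),
            class = "normalized_pssm")
}

#' Extract a sliding-window residue instance
#'
#' Builds the w x 20 window of normalized scores centred on position
#' `i`. Window rows falling outside the chain are zero-filled and
#' flagged in `pad_mask`, so they contribute nothing to downstream
#' pair/multi-relationship sums.
#'
#' @param npssm a `normalized_pssm`.
#' @param i 1-based target position.
#' @param w odd window size >= 3.
#' @param chain optional [protein_chain()]; when given, the window
#'   residue letters are attached (needed for sequence and
#'   physicochemical encoding).
#' @return object of class `residue_instance`: `chain_id`,
#'   `target_position`, `window_size`, `window` (w x 20 matrix),
#'   `pad_mask` (logical w), and `window_residues` when `chain` given.
#' @export
extract_window <- function(npssm, i, w, chain = NULL) {
  stopifnot(inherits(npssm, "normalized_pssm"))
  L <- nrow(npssm$values)
  if (w %% 2L != 1L || w < 3L) stop("window size w must be odd and >= 3")
  if (i < 1L || i > L) stop(sprintf("position %d out of range [1, %d]", i, L))
  half <- (w - 1L) %/% 2L
  pos <- (i - half):(i + half)
  inside <- pos >= 1L & pos <= L
  window <- matrix(0, w, 20L, dimnames = list(NULL, PSSM_COLUMNS))
  window[inside, ] <- npssm$values[pos[inside], , drop = FALSE]
  res <- NULL
  if (!is.null(chain)) {
    stopifnot(inherits(chain, "protein_chain"))
    chars <- strsplit(chain$sequence, "", fixed = TRUE)[[1]]
    res <- rep(NA_character_, w)
    res[inside] <- chars[pos[inside]]
  }
  structure(list(chain_id = npssm$chain_id, target_position = i,
                 window_size = w, window = window, pad_mask = !inside,
                 window_residues = res),
            class = "residue_instance")
}
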