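# Feature encoding: PSSM-RT blocks (conservation, pair-relationships,
# multi-relationships), sequence features, physicochemical features.

#' Amino-acid physicochemical property table
#'
#' Eight properties per standard amino acid: amino-group pKa,
#' carboxyl-group pKa, electron-ion interaction potential, lone
#' electron-pair count, Wiener index of the side chain, molecular mass,
#' side-chain pKa and hydrophobicity index. The default table ships
#' with the package (`inst/extdata/aa_properties.tsv`) and can be
#' replaced by an edited copy.
#'
#' @param path optional TSV with columns `aa` plus the 8 property
#'   columns; default uses the shipped table.
#' @return object of class `property_table`: `raw` (20 x 8 matrix,
#'   rows [PSSM_COLUMNS]) and `scaled` (min-max scaled to \[0, 1\] per
#'   property over the 20 amino acids).
#' @export
aa_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_properties.tsv", package = "pssmrt",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(PSSM_COLUMNS, tab$aa)
  if (length(missing) > 0L)
    stop("property table lacks amino acid(s): ", paste(missing, collapse = ", "))
  raw <- as.matrix(tab[match(PSSM_COLUMNS, tab$aa), -1L, drop = FALSE])
  rownames(raw) <- PSSM_COLUMNS
  if (ncol(raw) != 8L) stop("property table must have exactly 8 properties")
  if (any(!is.finite(raw))) stop("property table contains non-finite values")
  rng <- apply(raw, 2L, range)
  scaled <- sweep(sweep(raw, 2L, rng[1L, ]), 2L, rng[2L, ] - rng[1L, ], "/")
  structure(list(raw = raw, scaled = scaled, range = rng),
            class = "property_table")
}

half_width <- function(inst) (inst$window_size - 1L) %/% 2L

window_offsets <- function(w) seq.int(-(w - 1L) %/% 2L, (w - 1L) %/% 2L)

#' Conservation block
#'
#' Row-major flattening of the w x 20 window of logistic-normalized
#' scores, window order preserved (leftmost position first). Length
#' 20 * w; padded rows contribute zeros.
#'
#' @param inst a `residue_instance` from [extract_window()].
#' @return named numeric vector of length `20 * w`.
#' @export
encode_conservation <- function(inst) {
  stopifnot(inherits(inst, "residue_instance"))
  v <- as.vector(t(inst$window))
  names(v) <- paste0("cons_", rep(window_offsets(inst$window_size), each = 20L),
                     "_", rep(PSSM_COLUMNS, inst$window_size))
  v
}

#' Pair-relationship block
#'
#' For each ordered amino-acid pair (r1, r2), the sum over all context
#' positions j of `S^N[i, r2] * S^N[j, r1]`, where i is the target
#' position — the pairwise product of the target's normalized score for
#' r2 with the context's score for r1, accumulated over the whole
#' window context. 400 entries, row-major with r1 as the outer index
#' over [PSSM_COLUMNS]. Padded context rows contribute zero.
#'
#' @param inst a `residue_instance`.
#' @return named numeric vector of length 400 (`pair_<r1>_<r2>`).
#' @export
encode_pair_relationships <- function(inst) {
  stopifnot(inherits(inst, "residue_instance"))
  mid <- half_width(inst) + 1L
  target <- inst$window[mid, ]
  ctx_sum <- colSums(inst$window[-mid, , drop = FALSE])
  v <- as.vector(t(outer(ctx_sum, target)))  # [r1, r2] row-major
  names(v) <- paste0("pair_", rep(PSSM_COLUMNS, each = 20L), "_",
                     rep(PSSM_COLUMNS, 20L))
  v
}

#' Multi-relationship blocks
#'
#' Cumulative normalized scores over the left half-window (left context
#' plus target, 20 values) and the right half-window (target plus right
#' context, 20 values). Padded rows contribute zero.
#'
#' @param inst a `residue_instance`.
#' @return list with named numeric vectors `left` (`mleft_<r>`) and
#'   `right` (`mright_<r>`), each of length 20.
#' @export
encode_multi_relationships <- function(inst) {
  stopifnot(inherits(inst, "residue_instance"))
  mid <- half_width(inst) + 1L
  left <- colSums(inst$window[1:mid, , drop = FALSE])
  right <- colSums(inst$window[mid:inst$window_size, , drop = FALSE])
  names(left) <- paste0("mleft_", PSSM_COLUMNS)
  names(right) <- paste0("mright_", PSSM_COLUMNS)
  list(left = left, right = right)
}

#' Assemble the PSSM-RT feature vector
#'
#' Concatenates conservation | pair | multi_left | multi_right; total
#' length `20*w + 400 + 40`.
#'
#' @param inst a `residue_instance`.
#' @return named numeric vector with a `schema` attribute (data frame
#'   of block names, offsets and lengths).
#' @export
assemble_pssm_rt <- function(inst) {
  cons <- encode_conservation(inst)
  pair <- encode_pair_relationships(inst)
  multi <- encode_multi_relationships(inst)
  v <- c(cons, pair, multi$left, multi$right)
  attr(v, "schema") <- block_schema(c(conservation = length(cons), pair = 400L,
                                      multi_left = 20L, multi_right = 20L))
  v
}

block_schema <- function(lengths) {
  data.frame(block = names(lengths), length = as.integer(lengths),
             start = cumsum(c(1L, unname(utils::head(lengths, -1L)))),
             stringsAsFactors = FALSE)
}

#' Sequence feature block
#'
#' Window amino-acid composition (20 frequencies over non-padded
#' positions; 'X' counts toward no letter), per-position 3-state
#' secondary-structure one-hot (3w, order H/E/C), per-position
#' predicted relative solvent accessibility (w), and the target-residue
#' identity one-hot (20). Missing prediction tracks emit zeros with a
#' warning.
#'
#' @param inst a `residue_instance` carrying `window_residues`.
#' @param ss optional per-chain secondary-structure states, character
#'   vector of length L over H/E/C (e.g. from [read_ss2()]).
#' @param acc optional per-chain relative accessibility, numeric length
#'   L in \[0, 1\] (e.g. from [read_sable()]).
#' @param chain_length chain length used to validate track lengths;
#'   required when `ss` or `acc` given.
#' @param warn warn when a track is missing (default TRUE).
#' @return named numeric vector of length `20 + 3w + w + 20`.
#' @export
encode_sequence_features <- function(inst, ss = NULL, acc = NULL,
                                     chain_length = NULL, warn = TRUE) {
  stopifnot(inherits(inst, "residue_instance"))
  if (is.null(inst$window_residues))
    stop("instance lacks window residues; extract_window() needs `chain`")
  w <- inst$window_size
  off <- window_offsets(w)
  pos <- inst$target_position + off
  res <- inst$window_residues

  comp <- vapply(PSSM_COLUMNS, function(a) sum(res == a, na.rm = TRUE), 0)
  comp <- comp / sum(!inst$pad_mask)
  names(comp) <- paste0("comp_", PSSM_COLUMNS)

  ss_block <- numeric(3L * w)
  names(ss_block) <- paste0("ss_", rep(off, each = 3L), "_",
                            rep(c("H", "E", "C"), w))
  if (is.null(ss)) {
    if (warn) warning("no secondary-structure track; ss sub-block set to zero")
  } else {
    if (!is.null(chain_length) && length(ss) != chain_length)
      stop("secondary-structure track length != chain length")
    for (k in seq_len(w)) {
      if (inst$pad_mask[k]) next
      s <- match(ss[pos[k]], c("H", "E", "C"))
      if (!is.na(s)) ss_block[3L * (k - 1L) + s] <- 1
    }
  }

  acc_block <- numeric(w)
  names(acc_block) <- paste0("acc_", off)
  if (is.null(acc)) {
    if (warn) warning("no accessibility track; acc sub-block set to zero")
  } else {
    if (!is.null(chain_length) && length(acc) != chain_length)
      stop("accessibility track length != chain length")
    inside <- !inst$pad_mask
    acc_block[inside] <- acc[pos[inside]]
  }

  ident <- numeric(20L)
  names(ident) <- paste0("id_", PSSM_COLUMNS)
  t_idx <- match(res[half_width(inst) + 1L], PSSM_COLUMNS)
  if (!is.na(t_idx)) ident[t_idx] <- 1  # 'X' targets stay all-zero

  c(comp, ss_block, acc_block, ident)
}

#' Physicochemical feature block
#'
#' Eight min-max-scaled property values per window position (8w total);
#' padded positions and 'X' residues emit zeros.
#'
#' @param inst a `residue_instance` carrying `window_residues`.
#' @param table a [aa_property_table()]; default table used when NULL.
#' @return named numeric vector of length `8 * w`.
#' @export
encode_physicochemical <- function(inst, table = NULL) {
  stopifnot(inherits(inst, "residue_instance"))
  if (is.null(inst$window_residues))
    stop("instance lacks window residues; extract_window() needs `chain`")
  if (is.null(table)) table <- aa_property_table()
  stopifnot(inherits(table, "property_table"))
  w <- inst$window_size
  props <- colnames(table$scaled)
  out <- numeric(8L * w)
  names(out) <- paste0("pc_", rep(window_offsets(w), each = 8L), "_",
                       rep(props, w))
  for (k in seq_len(w)) {
    a <- inst$window_residues[k]
    if (inst$pad_mask[k] || is.na(a) || a == "X") next
    out[(8L * (k - 1L) + 1L):(8L * k)] <- table$scaled[a, ]
  }
  out
}

#' Encode one residue instance into feature blocks
#'
#' @param inst a `residue_instance` (with window residues for the
#'   sequence/physicochemical blocks).
#' @param blocks feature blocks to compute, subset of
#'   `c("pssm_rt", "sequence", "physicochemical")`.
#' @param ss,acc optional per-chain prediction tracks, see
#'   [encode_sequence_features()].
#' @param table optional [aa_property_table()].
#' @param chain_length chain length for track validation.
#' @param warn warn on missing tracks.
#' @return named list of named numeric vectors, one per block.
#' @export
encode_instance <- function(inst,
                            blocks = c("pssm_rt", "sequence", "physicochemical"),
                            ss = NULL, acc = NULL, table = NULL,
                            chain_length = NULL, warn = FALSE) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  out <- list()
  if ("pssm_rt" %in% blocks) out$pssm_rt <- assemble_pssm_rt(inst)
  if ("sequence" %in% blocks)
    out$sequence <- encode_sequence_features(inst, ss, acc, chain_length, warn)
  if ("physicochemical" %in% blocks)
    out$physicochemical <- encode_physicochemical(inst, table)
  out
}

#' Encode every residue of a set of chains
#'
#' Builds the per-residue feature matrices for all requested blocks.
#'
#' @param chains named list of [protein_chain()] objects.
#' @param npssms named list of `normalized_pssm` objects (same names).
#' @param w odd window size (default 13).
#' @param blocks which feature blocks to compute.
#' @param ss_tracks,acc_tracks optional named lists of per-chain
#'   prediction tracks.
#' @param table optional [aa_property_table()].
#' @return list with `meta` (data frame: chain_id, position, residue)
#'   and one numeric matrix per block (rows aligned with `meta`).
#' @export
encode_chains <- function(chains, npssms, w = 13L,
                          blocks = c("pssm_rt", "sequence", "physicochemical"),
                          ss_tracks = NULL, acc_tracks = NULL, table = NULL) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (is.null(table) && "physicochemical" %in% blocks)
    table <- aa_property_table()
  metas <- list(); rows <- stats::setNames(vector("list", length(blocks)), blocks)
  for (b in blocks) rows[[b]] <- list()
  for (id in names(chains)) {
    chain <- chains[[id]]
    npssm <- npssms[[id]]
    if (is.null(npssm)) stop("no PSSM for chain ", id)
    ss <- if (!is.null(ss_tracks)) ss_tracks[[id]] else NULL
    acc <- if (!is.null(acc_tracks)) acc_tracks[[id]] else NULL
    chars <- strsplit(chain$sequence, "", fixed = TRUE)[[1]]
    for (i in seq_len(chain$length)) {
      inst <- extract_window(npssm, i, w, chain)
      enc <- encode_instance(inst, blocks, ss, acc, table,
                             chain_length = chain$length, warn = FALSE)
      for (b in blocks) rows[[b]][[length(rows[[b]]) + 1L]] <- enc[[b]]
    }
    metas[[id]] <- data.frame(chain_id = id, position = seq_len(chain$length),
                              residue = chars, stringsAsFactors = FALSE)
  }
  out <- list(meta = do.call(rbind, c(metas, list(make.row.names = FALSE))))
  for (b in blocks) out[[b]] <- do.call(rbind, rows[[b]])
  out
}

#' Write a feature matrix as TSV
#'
#' One row per residue instance with `chain_id` and `position` columns
#' followed by the named feature slots.
#'
#' @param encoded result of [encode_chains()].
#' @param block which block to write.
#' @param path output TSV path.
#' @export
write_feature_tsv <- function(encoded, block, path) {
  m <- encoded[[block]]
  if (is.null(m)) stop("block not present: ", block)
  utils::write.table(cbind(encoded$meta[, c("chain_id", "position")],
                           as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a PSIPRED .ss2 secondary-structure prediction
#'
#' @param path PSIPRED vertical-format file: data rows `pos res state
#'   pC pH pE`.
#' @return list with `states` (character, H/E/C per position) and
#'   `probs` (L x 3 matrix, columns C/H/E).
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- grep("^\\s*\\d+\\s+[A-Za-z]\\s+[HEC]", lines, value = TRUE)
  if (length(data) == 0L) stop("no prediction rows found in ", path)
  tok <- strsplit(trimws(data), "\\s+")
  states <- vapply(tok, `[`, "", 3L)
  probs <- t(vapply(tok, function(x) as.numeric(x[4:6]), numeric(3L)))
  colnames(probs) <- c("C", "H", "E")
  list(states = states, probs = probs)
}

#' Read a solvent-accessibility prediction track
#'
#' Accepts either a two-column table (position, value) or a SABLE-style
#' digit string (one 0-9 digit per residue on lines following an "ACC"
#' header, scaled to \[0, 1\] by /9).
#'
#' @param path prediction file.
#' @return numeric vector of per-position relative accessibility in
#'   \[0, 1\].
#' @export
read_sable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tab <- grep("^\\s*\\d+\\s+-?[0-9.]+\\s*$", lines, value = TRUE)
  if (length(tab) > 0L) {
    tok <- strsplit(trimws(tab), "\\s+")
    vals <- vapply(tok, function(x) as.numeric(x[2L]), 0)
    if (max(vals) > 1) vals <- vals / 100  # percent RSA
    return(vals)
  }
  acc_at <- grep("^ACC", lines)
  if (length(acc_at) > 0L) {
    digits <- paste(gsub("[^0-9]", "", lines[acc_at + 1L]), collapse = "")
    return(as.numeric(strsplit(digits, "")[[1]]) / 9)
  }
  stop("unrecognized accessibility file layout: ", path)
}
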