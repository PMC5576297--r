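# Binding-residue labels from protein-DNA complex structures.

DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Read a protein-DNA complex structure
#'
#' Parses a PDB file and splits atoms into protein and nucleic-acid
#' chains by residue vocabulary (20 standard amino acids vs
#' DA/DC/DG/DT/DU and ribonucleotide variants). For atoms with
#' alternate locations, the highest-occupancy altloc is kept.
#' Hydrogens, when present, are retained.
#'
#' @param path PDB file.
#' @return object of class `complex_structure`: `protein` and `dna`
#'   data frames (chain, resno, resid, elety, x, y, z) plus `pdb_id`.
#' @export
read_complex <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # keep the highest-occupancy altloc per (chain, resno, atom name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    at <- at[order(-occ), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$chain, at$resno), , drop = FALSE]
  }
  cols <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  is_dna <- at$resid %in% DNA_RESIDUES
  is_prot <- at$resid %in% names(AA3)
  structure(list(protein = at[is_prot, cols, drop = FALSE],
                 dna = at[is_dna, cols, drop = FALSE],
                 pdb_id = basename(path)),
            class = "complex_structure")
}

#' Minimum atom-pair distance between two coordinate sets
#'
#' @param residue_atoms,dna_atoms numeric matrices with columns x, y, z
#'   (Angstrom).
#' @return smallest Euclidean distance over all atom pairs (Angstrom).
#' @export
min_distance_to_dna <- function(residue_atoms, dna_atoms) {
  residue_atoms <- as.matrix(residue_atoms)
  dna_atoms <- as.matrix(dna_atoms)
  if (nrow(residue_atoms) == 0L || nrow(dna_atoms) == 0L)
    stop("empty atom set")
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  aa <- rowSums(residue_atoms^2)
  bb <- rowSums(dna_atoms^2)
  d2 <- outer(aa, bb, "+") - 2 * residue_atoms %*% t(dna_atoms)
  sqrt(max(0, min(d2)))
}

#' Label residues of a protein-DNA complex
#'
#' A residue is a binding residue when any of its atoms (side chain or
#' backbone) lies within `cutoff` Angstrom (inclusive) of any atom of
#' any DNA chain in the complex.
#'
#' @param cx a `complex_structure` from [read_complex()].
#' @param cutoff distance cutoff in Angstrom (default 3.5).
#' @return data frame: `chain`, `position` (1-based rank of the residue
#'   within its chain), `resno` (author residue number), `residue`
#'   (one-letter code), `label` (`"binding"`/`"non-binding"`),
#'   `min_distance`.
#' @export
label_residues <- function(cx, cutoff = 3.5) {
  stopifnot(inherits(cx, "complex_structure"))
  if (nrow(cx$dna) == 0L) stop("no DNA chain detected in complex")
  if (nrow(cx$protein) == 0L) stop("no protein chain detected in complex")
  dna_xyz <- as.matrix(cx$dna[, c("x", "y", "z")])
  out <- list()
  for (ch in unique(cx$protein$chain)) {
    atoms <- cx$protein[cx$protein$chain == ch, , drop = FALSE]
    resnos <- unique(atoms$resno)
    md <- vapply(resnos, function(rn) {
      min_distance_to_dna(atoms[atoms$resno == rn, c("x", "y", "z")], dna_xyz)
    }, 0)
    res1 <- unname(AA3[atoms$resid[match(resnos, atoms$resno)]])
    out[[ch]] <- data.frame(chain = ch, position = seq_along(resnos),
                            resno = resnos, residue = res1,
                            label = ifelse(md <= cutoff, "binding",
                                           "non-binding"),
                            min_distance = md, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write residue labels as TSV
#'
#' @param labels data frame from [label_residues()].
#' @param path output TSV path.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
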