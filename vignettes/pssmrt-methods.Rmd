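---
title: "Predicting DNA-binding residues with PSSM relation transformation ensembles"
author: "pssmrt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding residues with PSSM relation transformation ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmrt)
```

## The problem

Protein–DNA recognition is mediated by a small fraction of a protein's
residues. Identifying those interface residues from sequence alone —
without a solved complex structure — is a long-standing problem in
structural bioinformatics, because structures are available for only a
minority of DNA-binding proteins. The standard ground truth comes from
solved protein–DNA complexes: a residue is a *binding residue* when any
of its atoms (backbone or side chain) lies within 3.5 Å of any atom of
the partner DNA. This package implements a sequence-based predictor of
that label, an evaluation protocol around it, and the feature analysis
that makes the learned model interpretable.

Two features of the problem shape the whole design:

1. **Evolutionary signal is relational.** The conservation profile of a
   residue (a row of its PSSM) is informative, but so is the *joint*
   conservation of the residue and its sequence neighbours: interfaces
   are built from co-occurring residue types (arginine/lysine-rich
   patches contacting the phosphate backbone, serine/glutamine hydrogen
   bonding). Encodings that concatenate per-position scores discard
   this pairing.
2. **Severe class imbalance.** Non-binding residues outnumber binding
   residues roughly 5:1 to 14:1 in curated complex datasets. A
   classifier trained naively maximizes accuracy by predicting
   "non-binding" everywhere; a classifier trained on a subsampled
   balanced set throws away most of the majority class.

## The PSSM-RT encoding

Input per chain is an L×20 PSSM of integer log-odds scores
$S_{i,r}$ (PSI-BLAST ASCII output; here produced externally, typically
from 3 iterations against NR at E ≤ 0.001). Scores are mapped to (0, 1)
by the logistic function

$$S^{(N)}_{i,r} = \frac{1}{1 + e^{-S_{i,r}}},$$

so a score of 0 (no information) maps to exactly 0.5. A residue-wise
instance is the odd-width window of w rows centred on the target
position i; the (w−1)/2 rows on either side are its context.

Three feature groups are derived from the normalized window:

* **Conservation** (20w values): the flattened window itself.
* **Pair-relationships** (400 values): for each ordered amino-acid pair
  (r1, r2),
  $\mathrm{RT}(i, r_1, r_2) = \sum_{j \ne i} S^{(N)}_{i,r_2}\,S^{(N)}_{j,r_1}$,
  the product of the target's preference for r2 with the context's
  preference for r1, summed over all context positions j in the
  window. This is the package's core quantity: it is nonzero exactly
  when the target and its context are *jointly* conserved for the pair.
* **Multi-relationships** (20 + 20 values): cumulative normalized
  scores over the left half-window ($\sum_{k=i-(w-1)/2}^{i}$) and the
  right half-window ($\sum_{k=i}^{i+(w-1)/2}$), both including the
  target row.

Total PSSM-RT dimension: 20w + 400 + 40 (700 at the default w = 13).
Two auxiliary blocks complete the instance: *sequence features* (window
amino-acid composition, per-position 3-state secondary-structure
one-hots, per-position predicted relative solvent accessibility, target
identity one-hot) and *physicochemical features* (8 properties per
window position, min–max scaled over the 20 amino acids: amino- and
carboxyl-group pKa, electron–ion interaction potential, lone
electron-pair count, side-chain Wiener index, molecular mass,
side-chain pKa, Kyte–Doolittle hydrophobicity). Secondary-structure and
accessibility tracks are consumed from PSIPRED `.ss2` and SABLE-style
files when available and are zero-filled (with a warning) otherwise.

### Conventions the literature leaves open

* **Index pairing in the pair-relationship product.** The defining
  product is implemented with the target position indexed by r2 and the
  context position by r1, exactly as the formula above; the opposite
  pairing produces the same 400-set up to transposition of the 20×20
  grid. The choice is fixed and documented so that discriminant-weight
  grids are interpretable.
* **Ordering.** Pair features are laid out row-major with r1 (context
  residue) as the outer index over the fixed PSI-BLAST column order
  `A R N D C Q E G H I L K M F P S T W Y V`.
* **Terminal padding.** Windows overrunning a chain terminus are
  zero-filled and flagged. Padding with 0 rather than 0.5 (the logistic
  image of "no information") means padded positions contribute nothing
  to pair/multi sums — the alternative would fabricate conservation
  signal at chain ends. Padded cells are the one place the encoding
  leaves the open interval (0, 1).
* **Non-standard residues** (B, Z, U, …) are mapped to 'X': they keep
  their PSSM rows (window geometry is preserved) but contribute nothing
  to identity one-hots, composition or physicochemical values.
* **Conservation block scale.** The conservation block uses the
  normalized scores, not raw log-odds, for consistency with the other
  blocks and to keep every feature bounded.

## The imbalance-aware ensemble

Training follows four steps:

1. **Balanced partition.** The non-binding instances are shuffled
   (seeded) and split into n = max(1, round(|neg|/|pos|)) disjoint
   subsets of near-equal size; each subset is paired with *all* binding
   instances. Every negative is used exactly once across the ensemble;
   no data are discarded.
2. **Encoding.** All instances are encoded in the three feature blocks.
3. **Base predictors.** On each balanced set, one RBF-kernel SVM and
   one random forest are trained per feature block: 6n predictors.
   SVM cost/width can be grid-searched by internal cross-validation on
   the balanced set; forests are seeded, single-threaded, and sized
   with an odd tree count so binary tree votes cannot tie.
4. **Diversity selection and vote.** On a held-out chain-level
   validation split (10% of training chains), the pool is pruned by
   dynamic ranking: start from one seeded-random predictor, repeatedly
   add the unselected predictor with the largest mean disagreement rate
   against the current members (ties by predictor id), and stop when
   that best gain falls below ε (default 0.01). The final predictor is
   a simple majority vote; the reported score is the binding vote
   fraction, which also serves as the ROC score. Exact vote ties
   resolve to binding, favouring the rare class.

Two details deserve their rationale:

* **Stopping rule.** The gain of a candidate is its mean diversity
  against the already-selected members — equivalently, the increase in
  the selected set's total pairwise diversity divided by the number of
  newly created pairs. An alternative reading (change in the *mean*
  pairwise diversity of the set) degenerates in practice: because the
  second member is chosen to maximize the pairwise mean, no later
  addition can raise it appreciably, and selection always terminates at
  two members, which defeats majority voting. Under the rule used here,
  selection keeps admitting predictors until every remaining one is an
  ε-near clone of the committee; with heterogeneous pools this retains
  most of the 6n predictors, which is consistent with the design goal
  of using all the data.
* **Vote-tie direction.** Binding residues are the rare class and the
  headline metric (ST, the mean of sensitivity and specificity) is
  symmetric, so resolving ties toward binding buys sensitivity at a
  smaller specificity cost. The rule is configurable in spirit: users
  can threshold the returned score themselves.

The default SVM grid is C ∈ {1, 10} at the 1/d kernel width, selected
by 3-fold internal cross-validation on each balanced set
(`run_config(cost_grid=, gamma_grid=, svm_folds=)` to change). Two
cautions: the internal CV splits residues, not chains, within a
balanced set, and neighbouring residues share most of their window, so
very aggressive grids can reward within-chain memorization; and the
grid multiplies training cost by roughly the number of combinations
times the fold count. The shipped tests and the acceptance script
therefore run the single-point C = 1 configuration, which keeps a full
train/predict cycle at tens of seconds at the problem sizes below.

## Labels from complex structures

`read_complex()` splits a PDB file into protein and nucleic chains by
residue vocabulary (20 amino acids vs DA/DC/DG/DT/DU and ribonucleotide
variants), keeps the highest-occupancy alternate location per atom, and
retains hydrogens if present. `label_residues()` computes each protein
residue's minimum atom-pair distance to the union of all DNA atoms in
the complex and labels it binding when that distance is ≤ the cutoff
(3.5 Å default, boundary inclusive, matching the usual "falls within"
phrasing). Hetero and modified residues are skipped: they have no PSSM
row. Taking the union of all DNA chains (rather than one annotated
partner) is the conservative reading when the complex contains a DNA
duplex.

## Evaluation protocol

Confusion-derived metrics are SN = TP/(TP+FN), SP = TN/(TN+FP),
ST = (SN+SP)/2, ACC, and
MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)). A metric whose
denominator vanishes is reported as `NA` with a warning — never
silently as 0. ROC curves sweep every distinct score threshold and AUC
is the trapezoidal integral, which equals the probability that a random
positive outscores a random negative with ties counting one half
(asserted against the rank formulation to 1e−12 in the tests, and
cross-checked against pROC). AUC lives in [0, 1]; 0.5 is chance.

Cross-validation is **chain-level**: all residues of a chain stay in
one fold. Residue-level splitting would place near-identical
overlapping windows on both sides of the split and inflate every
metric. Pooled metrics are computed from confusion counts summed across
folds (micro-averaging); per-fold values are retained for paired
method comparisons with the exact two-sided Wilcoxon signed-rank test.
The window-size sweep trains a balanced single SVM on the PSSM-RT block
per candidate w on a seeded chain-level holdout and reports ST per w,
preferring the smaller window on ties; on real benchmark profiles this
kind of sweep peaks at w = 13, which is the package default.

## Discriminant-weight feature analysis

For interpretability the package computes the discriminant weight
vector **W** = **A**ᵀ·**M**, where **M** is the n×d training feature
matrix and **A** assigns each training instance a signed weight. The
ensemble is not a single linear model, so **A** must be extracted by a
declared strategy; the default (`svm_dual`) sums, over the selected SVM
base predictors, each support vector's signed dual coefficient (α·y,
oriented toward the binding class — note e1071 orients its decision
value toward the class seen *first in the training data*, not the first
factor level). Instances that are never support vectors, or never
appear in a selected predictor's balanced set, get weight 0. The 400
pair-relationship slots of **W** are then ranked (signed weight
descending, ties lexicographic; absolute-value ranking available) and
exported as a 20×20 grid for heat maps. On real interface data this
ranking recovers the lysine/arginine/serine/glutamine pairs known to
dominate protein–DNA contacts.

## Synthetic data: what it emulates and what it does not

All tests run without downloads on generated data
(`gen_labeled_dataset()`):

* background PSSM scores are discretized normal (mean 0, sd 3, clipped
  to ±10 before shifting, ±12 after), roughly matching the dynamic
  range of real log-odds profiles;
* each residue is binding with probability 1/(ρ+1), ρ = 5 by default —
  the optimistic end of the 5–14 range seen in curated complex
  datasets;
* at a binding position the target row's score for one amino acid (R by
  default) and the context rows' scores for another (K) within ±3
  positions are shifted by +δ (δ = 6 by default), so the signal is
  carried primarily by one planted pair-relationship;
* binding positions are also compositionally enriched for the planted
  residue types (probability 0.4 of forcing the target letter, half
  that for context letters), mimicking the K/R/S enrichment of real
  interfaces that gives sequence and physicochemical features their
  power; a δ = 0 dataset has no enrichment and is fully null.

The generator is seed-deterministic (regenerated fixture files are
byte-identical) and writes standard formats (FASTA, ASCII PSSM, TSV,
JSON manifest), so the whole pipeline including parsers is exercised.
`gen_toy_complex()` writes minimal PDB complexes realizing requested
residue-to-DNA distances for testing the labeling geometry.

What passing tests on these data show: the encoders compute the defined
quantities exactly; the ensemble machinery turns a planted relational
signal into held-out AUC ≈ 0.9+ at δ = 6 and stays at chance for δ = 0;
the analysis recovers the planted pair near the top of 400. What they
do not show: performance on real NR-scale profiles, where conservation
is phylogenetically structured, labels are spatially clustered along
the chain, and prediction tracks are informative — reproducing
published benchmark numbers requires externally computed PSI-BLAST,
PSIPRED and SABLE outputs for hundreds of chains and is out of scope.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use ~30 chains of 80–120
residues (~3000 instances) for ensemble-level checks and 8–14 chains
for workflow-level checks; at these sizes a full train/predict cycle
takes tens of seconds on one core. Tolerances: encoder oracle
equivalence at 1e−9, AUC formulation equivalence at 1e−12, toy-complex
distances at 1e−3 Å (PDB coordinates have three decimals). Degenerate
inputs are defined, not rejected: a length-1 chain yields a fully
padded context and an all-zero pair block; an all-identical predictor
pool selects exactly one member; undefined metrics are `NA`.

## Known limitations

* The per-instance weight extraction for Eq.-style discriminant
  analysis is only defined when the selected ensemble contains at least
  one SVM; a forest-only ensemble needs a different (pluggable)
  strategy.
* Vote fractions are coarse scores (granularity 1/m for m selected
  predictors); no probability calibration is attempted.
* mmCIF input, checkpoint-format PSSMs and profile HMMs are not
  supported; CD-HIT-style redundancy reduction of training chains is
  the user's responsibility.
* The n = round(|neg|/|pos|) rule keeps balanced sets near 1:1; with
  extreme imbalance (ρ ≫ 14) the pool grows linearly and training cost
  with it.
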