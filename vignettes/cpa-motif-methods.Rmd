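---
title: "Methods: specificity-determining motif discovery and classification for cation/proton antiporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specificity-determining motif discovery and classification for cation/proton antiporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpamotif)
```

## The scientific problem

Cation/proton antiporters (CPAs) exchange Na\(^+\) or K\(^+\) for one or two
protons across membranes and fall into two phylogenetic subtrees, CPA1 and
CPA2. Two phenotypes organize the superfamily: *electrogenicity* (one cation
for two protons, moving net charge) versus electroneutrality, and *ion
selectivity* (Na\(^+\) vs K\(^+\)). Despite large sequence divergence, a
small set of eight conserved, spatially clustered residues — four on the
unwound section of TM-4, three on TM-5 and one on TM-10, written

\[ X_1X_2X_3X_4 \;\dots\; [E/\text{-}]_5\,\text{-}\,\text{-}\,\text{-}\,X_6D_7 \;\dots\; [R/K]_8 \]

in EcNhaA numbering (A131, T132, D133, I134, L159, D163, D164, K300) —
separates the clades and predicts both phenotypes. An auxiliary TM-3
position (P108 in EcNhaA; a uniquely conserved glutamate in mammalian
NHA-like CPA2s) refines the electrogenicity call. `cpamotif` implements the
full desk-scale analysis chain that supports this motif: family simulation
with planted motif states, sequence filters, profile-HMM alignment,
neighbor-joining trees with bootstrap supports and phylogenetic-diversity
subsetting, tree-aware conservation scoring, mutual-information discovery
of discriminating columns, the residue-rule classifier, and structural
distance checks.

## Decision rules

* **Family.** CPA1 requires the full fingerprint: glutamate at motif
  position 5 *and* arginine at position 8 (these two positions salt-bridge
  across TM-5/TM-10 in CPA1 structures). A non-E position 5 with any
  non-gap residue other than R at position 8 is CPA2. A partial signature
  (exactly one of the two) or a gap in positions 5–8 yields `ambiguous`
  rather than a guess: the cost of a wrong family call propagates into the
  electrogenicity call, so the rule is deliberately conservative.
* **Electrogenicity.** All CPA1s are electroneutral. A CPA2 is called
  electrogenic iff position 8 is lysine and position 6 is acidic (D or E):
  two binding-site carboxylates plus the TM-10 lysine are needed to carry
  a second proton. The mammalian-NHA-like pattern — acidic 6, D7, R8 and
  the TM-3 glutamate — is called electroneutral with the `NHA_LIKE_E_TM3`
  flag *before* the family gate, because such sequences carry a partial
  CPA1 signature (R8 without E5) and would otherwise fall through as
  `unknown`. A non-acidic position 7 flags likely transport deficiency
  (`POS7_NOT_ACIDIC`) but does not change the call. Engineered exceptions
  (e.g. K-to-R or K-to-H substitutions at position 8 that retain
  electrogenicity in vitro) are out of model and surface only as flags.
* **Selectivity.** Serine or threonine at position 1 or 4 calls K\(^+\)
  (the extra hydroxyl supplies the larger coordination shell potassium
  needs); nonpolar residues at both positions call Na\(^+\); anything else
  is `unknown`. Positions 2–3 are annotation only and influence no call.

The packaged clade reference ships consensus motifs for the 6 CPA1 and 9
CPA2 clades with a provenance tag per record: `text-derived` consensus
motifs are fully supported by described clade motifs (P1T2D3P4, S1T2D3A4,
A1T2D3I4, L1S2S3T4 plus the position 5–8 signatures); `partial-text`
records have the mechanistically load-bearing positions supported and the
remainder filled in; `synthetic` records are stand-ins constructed to be
consistent with each clade's known family, electrogenicity and selectivity
(the per-clade figure legends are not machine-readable in this build).
Nearest-clade assignment is Hamming distance over the 8 consensus states
with an explicit margin and a lexicographic tie-break (`AMBIGUOUS_CLADE`).

## The synthetic family generator

The generator is first-class, tested code: it produces the study
conditions under which every downstream stage is validated.

* **Tree.** Yule (pure-birth) topology; a uniformly chosen extant leaf is
  split until `n_leaves` is reached. Branch lengths are i.i.d. exponential
  with mean 0.1 substitutions/site — a generative stand-in chosen for
  simplicity, since any clade-structured tree suffices for the tests.
* **Clades.** A partition into monophyletic groups obtained by repeatedly
  splitting a leaf-count-weighted random part at its root node; every
  clade is therefore exactly the leaf set under one internal edge.
* **Sequences.** The root sequence is drawn from the LG equilibrium
  frequencies and evolved along the tree under the LG model (taken from
  `phangorn` at run time) with per-site gamma rates (shape
  `gamma_alpha`, discretized to 16 equal-mass categories for speed).
* **Planting.** The 8 motif columns plus the auxiliary column are then
  overwritten with each leaf's clade states; each cell is independently
  replaced by a uniformly random residue with probability
  `motif_noise_eps`. Default columns follow the EcNhaA layout
  (131–134, 159, 163, 164, 300; aux 108) so synthetic coordinates read
  like the reference transporter; for alignments shorter than 320 columns
  the layout is rescaled proportionally.
* **Indels.** Deletions only: geometric-length runs (mean
  `indel_mean_len`) started with probability `indel_rate` per non-motif
  column. Modeling insertions would add all-gap columns and shift the true
  motif coordinates without adding testable signal, so the true alignment
  always has exactly `seq_length` columns and column-level truth is
  preserved. Degapping any alignment row reproduces that leaf's unaligned
  sequence exactly.
* **Truth.** Phenotypes in the truth table are derived from each clade's
  *noise-free* planted states through the classifier rules themselves, so
  the generator and classifier are consistent by construction; what the
  end-to-end tests then measure is the fidelity of extraction and
  classification under noise, alignment and filtering.

What the generator does *not* emulate: within-motif covariation,
heterotachy, compositional biases of membrane proteins, and insertions.
Passing tests therefore demonstrate algorithmic correctness under
clade-structured divergence, not performance on real superfamily data.

## Conservation scoring and motif discovery

Per-column rates are empirical-Bayes posterior means over a discrete gamma:
the shape \(\alpha\) is chosen from a 25-point grid on 0.2–5.0 by
maximizing the summed log-likelihood with 8 equal-prior categories, and
each column's rate is \(\sum_c r_c L_c / \sum_c L_c\), renormalized to
mean 1 over non-degenerate columns. Likelihoods come from Felsenstein
pruning under LG with branch lengths taken from the input tree (no
re-optimization); gaps are missing data; all-gap columns are flagged and
excluded. Columns are ranked into nine equal-frequency grades with grade 9
the most conserved; ties resolve by column index. Candidates for
specificity-determining positions are columns of grade ≥ 8 whose modal
residue is polar or charged (charged {D,E,K,R,H}, polar {S,T,N,Q,Y,C,W};
the split is standard biochemistry and overridable) with gap fraction
≤ 0.5.

Discovery is greedy forward selection over candidates maximizing the
normalized mutual information \(I(\text{joint states};\text{labels}) /
H(\text{labels})\) (plug-in estimates; gaps count as a state in the joint).
Selection stops at `k_max` (default 8) or when the gain falls below
`min_gain` (default 0: run to `k_max`). Two numerical choices make the
greedy well defined: gains are quantized at \(10^{-10}\) so floating-point
noise cannot mask exact ties, and ties are broken first by per-column
association (descending), then by column index. The association layer
matters because the objective saturates at \(H(\text{labels})\): once the
selected columns fully explain the labels, *every* remaining column has
exactly zero gain, and index order alone would select arbitrary
candidates.

Two properties of this formalization are worth stating plainly. First,
columns that acquired substitutions exactly on clade-separating branches
("hitchhikers") are genuinely clade-discriminating by mutual information,
and nothing in a labels-only criterion can demote them below planted
columns whose states repeat between clades; the discovery study condition
therefore plants a distinct polar/charged state per clade in every motif
column. Second, the uniform planting noise is independent of the tree, so
even a few percent of randomized cells inflates a column's apparent
evolutionary rate far more than clade-consistent variation would; at 5%
noise planted columns typically fall to grade 7 and out of the candidate
set. The discovery suite therefore runs with noise-free planting, while
classifier robustness to motif noise is exercised separately at 5% noise
in the phenotype-accuracy suite, where accuracy is measured as the
fraction of phenotype *calls* (family, electrogenicity, selectivity; three
per leaf) matching the truth table.

## Phylogenetics at desk scale

Pairwise distances are maximum-likelihood estimates under LG
(one-dimensional optimization per pair, gap sites excluded pairwise,
saturation cap 3.0 substitutions/site). Topologies come from canonical
neighbor joining (`ape::nj`), with negative branch lengths clamped to zero
and reported. Bootstrap supports resample columns with replacement,
rebuild the NJ tree per replicate and annotate each internal edge of the
base tree with the fraction of replicates containing the same
canonicalized split (smaller side, lexicographic). Phylogenetic diversity
is the branch-length sum of the minimal spanning subtree; the greedy
subset selection starts from the diameter pair and adds the leaf with the
largest PD gain (lexicographic tie-breaks), which is provably optimal for
PD and verified against exhaustive enumeration in the tests. Maximum-
likelihood tree search, model selection and rogue-taxon removal are out of
scope; a per-leaf instability diagnostic summarizes split agreement across
replicates instead.

## Profile HMM

The profile uses match/insert/delete nodes with the seven classical
transitions (M→M/I/D, I→M/I, D→M/D plus begin/end); I→D and D→I are not
modeled and such seed pairs are simply not counted. Columns with gap
fraction ≤ 0.5 become match states; emissions are counts plus one
background-weighted pseudocount; transitions are observed-path counts with
add-one smoothing. Alignment is glocal Viterbi — the full profile must be
traversed, deletions are free to open at either end, and flanking query
residues cost nothing — in log-odds bits against the LG equilibrium
background, so insert and flank residues score zero. Viterbi was chosen
over posterior decoding for exact testability: the implementation is
checked against brute-force enumeration of every legal state path on
small profiles. Scores carry no E-value calibration and are for ranking
only.

## Structure checks

Legacy PDB is the contract format (first MODEL, altloc A, author residue
numbering verbatim). Salt bridges are called when the minimum distance
between acidic carboxylate oxygens (OD1/OD2/OE1/OE2) and basic nitrogens
(NZ/NH1/NH2/NE/ND1/NE2) is strictly below 4 Å; histidine counts as basic
by default (configurable). Residue separations such as the TtNapA
K305–E333 check use the side-chain-charged minimum distance; the spatial
extent of the motif is the maximum pairwise CA distance, reported rather
than thresholded. The packaged tests exercise this machinery on synthetic
structures built in code; measurements on deposited structures require the
user to supply the PDB files (see `tests/testthat/test-acceptance.R`).

## Problem sizes and numerical choices

The shipped suites use families of 120 leaves × 400 columns × 4 clades
(20 replicates for discovery, 5 per noise level for phenotype accuracy),
50 random 5–8-leaf additive trees for NJ recovery, trees of ≤ 12 leaves
for exhaustive PD enumeration, and profiles of M ≤ 4 with queries of ≤ 6
residues for exhaustive Viterbi enumeration — sizes at which every oracle
is exact and the whole suite runs on a single CPU. Other conventions:
pairwise identity for clustering is matches over global alignment length
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1), a stated surrogate
for CD-HIT's definition; grade binning is equal-frequency, a stated
surrogate for ConSurf's scheme; distances saturate at 3.0; pruning
rescales partial likelihoods per column at every internal node to avoid
underflow.

## Known limitations

* The clade reference mixes text-derived, partially supported and
  synthetic consensus states; nearest-clade assignments to `synthetic`
  records should be read as structural placement, not literature claims.
* Labels-only mutual information cannot distinguish planted
  specificity-determining positions from hitchhiker columns once labels
  are saturated (see above); on real data the structural-context filter
  (a residue allow-list from the structure module) is the intended remedy
  and is optional, not automatic.
* The candidate grade filter is sensitive to tree-independent noise in
  conserved columns; annotation-error-like noise above ~2% can push true
  determinants below grade 8 at these problem sizes.
* The electrogenicity rule encodes the broadened definition (K8 with
  acidic 6); naturally occurring exceptions are flagged, not predicted.
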