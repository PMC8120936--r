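---
title: "Methods: distance-dependent statistical potentials in ddscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-dependent statistical potentials in ddscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

ddscore builds knowledge-based scoring functions for protein structure
models from the distance statistics of native structures. Two families of
binned distance distributions are estimated from a training set:

* a **conditional model** `M1`: one distribution per *pair class*, i.e. per
  unordered pair of (residue type, site label) types, describing how far
  apart sites of that class sit in native structures;
* a **reference model** `M2` (the *reference state*): a single distribution
  pooled over all site pairs, blind to types — the Bayesian prior that the
  conditional model updates.

A conformation is scored by projecting it onto the chosen representation,
collecting all site pairs at sequence separation >= 3 within the scoring
cutoff, and summing one of two per-pair terms:

* **PMF** (potential of mean force): `-log(P(d|M1) / P(d|M2))`, the negative
  log-likelihood ratio;
* **TIG** (total information gain): `-(P(d|M1) / P(d|M2) - 1)`, the relative
  difference, negated here so that both formalisms share the
  lower-is-better orientation that the benchmark consumes.

Lower totals mean the conformation's distances support the native,
type-conditioned statistics over the type-blind background. The PMF term is
the negative of the Shannon information gain `dI = (-log P(d|M2)) -
(-log P(d|M1))`; `information_gain()` exposes it and the package asserts
numerically that the PMF total equals `-sum(dI)` over the scored pairs.

# Representations

Ten projections of a chain onto scoring sites are supported, from
coarse to fine: `CA`, `CB`, `CA_CB`, `BACKBONE` (N, CA, C, O),
`BACKBONE_CB`, `SIDECHAINS` (all heavy atoms beyond the backbone),
`ALL_ATOM`, and the coarse-grained `BB`, `SC`, `BB_SC` bead projections.
Bead projections follow the MARTINI 2.x amino-acid definitions shipped as a
plain-text table (`inst/extdata/martini_beads_v2.tsv`): one backbone bead
per residue at the unweighted centroid of its backbone heavy atoms, and
zero (GLY, ALA) to four (TRP) side-chain beads at centroids of fixed atom
groups. MARTINI tooling uses mass-weighted centers; we use unweighted
centroids, a small and documented deviation — the potential only needs
consistent geometry and typing, not force-field parameters.

Glycine has no C-beta; in C-beta-containing representations its treatment
is the `glycine_policy`: `substitute_ca` (default) represents glycine by its
C-alpha, `exclude` drops it.

## Pair-class counting

`enumerate_pair_classes()` counts distinct canonical unordered pairs,
self-pairs included, over the representation's possible (residue type, site
label) types, by generated enumeration rather than formula. For `CB` with
substitution this gives 20 single-site types and 210 classes; with glycine
excluded, 19 types and 190 classes. (Counting conventions differ in the
literature — 171 = C(19,2) arises if self-pairs are excluded; we use one
convention, self-pairs included, consistently.) For `CA_CB` the glycine
site produced by the C-alpha selector and by substitution is one and the
same (GLY, CA) type, so the deduplicated universe has 39 types and
39·40/2 = 780 classes: a pair class is defined by its labels, not by which
selector emitted the site.

# Training

Per training chain, sites are projected and all unordered pairs with
residue-ordinal separation >= `min_separation` (default 3) and distance <=
`train_cutoff` (default 17.0 Å) are collected; observations are pooled
across chains before fitting (not fitted per chain and averaged). Each pair
class's distances feed a Gaussian kernel density estimate with Scott's
rule-of-thumb bandwidth `h = sd(x) * n^(-1/5)`, evaluated at the centers of
0.5 Å bins and converted to bin probabilities (density × width), floored
at `probability_floor = 1e-10` and renormalized. The reference `M2` is
fitted the same way from the pooled, class-blind observations of the
*prior* projection:

* `all_atom_prior` (default): the all-heavy-atom projection — or all beads
  (`BB_SC`) for bead representations, which live in a bead universe;
* `representation_prior`: the representation's own sites (the restricted
  "C-beta-only reference" experimental arm).

The all-atom default reflects the Bayesian reading of these potentials: a
type-blind all-atom prior maximizes the information added when updating to
the type-conditioned posterior, and restricted reference states measurably
degrade accuracy, most severely for TIG.

## Numerical choices

* **Bandwidth scope**: Scott's rule is applied per distribution by default
  (`bandwidth = "per_class"`); a `"global"` mode reuses the pooled
  reference bandwidth for every class, for sensitivity checks. Per-class is
  the default because each class's sample has its own scale and size.
* **Probability floor**: 1e-10 per bin before renormalization prevents
  `log(0)` in the PMF and division by zero in the TIG ratio. After
  renormalization the minimum bin probability is the floor up to a relative
  1e-8.
* **Bin edge ownership**: bins are half-open `[k·w, (k+1)·w)`; a distance
  exactly at the scoring cutoff falls in the last bin.
* **Scoring grid**: distributions are trained on the 17 Å grid, truncated
  to the 15 Å scoring cutoff and renormalized at scoring time
  (`truncate_at_scoring = TRUE`; configurable off). Because conditional and
  reference are truncated identically, the identity "M1 == M2 implies score
  exactly 0" is preserved.
* **Degenerate samples**: classes with fewer than 2 observations or zero
  variance fall back to a plain histogram; empty classes yield the
  floored-uniform distribution flagged low-confidence. A pair whose class
  was never observed in training scores through the floored-uniform
  conditional and is counted in the result's diagnostics.
* **No lower distance cutoff**: clashes (d < 2 Å) score through the learned
  distributions (see Limitations).

# Ground truth: Kabsch and TM-score

`tm_score()` is a deliberately simplified variant of the published
TM-score algorithm, sufficient for a consistent ground-truth ordering of
decoys: residues are matched by author numbering, seed alignments slide
over fragments of lengths L, L/2, L/4 (minimum 4, stride 1), each seed is
refined by iterative Kabsch superposition re-including residues within a
d0-based cutoff (`max(d0, 4.5)` Å) until stable, and the maximum of
`(1/L) * sum 1/(1+(d_i/d0)^2)` over all seeds and iterations is returned.
`d0 = 1.24 (L-15)^(1/3) - 1.8` uses the native length L and is floored at
0.5 Å so short synthetic chains remain usable. Self-comparison returns
exactly 1.0; the search agrees with exhaustive seed enumeration on small
chains to within 0.02 in the test suite. Externally computed TM-scores can
be supplied to the benchmark as a TSV to bypass this module.

Quality categories follow half-open TM intervals: near-native (0.8, 1.0],
good (0.6, 0.8], medium (0.4, 0.6], poor [0, 0.4]; boundary values fall
into the lower category.

# Benchmark definitions

* **Pairwise ranking accuracy**: within each target, every unordered model
  pair with |ΔTM| >= 0.1 is ranked; a pair is correct when the higher-TM
  model got the lower score. Pairs are pooled over targets (a per-target
  averaging mode exists) and attributed to the category of the higher-TM
  member — the model "being recognized". The attribution side is
  configurable (`higher`/`lower`/`both`) because a pair can span two
  categories and the choice is a convention, not a derivation. Score ties
  count as incorrect.
* **Correlations**: Pearson, Spearman and Kendall between TM and the
  negated score, per target, averaged unweighted; zero-variance targets are
  skipped with a warning.
* **Average predicted rank**: fractional ranks of ascending score (rank 1 =
  best), pooled over targets for the records of one category. Native
  records are included by default.
* **Scorer comparison**: Wilcoxon signed-rank on paired per-pair
  correctness indicators, zero differences dropped, alpha 0.05.
* **Class subsetting**: the full benchmark recomputed per user-supplied
  target class label, with partition conservation of pair counts.

# The synthetic world

The generators exist so the entire pipeline is testable offline; they
emulate *single-chain, heavy-atom, secondary-structure-level* proteins and
deliberately not real ones:

* `make_chain()` builds ideal-geometry backbones (helix phi/psi = -57/-47,
  strand -120/+120, mixed alternates 8-residue blocks), C-beta by ideal
  internal coordinates, and one pseudo side-chain heavy atom per
  non-GLY/ALA residue along the CA->CB direction at a residue-type-specific
  distance, named after the residue's real gamma atom so that side-chain
  and bead projections are exercised. There is no rotamer library, no
  tertiary packing, and residue identity has almost no geometric
  consequence — so type-conditioned distributions carry far less
  information than in real proteins.
* `make_training_set()` adds 0.2 Å coordinate jitter, the scale of
  crystallographic coordinate uncertainty, so distributions have realistic
  width; 60-residue chains are the default, a compromise between pair
  counts and run time chosen once.
* `make_decoy_ladder()` perturbs every atom coordinate with i.i.d. Gaussian
  noise of sd sigma and computes true TM-scores. Mean TM decreases
  strictly with sigma; unlike fragment-based decoy generators, the decoys
  are *not* compact protein-like conformations.

A green test on this world therefore establishes internal consistency
(filters, algebra, invariances, serialization, benchmark statistics) and
coarse discrimination, not real-data accuracy.

# Known limitations

* **Summed scores under extreme perturbation**: both formalisms sum
  per-pair terms over pairs within the 15 Å cutoff. Independent Gaussian
  noise of sd sigma inflates a pair distance d to about
  `sqrt(d^2 + 6 sigma^2)`, so at sigma = 8 Å nearly all pairs leave the
  cutoff and totals collapse toward zero regardless of how wrong the
  structure is, while mid-noise decoys retain many mildly penalized pairs
  and score *worse*. Expected totals are consequently non-monotone along a
  (0.5, 1, 2, 4, 8) Å ladder, and the package's strictest acceptance test
  — requiring correct score-ordering of that full ladder in >= 90% of
  replicates — fails by design honesty rather than by implementation
  error (measured ~7% for PMF, ~11% for TIG). Orderings among mild
  perturbations (<= 1 Å), where decoys remain compact, are reliable.
* **Clash reward in sparse regimes**: with per-class Scott bandwidths and
  few observations per class, conditional KDE tails reach into the clash
  region (d < 2.7 Å) where the data-rich reference is floored, so
  clash-generating decoys can receive large spurious negative terms —
  extreme for TIG, whose term is linear in the ratio. Real training sets
  with tens of thousands of observations per class shrink the bandwidths
  and physical decoys avoid the regime entirely; the `"global"` bandwidth
  mode removes the asymmetry at the cost of spikier conditionals.
* **OXT and altloc conventions**: terminal OXT is dropped at parse time (it
  is not one of N/CA/C/O and would otherwise create its own pair classes);
  alternate locations keep the highest-occupancy conformer, ties broken by
  altloc code order. Sequence separation uses residue ordinal rank within
  the chain, not author numbers, so numbering gaps and insertion codes
  cannot corrupt the separation filter.
* **Scope**: no angular or orientation terms, no solvent accessibility, no
  multi-chain assemblies, no mmCIF.
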