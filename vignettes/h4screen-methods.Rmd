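---
title: "Methods: sequential ligand- and structure-based screening with h4screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential ligand- and structure-based screening with h4screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h4screen)
```

`h4screen` implements a two-stage virtual screening analysis for human
histamine H4 receptor (hH4R) antagonists: a ligand-based stage that learns
descriptor-range classifiers and combines them into a per-molecule
bioactivity index, and a structure-based stage that post-processes docking
poses. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## The ligand-based model

### Descriptor panel

Molecules are represented by eleven 2D descriptors
(`descriptor_panel()`): molecular weight (Da), net formal charge (e),
nitrogen and oxygen counts, aromatic-atom count, hydrogen-bond donors and
acceptors, an atom-contribution logP, ring count, rotatable-bond count, and
the fractional negative van der Waals surface area (`fasa_neg`, in
[0, 1]). All are computable from the connection table; no conformers are
generated. Chemistry is delegated to OpenBabel through ChemmineOB: SMILES
parsing and canonicalization, molecular properties, SMARTS matching
(rotor count), and Gasteiger partial charges.

Two descriptors deserve comment because the originals come from commercial
software and are not bit-reproducible:

* **`fasa_neg`** is approximated as the fraction of total VdW surface
  carried by atoms with negative Gasteiger partial charge, each atom
  contributing the full sphere area of its Bondi radius. This preserves
  the descriptor's meaning (how much of the molecular surface is
  electron-rich) while remaining a pure function of the 2D structure.
* **`logp`** is OpenBabel's atom-contribution estimate.

Consequently, numeric bounds learned on these descriptors are meaningful
relative to this implementation, not interchangeable with values computed
by other descriptor engines.

### Range filters and the class-normalized MCC

A range filter is a conjunction of closed intervals over a descriptor
subset; a molecule passes iff every constrained descriptor lies inside its
interval. Filter quality is the Matthews correlation coefficient computed
on a **class-normalized** table: the per-class pass/fail percentages
(P_A, N_A, P_NA, N_NA) are used directly as confusion-table entries, so
both classes weigh equally no matter how imbalanced the training set is.
This convention is the one under which per-class pass rates of 87%
(actives) and 5% (non-actives) yield an MCC of 0.82; the raw-count MCC on
an imbalanced set would differ and is available via
`evaluate_filter(..., mcc_type = "raw")`.

### Discretization

`discretize()` places candidate interval bounds at pooled empirical
quantiles (deciles by default; e.g. molecular weight described by ten
bins). The inverse-ECDF quantile (type 1) is used so cut-points are always
observed values — integer for integer-valued descriptors. Binning is
closed on the right: a value exactly on a cut-point belongs to the lower
interval (`encode_binary()` one-hot encodes this membership). Constant
descriptors collapse to a single degenerate interval, are flagged, and are
excluded from the search.

### Iterative Stochastic Elimination

ISE treats filter construction as combinatorial optimization over
variables (each descriptor's low and high bound) and values (the interval
edges). Each iteration samples `sample_size` random filters — a random
descriptor subset of size `subset_min`–`subset_max`, a random admissible
(low, high) edge pair per descriptor — scores them, and compares the
frequency of each edge value among the worst `worst_fraction` of the
sample against the best `best_fraction`; values whose margin exceeds
`elimination_margin` are eliminated. When the remaining space holds at
most `exhaustive_limit` filters it is enumerated exhaustively; the
iteration cap `max_iterations` bounds the run otherwise.

Defaults (`ise_config()`): `sample_size` 1000, worst/best fractions 0.1,
`elimination_margin` 0.1, `exhaustive_limit` 1e5, `mcc_floor` 0.6
(mirroring the learned filters' reported MCC range of 0.6–0.87),
descriptor-subset size 3–6, 50 iterations. These are desk-scale defaults
chosen for tractability; the algorithm's published description does not
fix them. All randomness flows from an explicit `seed`, and two runs with
identical inputs and seed are identical.

The ensemble of "efficient filters" consists of every distinct evaluated
filter with MCC at least `mcc_floor`, deduplicated by exact constraint
equality (filter uniqueness is not defined more finely than that). The
best filter is always included.

### The Molecular Bioactivity Index

The per-molecule index over an ensemble of n filters is

MBI = (1/n) Σᵢ [ δ_Ai · P_Ai / max(P_NAi, ε) − δ_NAi · N_NAi / max(N_Ai, ε) ]

with δ_Ai = 1 iff the molecule passes filter i and δ_NAi = 1 − δ_Ai. The
pass term is the filter's "efficiency factor" for bioactives
(true-positive over false-positive percentage); the fail term penalizes
failing a filter that identifies non-actives well. Two design choices were
genuinely open and are resolved as follows:

* **Normalization and functional form.** The published equation is only
  available as a low-resolution figure; the accompanying text names
  P_A/P_NA as the pass-side efficiency factor and N_A/N_NA as the
  misidentification factor. We take the mean over filters of
  (+pass ratio, −reciprocal misidentification ratio). The formula is
  isolated in one internal function (`mbi_from_pass()`), so an alternative
  reading is a one-line change and would only rescale ranks
  monotonically for a fixed ensemble.
* **ε = 0.5 percentage points** floors the denominators so a filter with
  zero false positives (or zero false negatives) on the training set
  cannot contribute an infinite score.

`rank_library()` orders by descending MBI with deterministic tie-breaks
(descending number of filters passed, then id). The "highly indexed"
focused set defaults to the top fraction of the ranking (1% mirrors the
published enrichment view; the desk-scale pipeline default is 5% so the
focused set is large enough to triage).

## The structure-based stage

### Best pose and energy clustering

Docking bundles carry 16 poses per compound by default; only the best pose
per compound — minimal total docked energy, ties broken by pose rank — is
analyzed, as in the published docking figures. Electrostatic energies of
the best poses are clustered with `kmeans_1d()`. Because 1-D SSE-optimal
clusters are contiguous in value order, the package computes the exact
optimum by dynamic programming rather than Lloyd iteration: the reported
three-group separation (boundaries near −4 and −1.1 kcal/mol in the
published analysis) is a global property of the energy distribution, and a
heuristic clusterer can miss it from an unlucky start. The optimal
partition is itself a Lloyd fixed point, so every point is assigned to its
nearest centroid and boundaries are midpoints of adjacent centroids.
Cluster indices are 0-based with cluster 0 the lowest-energy group; `k = 3`
is the default. Energy thresholds are re-derived per pose population (the
printed −3.16 kcal/mol boundary was specific to one receptor model's test
set and is treated as a regression fixture, not a constant).

### Distance scoring

The conformational filter measures, per reference residue, the minimum
Euclidean distance between any polar heavy ligand atom and any side-chain
carboxylate oxygen of that residue; an interaction is a distance strictly
below 4 Å. The score counts interacting residues (0, 1, 2). Choices the
source left open: polar heavy atoms are N and O only (sulfur excluded);
the carboxylate is represented by its oxygens (OD1/OD2 for Asp, OE1/OE2
for Glu), carbons excluded; "below the threshold" is strict. The score is
invariant under rigid motions applied jointly to pose and site, and
monotone in the threshold — both property-tested.

### Combined filter, enrichment, consensus

The two filters are conjunctive (`combined_filter()`): pass iff the
electrostatic energy falls in the allowed lowest cluster(s)
(`lowest_cluster` or `two_lowest_clusters`) and the distance score reaches
the configured minimum. Stringency nests: the strict configuration's pass
set is a subset of the permissive one's.

Enrichment follows the verification protocol: the reference set is
sub-sampled without replacement over `folds` draws (20 and 100 in the
published evaluations, with 137 compounds per draw in the focused-library
case), and EF = active pass % divided by the mean reference pass % across
folds. A zero reference rate flags the EF as infinite rather than
producing NaN. The consensus library is the pose-filter passers ordered by
MBI rank, truncated to `size` (default 11).

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable with exact ground truth.

`gen_descriptor_set()` draws per-class descriptor vectors — without
chemical structures, since the learning machinery never consults the
structure — and plants a range rule: actives satisfy it with probability
1 − `label_noise` (default 0.13), decoys with probability
`decoy_rule_rate` (default 0.05), reproducing the three-rules operating
point (87%/5%, MCC ≈ 0.82). Default marginals mirror the antagonist
property profile: charge +1 dominant, 3–7 nitrogens, fasa_neg ≈
N(0.30, 0.06), molecular weight ≈ N(280, 60) truncated above 100 Da,
moderate logP; decoys broader on every axis. Rule membership is enforced
by resampling the constrained descriptors (inside or outside the rule), so
the `in_rule` flag is exact; marginal moments are only guaranteed when no
rule is planted.

`gen_pose_set()` plants binders with one polar nitrogen per reference
residue at a uniform 2.5–3.8 Å from a randomly chosen carboxylate oxygen
and electrostatic energy N(−4.5, 0.5) kcal/mol; non-binders sit beyond a
5–12 Å clearance with background energies N(−0.5, 0.7). The construction
is separable by design (binder distances below the 4 Å rule, non-binder
distances above; an energy gap around −2.5 kcal/mol), so planted truth
maps exactly onto filter outcomes.

What passing tests on these sets does **not** show: real screening
libraries have correlated descriptors, activity cliffs, and decoys that
are not uniformly "broader" than actives; real docking poses have
continuous binding-quality gradations rather than a planted gap, and their
electrostatic energies depend on protonation and receptor conformation.
The synthetic results validate the machinery (optimization, scoring,
filtering, bookkeeping), not the biological discrimination power of any
particular descriptor set or receptor model.

For the end-to-end planted pipeline the analytic enrichment factor is the
ratio of planted binder rates (0.20/0.01 = 20); the acceptance check uses
a reference population of 1000 compounds so the expected number of
reference binders (10) keeps the fold-averaged EF finite and its binomial
(delta-method) standard error meaningful.

## Problem sizes and other numerical choices

The test suite and the example pipeline run at desk scale, chosen so the
statistical claims are testable rather than to mimic full campaign sizes:
training sets of 10²–10³ per class, 6–10 discretization bins, ISE samples
of 50–300 filters over 2–3-descriptor subsets with exhaustive limits of
10³–10⁶, pose sets of tens to ~10³ compounds at 16 poses each, and 20–100
sub-sampling folds. The published full-scale quantities that depend on
proprietary descriptors, the commercial learning engine, actual AutoDock
runs or the ZINC library (the 48-filter ensemble, the 46-ligand diverse
active set, the 872-compound focused library, model-specific energy
boundaries) are treated as regime descriptions, not reproduction targets;
their testable structure is covered by property-based checks instead
(exhaustive-search equivalence, planted-rule recovery, clustering
optimality, rigid-motion invariance, planted enrichment recovery).

Degenerate inputs are handled explicitly: constant descriptors are flagged
out of the search; a filter space eliminated to nothing is a fatal error
carrying the iteration trace; an empty class, a zero-atom pose model, and
a clustering with k above the number of distinct values are fatal; ties in
ranking and pose selection break deterministically; boundary values in
binning go to the lower interval; and all bounds in the printed rule sets
(Lipinski, Oprea, three-rules) are inclusive exactly as printed.

## Known limitations

* Descriptor values follow OpenBabel conventions (HBD/HBA SMARTS
  definitions, Gasteiger charges, atom-contribution logP); bounds are not
  transferable to MOE-computed descriptors, and the diverse-ligand counts
  reported for the original sets are not expected to reproduce exactly
  under a different fingerprint implementation.
* Protonation is taken as written in the input SMILES; there is no
  pH-dependent protomer model, so charge-dependent descriptors reflect the
  input representation.
* The ECFP4-style fingerprint is a faithful radius-2 circular fingerprint
  (atom-order independent, 2048 bits) but its hashing differs from any
  specific toolkit's, so absolute Tanimoto values differ across toolkits
  even though orderings are broadly preserved.
* The exact MBI functional form is a documented design choice (see above);
  ensembles serialized by this package record everything needed to rescore
  under an alternative form.
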