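---
title: "Hierarchical TAD folding: models, statistics and design choices"
author: "metatadr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical TAD folding: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatadr)
```

## Scope

Hi-C contact maps show that mammalian chromosomes fold into topologically
associating domains (TADs) of roughly 0.5 Mb, and that TAD–TAD contacts
extend far beyond individual domains.  `metatadr` implements an analysis
of that higher-order organization: TADs are merged bottom-up into a
binary tree of "metaTADs" by adjacency-constrained single-linkage
clustering of their contact frequencies, and the resulting hierarchy is
related to contact enrichment, epigenomic feature tracks, A/B
compartments, lamina-associated domains (LADs), and — across two cell
states — to rewiring of the tree and coherent gene-expression change.
A lattice polymer model (strings-and-binders, SBS) demonstrates the
physical side of the same picture: interspersed binding sites can fold
two TADs into a higher-order domain, compacting the chain without
degrading contact specificity.

Everything operates on synthetic data with a *planted* hierarchy, so
every stage has an exact ground truth.  This vignette records the models
and the design decisions a maintainer would want to know.

## The synthetic generator

`plant_hierarchy()` tiles one synthetic chromosome with `n_tads`
contiguous TADs and draws a random contiguous binary tree over them by
recursive bisection (`shape = "balanced"` gives the deterministic
midpoint tree, useful when an analysis needs controlled neighbourhood
structure).  Expected contact between bins $i, j$ is

$$ E[c_{ij}] = A\,(|i-j|+1)^{-\gamma}\prod_{\text{nodes } v \supseteq \{i,j\}} \beta_v $$

a power-law distance decay (default $\gamma = 1$) multiplied by the
boost $\beta_v$ of every tree node whose span contains both bins, the
leaf TAD included.  Boosts are geometric in node height: $3.0$ at the
TAD level decaying to $1.05$ at the root, so nesting is strongest at the
bottom of the tree, mirroring the progressive weakening of higher-order
contacts in real maps.  Noise is Poisson sampling at a configurable
sequencing depth (default 10 expected counts per unit of expectation;
lognormal noise is available, `noise = "none"` gives the exact
expectation).

Two generator choices deserve comment:

* **Equal TAD widths by default.**  TAD-level contact scores are block
  means, and the mean of $(d+1)^{-\gamma}$ over a block depends on the
  block's width.  With variable widths that geometric factor varies by
  tens of percent across junctions — more than the $\sim 5$–$10\%$
  per-level margin the boost schedule leaves near the root — so merge
  order would be partly driven by TAD geometry rather than by the
  planted hierarchy.  With equal widths (the default; the width is
  `mean_tad_size` rounded to whole bins) the decay factor is identical
  at every junction, and one can show the greedy single-linkage
  agglomeration recovers the planted topology *exactly* on noiseless
  matrices, for every seed and TAD count.  `width_dispersion =
  "poisson"` restores realistic size variation for robustness studies;
  recovery is then approximate, which is itself informative.
* **What the generator does not emulate.**  No trans contacts, no
  restriction-fragment structure, no mappability or coverage bias, no
  copy-number variation; bins are never missing unless masked
  downstream.  Passing tests therefore validate the statistical
  machinery, not robustness to every artefact of real Hi-C.

`simulate_feature_track()` gives every tree node an independent Gaussian
effect (sd `level_sd`) and sums effects along each root-to-leaf path, so
feature similarity decays with tree distance by construction; per-bin
jitter (sd `bin_jitter_sd`) models sub-TAD variability.
`simulate_timepoint_pair()` produces a second time point by inverting
the local merge order inside chosen internal nodes ("rewiring"; spans
and boosts outside the rotated subtrees are untouched) and applying
multiplicative expression shifts to the member TADs of each rewired
subtree, coherently (all up) or not, on top of a lognormal baseline in
FPKM-like units.

## From contact matrix to metaTAD tree

`ice_balance()` performs iterative correction until unmasked row sums
agree within `tol` (default $10^{-6}$), after masking bins below the 2nd
percentile of coverage.  `oe_normalize()` divides each entry by the mean
contact at its distance; an optional per-distance minimum subtraction is
provided (off by default) for data that carry additive background.
`directionality_index()` contrasts upstream/downstream contact sums in a
2 Mb window with the usual signed chi-square form, and `call_tads()`
segments the median-filtered track at strong-negative to strong-positive
transitions ("strong" means $|DI|$ above the chromosome-wise median
absolute deviation) — a deliberate simplification of the original
HMM-based caller, adequate for synthetic maps and clearly flagged as
such.

`tad_contact_matrix()` averages (balanced) contacts over TAD-pair
blocks; `build_metatad_tree()` then iteratively merges the two most
strongly interacting *genomically adjacent* domains until the chromosome
is one domain.  Under `single` linkage the candidate score of a domain
pair is the maximum TAD-level entry across the pair, under `average` the
mean of all cross entries; both are exposed because a mean-based
interaction statistic is equally defensible, and the oracle tests cover
both.  Ties break toward the leftmost junction; no randomness enters
tree construction.  Tree recovery runs on the *raw* TAD contact matrix:
the observed/expected correction is kept for the control analyses (for
instance the nearest-neighbour fraction after removing 1D proximity),
where empirically it belongs — dividing by per-distance means that are
themselves structured by the hierarchy distorts merge scores.

Tree distance between two TADs is the number of edges on their
leaf-to-leaf path minus one (siblings are at distance 1).

## Enrichment statistics and nulls

For every merge creating a metaTAD of $n$ TADs, $I$ is the mean contact
between the two merged domains and $J$ the mean contact within the whole
metaTAD.  Backgrounds $I_C$ and $J_C$ come from 100 random placements of
size-matched pseudo-domains anchored at the junctions of other
neighbouring TAD pairs on the same chromosome (placements that do not
fit are resampled; a merge with no fitting placement is excluded with a
warning — in practice only the root).  Placements are drawn with
replacement; the placement standard deviation is reported as the
dispersion.  The second null is `shuffle_matrix_by_diagonal()`, which
permutes entries within each diagonal: distance decay is preserved
exactly while all positional structure is destroyed, so $I/I_C$ on a
shuffled matrix calibrates the curve at 1.

## Tree–feature statistics

Per-TAD feature values are coverage-weighted means of bedGraph bins.
`correlation_vs_distance()` computes a Pearson correlation per distance
(tree or linear), each unordered TAD pair entering once in (min id, max
id) orientation; profiles are therefore invariant under coordinate
reversal, and the per-distance estimates carry the usual small negative
bias of lagged correlations at small TAD counts.  `correlation_length()`
interpolates the profile linearly against genomic separation to the 20%
threshold (the conventional, admittedly arbitrary, comparison point);
profiles that never cross are returned censored at the largest
separation.  Significance uses `random_neighbour_trees()`: the same
constrained agglomeration with uniformly random adjacent-pair choices,
which preserves leaf set, order and node count while carrying no contact
information.  All permutation p-values in the package use the
$(r+1)/(n+1)$ estimator, so zero p-values cannot occur.

Compartments come from the first principal component of the Pearson
correlation matrix of the O/E map, oriented by a reference track (gene
density or GC) when supplied, and otherwise by fixing the first unmasked
bin positive; per-TAD labels are majority labels with the A-coverage
fraction retained.  A structureless (uniform) map yields zero scores
flagged unreliable rather than an arbitrary labelling.  LAD-transition
coincidence counts boundaries within 100 kb (configurable; the scale of
a few Hi-C bins) of a LAD/inter-LAD transition against a circular-shift
null of the boundary set.

## Differentiation comparisons

Tree similarity across time points is the cophenetic correlation:
Pearson correlation of the two leaf-pair tree-distance vectors over
shared leaves (conserved TADs from `match_boundaries()`; edge-count
distances, matching the tree-distance definition used everywhere else).
The local tree change of TAD $t$ averages $|d_A(t,u) - d_B(t,u)|$ over
the neighbourhood of $t$ up to its third-closest shared leaf in tree A,
and is symmetrized by averaging with the B-anchored score, since neither
anchor is privileged; z-scores standardize over the scored set and the
primary binary call is $z > 0$, with the raw $> 1$ rule reported
alongside.

Expression change requires both fold change $> 1.5$ (with a 0.1
pseudocount in FPKM-like units, so zero-expression TADs are defined) and
absolute difference above one quarter of the interquartile range of the
absolute per-TAD differences of that transition; the IQR population is
the per-TAD differences (configurable to expression levels instead), and
the double criterion exists precisely to exclude large fold changes at
negligible expression.  Overlaps of labelled region sets use the Jaccard
index on merged intervals and a circular permutation test (default
10,000 shifts; per chromosome, wrapping, coverage-preserving).
Coherence of expression change is evaluated at TAD pairs whose tree
distance is equal in both trees, against a label-permutation null, up to
tree distance 5.

## The SBS polymer model

The chain lives on a cubic lattice with bond length 1, hard walls and at
most one particle per site.  Moves are single-bead corner flips,
end-bead pivots and binder steps, each proposal symmetric, accepted with
the Metropolis rule; a binder adjacent to a matching-colour bead
contributes $-E_c$ (in kT).  The incremental energy bookkeeping is
tested against full recomputation (exact), a four-bead toy chain is
tested against exact Boltzmann enumeration, and zero-binder chains
reproduce the self-avoiding-walk gyration exponent — together these
pin the engine's statistical mechanics at desk scale.  Local-move
dynamics are slow for strongly crosslinked states, so runs at strong
binding report an energy-plateau flag (`equilibrated`) computed from the
third vs fourth quarter of the energy trace; flagged trajectories should
be rerun longer.

The matched comparison uses two presets with identical red/green
layout: red sites on the odd beads of the first half, green sites on
the odd beads of the second half.  In the TAD-only preset the even
beads are neutral; in the metaTAD preset they carry blue sites
interspersed across both halves, with their own binders.  Occupied
volume is the number of lattice sites inside the 3D convex hull of the
chain (computed with exact integer predicates); the
equivalent-ellipsoid volume would behave similarly but the hull is the
more literal reading of "occupied volume".  Contacts use a Euclidean
distance threshold of 2 lattice units.  A blue site counts as "engaged"
when it touches a blue binder that simultaneously touches at least one
other blue site — i.e. when it participates in a blue-mediated bridge.

Binder concentrations and affinities are not universal constants: the
interesting regime is the one where each colour forms its own domain
while cross-colour contacts stay negligible, and `sbs_sweep()` is the
documented utility for locating it.  Several sweeps shaped the
calibrated values frozen in `sbs_experiment_defaults()`, and the
failures are as instructive as the result: binder counts scaled to box
volume oversaturate the sites and re-swell the chain (the re-entrant
branch of the binders-switch transition), dense site blocks saturate
binders with chain-local bonds that never form loops, and site spacings
beyond two beads cannot form doubly-bound bridges at all under local
moves, because the first bond pins the binder while the loop closure it
needs remains entropically expensive.  The calibrated regime therefore
uses moderate red/green binding — the TAD-only chain carries two
contact-enriched domains but remains spatially extended — and a
stronger, site-stoichiometric blue system on the alternating neutral
beads, which folds the metaTAD chain into one compact domain.  Both
presets start from a deterministic compact conformation: the open state
is reached from there without any barrier, whereas collapse from open
starts is nucleation-limited and can fail entirely within a desk-scale
run.  Because the occupied volume of the extended state fluctuates on
the chain's slowest conformational timescales, the experiment averages
two independently seeded run pairs, and the volume comparison should be
read with that sampling noise (roughly ten percentage points per run
pair) in mind.  At these settings the interspersed blue sites roughly
halve the occupied volume, red–green contact probability stays several
times below intra-domain levels, and about half of the blue sites are
engaged in a blue-mediated bridge at any sampled instant.

## Problem sizes and numerical choices

The test-suite and acceptance analyses use 32–64 TADs of 10 bins (50 kb
bins), 100 background placements per merge, 200–500 replicate
permutation tests at 200 permutations each, and polymer chains of
50–200 beads with $10^7$–$6 \times 10^8$ elementary moves (the matched
polymer comparison averages six independently seeded run pairs); these
sizes make every analysis rerunnable on a single CPU while leaving most
statistics comfortably inside their tolerances.  The occupied-volume
comparison is the exception: the TAD-only reference state lives near
its folding transition, where both the open and the partially folded
branch are visited across seeds, so the percent volume reduction
carries a standard error of several percentage points even after
replicate averaging, and individual seeds can scatter by more.  Degenerate inputs are
handled explicitly: all-zero DI tracks give one chromosome-spanning TAD
with a warning, fully masked TADs must be dropped before clustering,
constant cophenetic vectors return `NA` with a warning, empty interval
sets make the Jaccard index undefined rather than zero, and `n_perm = 0`
is an error rather than a silent p-value of 1.

## Known limitations

* The TAD caller is a simplified directionality-index segmentation, not
  the original HMM; boundary positions on noisy real data will differ.
* The exact form of any additional background subtraction applied to
  real Hi-C is data-set specific; the per-distance minimum subtraction
  here is off by default and experimental.
* Cophenetic and local tree-change statistics require a conserved-TAD
  mapping; TADs that split or merge between time points are excluded
  rather than partially matched.
* The SBS model is a minimal lattice caricature: no bending rigidity,
  no binder–binder interactions, hard walls rather than dilute
  periodic boundary conditions, and local moves whose relaxation time
  grows quickly with binding strength.
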