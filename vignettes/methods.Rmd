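---
title: "Methods: cross-system network inference and comparison with crossclr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-system network inference and comparison with crossclr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossclr)
```

# The question the package addresses

Toxicity screening would like to replace animal exposure studies with
cultured-cell assays, but a cell line is only a useful surrogate if the
*regulatory program* it mounts against a chemical matches what the organ
does in the animal. crossclr implements a complete chain for asking that
question with expression data: preprocess both systems' microarray-style
matrices, call differentially expressed (DE) genes in each, infer a static
gene-regulatory network per system from a large expression compendium, and
intersect the two networks to extract the regulatory modules conserved
between systems. A planted-truth simulator generates paired benchmarks so
every stage is testable without external data.

# Preprocessing model

Single-channel intensities are floored at 5.0 (near-background probes
otherwise produce explosive ratios), divided by each array's 50th percentile
(per-chip normalization; linear-interpolation quantile, the common
convention — the convention is a `type` argument so an alternative can be
selected), divided by each gene's median across arrays (per-gene
normalization), filtered to probes with present calls on at least 50% of
arrays (inclusive threshold), and log2 transformed.

Array quality control thresholds each array's mean Pearson correlation with
all other arrays at 0.8. Two decisions deserve comment:

* **QC runs on per-chip-normalized (log2) data, before per-gene
  normalization.** The high inter-array correlation that makes this filter
  work is carried almost entirely by the shared abundance profile — bright
  genes are bright on every good array. Per-gene centering removes exactly
  that profile; after it, even perfect replicate arrays correlate near zero
  and the 0.8 threshold would reject everything. We verified this failure
  mode directly on simulated arrays.
* **Exclusion is decided in a single pass** over the correlation matrix of
  the original array set, not iteratively. This makes the result
  deterministic and independent of array order; an iterative variant would
  depend on removal order.

Missing values are not supported: the present-flag filter precedes analysis
and an `NA` cell is a parse error. Flag files accept both the `P`/`A` and
`1`/`0` dialects; anything else is an error.

# Differential expression

In the dose-series (in-vivo-style) design, each gene is tested with a
classical one-way fixed-effects ANOVA across the dose groups at each time
point. A gene passes when `p < 0.05` (strict) **and** the largest fold
change between any pair of dose-group means is at least 1.5 (inclusive).
The per-system DE universe is the union of the per-time-point pass sets.
In the control-vs-treated (in-vitro-style) design the test is an unpaired
pooled-variance Student t-test (Welch's form is available behind
`var_equal = FALSE`), with the same fold rule.

Numerical conventions:

* Fold changes are computed on **linear-scale** group means (log2 data are
  exponentiated first): a "1.5-fold change" reads as a linear ratio. The
  max-pairwise convention `max(means)/min(means)` keeps fold changes >= 1.
* A constant gene (zero within-group variance, equal means) gets `F = 0,
  p = 1` — no evidence — rather than an error, so genome-wide scans flow
  through degenerate rows.
* No multiple-testing correction enters the pass rule, matching the raw
  `p < 0.05` screening convention this kind of study uses; BH-adjusted
  q-values are emitted alongside for transparency.

Overlap percentages between systems are reported as integers rounded half
away from zero, the convention used when stating "N transcripts (X% of the
in vitro transcripts)".

# Condition clustering

For pattern comparison, every sample is divided gene-wise by the mean of its
(system, time) stratum's control samples, replicates are averaged into one
column per (system, compound, dose, time) condition, and both genes and
conditions are clustered with Pearson correlation distance (`d = 1 - r`,
centered Pearson; the uncentered variant was considered and not used) under
average linkage (UPGMA). Ties between equal-dissimilarity merges are broken
by the lexicographically smallest pair of cluster labels, so the tree is
deterministic across platforms. Trees are exported as Newick with merge
heights as branch lengths.

# CLR network inference

The core algorithm is the context likelihood of relatedness. For genes
$A$ and $B$ the mutual information
$I(A;B) = \sum p(a,b)\,\log_2 \frac{p(a,b)}{p(a)\,p(b)}$
is estimated by B-spline fractional binning: each expression value is
linearly rescaled onto the spline domain and assigned fractional membership
in 10 bins through B-spline basis functions of order 3 (an order-1 spline
degenerates to hard binning, which is how the estimator is cross-checked).
Each sample's weights are nonnegative and sum to one, so the averaged outer
product of two genes' weight rows is a proper joint distribution. The
implementation computes all pairs at once through a single blockwise
cross-product of the stacked weight matrices and the identity
$I = H_A + H_B - H_{AB}$, which is algebraically the formula above.

Each gene's MI values to all other genes (self excluded) form its background
distribution. The pair score is
$\sqrt{\max(0, z_A)^2 + \max(0, z_B)^2}$
where $z_A$ is the background z-score of the pair's MI in $A$'s
distribution (population-variance denominator). Clamping negative z at zero
follows the original CLR behaviour and stops mutually-low-MI pairs from
scoring high; it is switchable (`z_clamp = FALSE`) because the composite
formula itself is silent about it. Edges with composite score >= 2.0
(inclusive) are retained. The cutoff applies to the composite score, not to
each z separately. Degenerate constant genes get MI 0 everywhere; genes
with zero background spread get z = 0.

Probe-level data are collapsed to one row per gene symbol by the
maximum-variance probe before inference, so each network node is one gene.

# Conserved subnetworks and TF connectivity

Two inferred networks over a shared namespace are intersected as sets of
unordered pairs; connected components of the intersection are the conserved
subnetworks, ordered by size. When per-gene DE directions are supplied for
both systems, each component is annotated with whether every member is
regulated in the same direction in both systems, and whether the module is
coherently induced or repressed ("up"/"down") or direction-heterogeneous
("mixed"). Transcription-factor connectivity is tabulated per network;
hubs are flagged at strictly more than 15 connections, and regulators with
at least a two-fold degree difference between systems are flagged
(any positive degree versus zero counts; zero versus zero does not).

# Benchmark scoring

Recovery of a planted regulator-to-target truth is scored with the standard
regulator-restricted protocol of the network-inference assessment
literature: only candidate pairs with at least one regulator endpoint enter
the precision–recall computation. The reason is statistical, not cosmetic.
Two targets of one TF are genuinely mutually informative under any
common-driver model — their dependence is real, merely indirect — so a
directed truth can call such a pair neither correct nor incorrect.
Mutual-information methods cannot, even in principle, separate co-targets
from direct targets on observational data; scoring them as false positives
would measure that impossibility rather than the method. The thresholded
networks themselves always keep all edges, TF-incident or not; only the
benchmark scoring restricts candidates.

A related point shapes the permutation control. Because CLR standardizes
every MI value against per-gene backgrounds, the *rate* of edges passing a
fixed composite cutoff is roughly constant (a few percent of pairs) whether
or not the data contain signal — a fully permuted matrix still yields a
floor of edges. What permutation destroys is *recovery*: planted-edge recall
collapses to chance and the area under the precision–recall curve falls to
the baseline. The test suite asserts exactly that.

# The synthetic benchmark

`sim_config()` fixes the study conditions; `generate_truth_networks()` and
`simulate_expression()` realize them.

* **Truth.** 10 TF-centered modules of 8 dedicated targets among 200 genes.
  4 modules are conserved: identical targets, signs, effect sizes and dose
  sensitivities in both systems. The remaining modules draw their target
  sets on disjoint pools per system, so the edge intersection of the two
  truths is exactly the shared core.
* **Regulation.** Linear-Gaussian on the log2 scale: a TF's latent activity
  *is* its own condition-level expression (drawn N(0,1) per compendium
  condition), and each target adds signed slope x activity. Slope
  magnitudes are `max(N(1, 0.2), 0.5)` log2 units per activity unit. This
  choice matters: if the TF's measured expression were as noisy a readout
  of its activity as the targets are, TF-target and co-target dependencies
  would be statistically identical and no method could rank direct edges
  first.
* **Variance components** (log2 units): `noise_sd = 0.3` replicate-level
  measurement noise, typical of array replicates; `condition_sd = 1.0`
  per-gene condition-level biological variation in the compendium,
  expressing that a single modeled regulator explains only part of a
  target's variance across heterogeneous conditions; `activity_re_sd =
  0.25` condition random effect on TF activity in the perturbation designs.
* **Designs.** Dose series 0/4.8/48/96/192 mg/kg x 24/48 h x 4 replicates;
  control-vs-treated with 3 replicates; 120-condition compendia. The
  dose response is linear in log dose by default (a Hill form is available).
  TF dose sensitivities are uniform in [1, 2] with random sign, so planted
  DE genes shift by 0.5–2.5 log2 units at top dose.
* **Baselines.** Per-gene baseline abundance N(9, 2) on the log2 scale;
  output is `2^(baseline + deviation)` on intensity scale with present
  flags, so the full normalization chain exercises realistically.
* **Determinism.** All randomness flows from one seed through
  per-(stream, gene) substreams (a hashed `set.seed` per gene), so adding
  genes or matrices does not perturb existing draws and fixture bundles are
  byte-identical across runs.

What the generator does **not** emulate: dye and spatial artifacts,
intensity-dependent noise, probe cross-hybridization, correlated replicate
structure, RNA-seq counts, and — importantly — indirect regulation chains
longer than one step. Passing tests therefore show that the chain behaves
correctly under its own model assumptions; they do not certify performance
on real arrays, where signal-to-noise and confounding are less kind.

# Problem sizes and tolerances

The test suite runs the full benchmark at 200 genes x 120 compendium
conditions (seconds per network on one core thanks to the blockwise MI) and
the null calibration at 10,000 genes x 40 arrays; exact identities
(partition of unity, order-1 equivalence to hard binning, F = t²,
hypergeometric = one-sided Fisher) are asserted at 1e-10 to 1e-12, and
Monte-Carlo quantities (type-I rate, recovery metrics) at bands derived
from their sampling variance. UPGMA is verified against exhaustive
brute-force agglomeration on up to 6 leaves, where enumeration is cheap and
unambiguous.

# Known limitations

* CLR networks are undirected; the regulator-to-target orientation of the
  planted truth is not recoverable from MI alone.
* Enrichment is a transparent hypergeometric stand-in driven by
  user-supplied GMT files; it does not reproduce any proprietary
  knowledge-base's category system, and heavily overlapping gene sets are
  tested marginally, with no inter-set dependence correction.
* The composite z cutoff of 2.0 is liberal: a few percent of null pairs
  pass it by construction. Interpreting a single thresholded network's edge
  list therefore requires the cross-system intersection (or a truth to
  score against); the intersection is where the false edges fall away,
  because independent noise rarely repeats.
* With few samples (< 20 arrays) the B-spline MI estimator is biased and
  unstable; `mi_matrix()` warns below 4 samples, and compendium-scale input
  (>= 100 conditions) is the intended regime.
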