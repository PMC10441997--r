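---
title: "Methods: quantifying gut-microbiome network stability with microstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gut-microbiome network stability with microstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

`microstab` measures how stable a microbial community is, starting from an
ASV (amplicon sequence variant) count table. It chains together a set of
ecology-standard analyses — signed co-occurrence networks, cohesion,
abundance-weighted extinction cascades, global-efficiency vulnerability, the
Sloan neutral community model, consenTRAIT, Mantel correlograms, and Levins
niche overlap — and ships seeded generators that produce data with the
statistical structure each stage assumes, so the whole pipeline is testable
without sequencing data. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the synthetic
generators do and do not emulate.

## Input data and table hygiene

All stages start from a non-negative integer matrix, taxa in rows, samples in
columns, with unique identifiers on both axes. Rarefaction (`rarefy()`)
subsamples each sample without replacement to a common depth; samples below
the depth are dropped (the conventional choice — resampling shallow samples
with replacement would fabricate reads), and taxon rows are retained even
when rarefied to zero so that taxon identity is stable across stages. The
documented default depth for the mouse-diet dataset the pipeline was built
around is 16,866 reads per sample; synthetic runs choose their own depth.
Rarefaction precedes every stage by default (configurable): diversity indices
require it, and applying it uniformly keeps the neutral-model detection limit
well-defined (one value of reads-per-sample `N` for all samples).

## Co-occurrence networks

Within each sample group, taxa present in fewer than 20% of samples are
removed (rare taxa otherwise contribute spurious perfect correlations), the
table is converted to relative abundances, and all pairwise Spearman
correlations are computed with average-rank ties and p-values from the t
approximation. Benjamini–Hochberg adjustment runs across all tested pairs.
An edge joins two taxa when `|rho| > 0.6` and the adjusted p-value is below
0.01; the signed correlation is kept as the edge weight. The absolute-value
reading of the threshold is deliberate: negative edges are required
downstream, where the sign of an interaction decides whether losing a
partner pushes a taxon toward extinction. Each node carries its group-mean
relative abundance.

Topology metrics (topological coefficient, neighborhood connectivity, local
clustering coefficient) are computed on the unweighted, sign-blind skeleton.
The topological coefficient of a node n with degree k ≥ 2 averages
`J(n, m) / k` over all nodes m sharing at least one neighbor with n, where J
counts shared neighbors plus one if n and m are adjacent; nodes with k < 2
score 0.

Modules come from Clauset–Newman–Moore greedy modularity maximization with
`|rho|` as the edge weight, chosen over Louvain as the default because it is
deterministic given the graph; nodes are pre-sorted lexicographically so the
agglomeration order (the only tie-break) is reproducible, and Louvain remains
available behind the `method` argument with seed control. If the greedy
partition scores below the trivial single-module partition (possible on
near-complete graphs, where the agglomeration stops one merge early), the
single module with Q = 0 is reported instead — no partition should be
reported that is worse than doing nothing. Module hubs are ranked by the
within-module degree z-score; modules of size one, or with zero degree
spread, yield z = 0 rather than an undefined value.

## Cohesion

Cohesion asks how strongly a sample's community is interacting, separately
for positive and negative associations. The backbone is the observed Pearson
correlation between taxa on relative abundances, minus the mean correlation
over 200 taxon-shuffle permutations (each taxon's abundance vector permuted
independently across samples); the subtraction removes correlation expected
from the abundance distributions alone. Pearson is used here — rather than
the Spearman backbone of the network stage — because that is the cohesion
method's own convention; both backbones are arguments. Each taxon's
connectedness is the mean of its strictly positive (respectively strictly
negative) corrected correlations, and a sample's positive (negative)
cohesion is the abundance-weighted sum of connectedness over its taxa. The
negative:positive ratio `|cohesion_neg| / cohesion_pos` is reported per
sample and summarized per group as the median, with per-sample values always
emitted so any other summary can be recomputed.

## Robustness: abundance-weighted extinction cascades

The abundance-weighted mean interaction strength of node i over the live
node set is

wMIS_i = Σ_{j≠i} b_j s_ij / Σ_{j≠i} b_j,

with `b_j` the node's relative abundance, `s_ij` the signed edge weight and
`s_ij = 0` for non-adjacent pairs. After a perturbation removes some nodes,
every node with wMIS ≤ 0 is removed — all of them simultaneously in each
round — and the process repeats until every survivor has strictly positive
wMIS. The simultaneous (synchronous) rule is a deliberate choice: removing
one node at a time can rescue a node whose negative-edge partner dies first,
so the one-at-a-time cascade is order-dependent and reaches a different
fixed point in a noticeable fraction of random instances. Synchronous
removal is order-free and reproducible. Abundances are never rescaled during
the cascade; the wMIS denominator renormalizes automatically.

Robustness is the proportion of original nodes surviving when a fraction
f = 0.5 of nodes is removed uniformly at random (100 repetitions, mean ± SD)
or when the top five module hubs are removed once. Vulnerability uses global
efficiency E, the mean inverse shortest-path length over ordered node pairs
on the unweighted skeleton (disconnected pairs contribute 0; correlation
weights are not distances, so hops are the right metric): node i's
vulnerability is `(E − E_i)/E` with `E_i` the efficiency of the network
without i, computed over the remaining pairs, and the network's
vulnerability is the maximum over nodes.

## The Sloan neutral community model

Under neutral assembly with migration, a taxon with mean relative abundance
p has local abundance distributed approximately Beta(Nm·p, Nm·(1−p)), so its
probability of detection in a sample is `1 − BetaCDF(d; Nm p, Nm(1−p))` for
detection limit d. `fit_ncm()` estimates Nm by least squares of observed
against predicted detection frequency, searching `log10(Nm)` on [−3, 7], and
reports `m = Nm/N` and `R² = 1 − SSE/SST` (negative values are reported
as-is). Confidence intervals and a 95% band come from 1000 bootstrap
resamples of ASVs, and each ASV is classed above/within/below that band.
Note the band reflects uncertainty in the fitted curve, not the scatter of
individual ASVs, so with many ASVs it is narrow and most taxa fall outside
it.

The detection limit defaults to `d = 1/(2N)`, not `1/N`. A censused sample
of N reads detects a taxon whenever its count is at least 1, which under the
continuum approximation corresponds to a latent relative abundance of at
least half a count; attributing the beta mass between `1/(2N)` and `1/N` to
non-detection systematically understates the detection of rare taxa and
inflates the fitted Nm. Against the package's own neutral simulator
(`simulate_neutral_assembly()`, N = 1000, 50 samples, 500 pool taxa) the
half-count limit recovers m within about 10% across m ∈ {0.05, 0.2, 0.6},
whereas `d = 1/N` overshoots by 1.2–2.2×. `d` remains an argument for users
who want the other convention.

## Phylogenetic conservation of responses

Per-ASV responses between two groups are summarized as
`log2((mean_treatment + pc)/(mean_reference + pc))` on counts normalized by
median-of-ratios size factors (geometric-mean reference over taxa with
all-positive counts; total-count scaling as fallback), with pseudocount
pc = 0.5. This is a light substitute for a shrinkage estimator: it gets the
sign and approximate magnitude right at moderate depths, and externally
computed fold changes can be supplied instead wherever a trait table is
accepted.

consenTRAIT measures the phylogenetic depth of a binary trait: maximal
clades in which at least 90% of leaves carry the trait are found by
post-order traversal (once a clade qualifies, nested sub-clades are not
counted again), each clade contributes its mean root-node-to-member path
length, and τ_D averages over clades. Trait-positive leaves falling in no
qualifying clade are treated as undersampled size-1 clades contributing half
their terminal branch length (the conventional choice; an
`include_singletons = FALSE` flag excludes them). Significance is one-sided:
a conserved trait gives a deeper τ_D than leaf-label shuffles, and the
p-value uses add-one smoothing, `(1 + #null ≥ obs)/(1 + permutations)`. The
ensemble variant averages τ_D over bootstrap trees and pools a fixed number
of shuffles per tree into one null.

The Mantel correlogram relates `|magnitude_i − magnitude_j|` (absolute
fold-change difference — magnitudes, not signed values) to phylogenetic
distance. Distances are cut into equal-width classes covering the full
observed range, with the class count set by Sturges' rule; per class, the
statistic is the Pearson correlation between the unfolded difference matrix
and the 0/1 class indicator, so similar responses among close relatives show
up as a *negative* statistic in the shortest class. Significance is a
two-sided joint-label permutation test (999 by default) with progressive
Holm correction across classes in increasing-distance order. This
implementation deliberately differs from correlogram conventions that invert
the sign and truncate at half the maximum distance; the full range is kept
so the classes partition every pair.

## Levins niche breadth and overlap

Resource states default to the samples of a group — the Levins indices are
defined over an abstract resource axis that amplicon data never observes
directly, and a taxon's distribution of abundance across samples is the
usual observable proxy; the choice is configurable and flagged in outputs. Breadth is `B = 1/Σ p_s²` (1 for a point mass, the state count for
uniform usage). Overlap is the asymmetric `O_ij = Σ p_is p_js / Σ p_is²`
with the symmetrized mean reported by default; the product `O_ij O_ji` is
Cauchy–Schwarz-bounded by 1. The group summary is the mean symmetrized
overlap over distinct taxon pairs with positive abundance.

## Synthetic data: what it emulates, and what it cannot

`simulate_correlated_community()` draws a latent multivariate Gaussian with
a block correlation matrix (blocks play the role of network modules),
rank-maps each taxon through a lognormal intensity around its lognormal base
abundance, and samples counts multinomially at fixed depth. Correlation
sign and strength are therefore controlled independently of the abundance
distribution. Indefinite latent matrices are repaired by eigenvalue
clipping; a repair that moves any correlation by more than 0.1 aborts as
infeasible. `simulate_neutral_assembly()` runs the Hubbell death–replacement
process per sample (immigration with probability m per event, local
recruitment otherwise; 100 generations of burn-in by default, which is well
past stationarity for m ≥ 0.05 at N = 1000) with the inner loop in C++.
`simulate_tree_and_traits()` grows Yule trees, paints whole clades
trait-positive (or assigns the trait at random), and evolves response
magnitudes by Brownian motion.

The shipped `reference_scenario()` pair encodes two community archetypes at
identical depth and sample count. *Balanced*: four even-abundance guilds,
strong within-guild cooperation (latent ρ = 0.8) and weak between-guild
competition (ρ = −0.25 — strong enough for the un-thresholded cohesion
backbone to see, too weak to pass the 0.6 edge threshold, so the network
stays four clean modules). *Unbalanced*: two positively co-responding
winner blocks (ρ = 0.8, cross-block ρ = 0.55) whose members are boosted a
full log-unit in base abundance — a bloom of diet-favored taxa that
concentrates community mass and lowers effective richness — over a large
uncorrelated background.

On these conditions the constructed networks reproduce the expected
direction of the modularity, robustness and vulnerability contrasts (the
unbalanced community is less modular, less robust, more vulnerable in ≥ 9
of 10 seed replicates). Two contrasts do **not** reproduce, and the reason
is informative: relative-abundance closure forces every taxon's summed
covariance with the rest to be negative, so a community whose latent
associations are all positive cannot display predominantly positive
relative-abundance correlations — the shared factor is cancelled by
normalization and re-expressed as diffuse negative correlations, which the
cohesion backbone counts as negative connectedness. Under this generator
the unbalanced scenario therefore measures a *higher* negative:positive
cohesion ratio than the balanced one, and the same cancellation dilutes the
winners' shared-usage signal in the Levins overlap contrast (7 of 10
replicates rather than 9). Reproducing those two directions appears to
require features the generator deliberately does not model — per-taxon
dispersion heterogeneity, absolute microbial load (as measured by qPCR),
or taxon-specific responses to a continuous host gradient — so passing the
other checks on synthetic data says nothing about them, and results on real
data should lean on the per-sample outputs rather than these two synthetic
contrasts.

## Reproducibility and numerical conventions

Every stochastic function takes a seed and restores the caller's RNG state.
The pipeline fans one global seed out to per-stage child seeds through a
counter scheme (`child_seed()`), so inserting a stage never shifts another
stage's stream, and two runs with the same configuration and seed are
byte-identical (output files carry no timestamps; numbers are serialized at
10 significant digits; the manifest records file names relative to the
output directory). Degenerate inputs fail loudly and early: duplicate
identifiers, negative or fractional counts, zero-total samples, all-zero
usage vectors, edgeless networks for vulnerability, and constant response
vectors for the correlogram are all hard errors naming the offender.

Problem sizes used by the shipped checks — 60-taxon, 30-sample communities
at depth 10,000; 1000-individual neutral communities over 50 samples;
64-leaf trees — were chosen as the smallest sizes at which each stage's
signal (module recovery, parameter identifiability, clade detection) is
comfortably above its sampling noise; all scale linearly or quadratically
if increased.

## Worked example

```{r example, eval = FALSE}
tab <- simulate_correlated_community(reference_scenario("balanced", seed = 1))
net <- co_network(tab)                       # |rho| > 0.6, q < 0.01
mods <- detect_modules(net)
rob <- robustness(mods$network, "random", f = 0.5, seed = 1)
vul <- vulnerability(net)
coh <- cohesion(tab, seed = 1)
c(modularity = mods$modularity, robustness = rob$mean,
  vulnerability = vul$network_vulnerability, ratio = coh$ratio_median)
```

## Known limitations

- Correlation-based networks inherit compositionality; no SparCC-style
  correction is applied (out of scope), so closure-induced negative
  correlations are part of what cohesion measures.
- The log2-fold response estimator has no dispersion shrinkage; for low
  counts, supply externally estimated fold changes.
- The NCM prediction band quantifies fit uncertainty, not per-ASV scatter.
- Greedy modularity is a heuristic; for large dense networks Louvain with
  multiple seeds may find higher-Q partitions.
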