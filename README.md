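# microstab

Stability analysis of microbial communities from ASV count tables.

Gut microbiomes under dietary or antibiotic stress do not just change
composition — they change *how they are wired*. Communities dominated by
positive associations propagate perturbations through mutual-dependence
loops, while negative associations and modular structure dampen them. This
package quantifies that wiring and its consequences for anyone working with
16S amplicon data (microbial ecologists, microbiome bioinformaticians):
given a taxa × samples count table, sample groups, and optionally a rooted
phylogeny and per-taxon responses, it computes

- **Signed co-occurrence networks** per group (Spearman |ρ| > 0.6,
  BH-adjusted p < 0.01) with topology metrics, Clauset–Newman–Moore
  modularity, and within-module-degree-z module hubs;
- **Cohesion** (Herren–McMahon style): per-taxon connectedness from
  null-model-corrected correlations, per-sample abundance-weighted positive
  and negative cohesion, and the negative:positive ratio;
- **Robustness** under extinction cascades driven by the abundance-weighted
  mean interaction strength, wMIS_i = Σ_{j≠i} b_j s_ij / Σ_{j≠i} b_j: after
  random or hub-targeted node removal, every node with wMIS ≤ 0 is removed
  (synchronously) until all survivors interact positively; robustness is the
  surviving fraction;
- **Vulnerability** from global efficiency E = mean(1/d_ij): the maximal
  relative efficiency drop caused by deleting a single node;
- the **Sloan neutral community model**: detection frequency
  `1 − BetaCDF(d; Nm·p, Nm·(1−p))` fitted to occurrence data, yielding the
  migration rate m with bootstrap CIs and an above/within/below partition;
- **consenTRAIT** (mean phylogenetic depth τ_D of clades where ≥ 90% of
  leaves share a trait, permutation-tested) and **Mantel correlograms** of
  response-magnitude differences against phylogenetic distance;
- **Levins niche breadth and overlap** (B = 1/Σp², O_ij = Σp_i p_j / Σp_i²).

Seeded generators (`simulate_correlated_community()`,
`simulate_neutral_assembly()`, `simulate_tree_and_traits()`) produce count
tables with block-correlated taxa via a Gaussian copula, neutral communities
with known migration rate via Hubbell death–replacement dynamics (C++
inner loop), and Yule trees with clade-conserved traits — so every stage is
exercisable and testable without sequencing data.

## Worked example

```r
library(microstab)

tab  <- simulate_correlated_community(reference_scenario("balanced", seed = 1))
net  <- co_network(tab)                  # 48 nodes, 257 edges
mods <- detect_modules(net)
rob  <- robustness(mods$network, "random", f = 0.5, seed = 1)
vul  <- vulnerability(net)
coh  <- cohesion(tab, seed = 1)

round(c(modularity = mods$modularity, robustness = rob$mean,
        vulnerability = vul$network_vulnerability, ratio = coh$ratio_median), 3)
#>    modularity    robustness vulnerability         ratio
#>         0.748         0.500         0.001         0.469
```

The four planted guilds are recovered as modules (Q = 0.748). Removing half
the nodes at random leaves exactly half alive (robustness 0.500): the
network's edges are all positive, so nobody's wMIS turns negative and only
direct removals die. No single node matters much to global efficiency
(vulnerability 0.001), and per sample, negative cohesion runs at about 47%
of positive cohesion.

Fitting the neutral model to a community assembled at migration rate 0.2:

```r
sim <- simulate_neutral_assembly(neutral_scenario(migration = 0.2, seed = 1))
fit <- fit_ncm(occurrence_stats(sim), N = 1000, seed = 1)
round(c(m = fit$m, R2 = fit$R2), 3)
#>     m    R2
#> 0.177 0.962
```

The fitted migration rate (0.177) recovers the generative value within ~12%,
and the beta-CDF occurrence curve explains 96% of the frequency variance.

The full pipeline — rarefaction, diversity, per-group networks, cohesion,
robustness/vulnerability, neutral model, phylogenetic response tests, niche
overlap — runs from one configuration:

```r
run_pipeline(list(table = "counts.tsv", metadata = "meta.tsv",
                  tree = "tree.nwk", outdir = "out", seed = 1))
```

Each output file carries its stage parameters and seed in a `#` header, and
`out/manifest.json` lists every artifact; identical config + seed gives
byte-identical outputs. A thin command-line wrapper lives in
`inst/scripts/microstab.R`.

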