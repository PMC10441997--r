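test_that("community generator is bit-reproducible and satisfies table invariants", {
  sc <- community_scenario(n_taxa = 20, n_samples = 12, depth = 2000,
                           module_blocks = list(c(6, 0.8), c(6, 0.8)), seed = 7)
  t1 <- simulate_correlated_community(sc)
  t2 <- simulate_correlated_community(sc)
  expect_identical(t1, t2)
  expect_silent(validate_asv_table(t1))
  expect_equal(unname(colSums(t1)), rep(2000, 12))
})

test_that("uncoupled blocks stay uncorrelated, coupled blocks correlate", {
  # The generator's contract is on the latent intensities: with
  # cross_block_correlation = 0 the two blocks are independent there (the
  # count table additionally carries compositional closure, which is
  # deliberately preserved, not a generator artefact).
  sc <- community_scenario(n_taxa = 60, n_samples = 500, depth = 10000,
                           module_blocks = list(c(12, 0.8), c(12, 0.8)),
                           cross_block_correlation = 0, positive_fraction = 1,
                           seed = 3)
  tab <- simulate_correlated_community(sc, return_intensity = TRUE)
  x <- attr(tab, "intensity")
  R <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  between <- R[1:12, 13:24]
  expect_lt(abs(mean(between)), 0.05)
  expect_gt(mean(R[1:12, 1:12][upper.tri(diag(12))]), 0.6)
  sc2 <- community_scenario(n_taxa = 40, n_samples = 200, depth = 10000,
                            module_blocks = list(c(12, 0.8), c(12, 0.8)),
                            positive_fraction = 1, seed = 4)
  tab2 <- simulate_correlated_community(sc2)
  R2 <- suppressWarnings(stats::cor(t(to_relative_abundance(tab2)),
                                    method = "spearman"))
  within <- c(R2[1:12, 1:12][upper.tri(matrix(0, 12, 12))],
              R2[13:24, 13:24][upper.tri(matrix(0, 12, 12))])
  expect_gt(mean(within), 0.4)
})

test_that("infeasible latent correlation matrices are refused", {
  sc <- community_scenario(module_blocks = list(c(10, 0.9), c(10, 0.9),
                                                c(10, 0.9), c(10, 0.9)),
                           cross_block_correlation = -0.6, n_taxa = 40)
  expect_error(simulate_correlated_community(sc), "infeasible")
  # a mildly indefinite matrix is repaired with a warning instead
  sc_ok <- community_scenario(module_blocks = list(c(10, 0.9), c(10, 0.9),
                                                   c(10, 0.9), c(10, 0.9)),
                              cross_block_correlation = -0.32, n_taxa = 40)
  expect_warning(simulate_correlated_community(sc_ok), "repaired")
  expect_error(community_scenario(module_blocks = list(c(5, 1.2))), "\\[-1, 1\\]")
})

test_that("neutral assembly reproduces its limit behaviours", {
  # m -> 1: local community is a fresh metacommunity draw every event
  p <- rep(1 / 20, 20)
  ns <- neutral_scenario(metacommunity_taxa = 20, metacommunity_abundances = p,
                         local_size = 10000, migration = 0.999, burn_in = 5,
                         n_samples = 1, seed = 2)
  tab <- simulate_neutral_assembly(ns)
  gof <- suppressWarnings(stats::chisq.test(tab[, 1], p = p))
  expect_gt(gof$p.value, 0.01)
  # m -> 0 with long burn-in: drift to near-fixation
  ns0 <- neutral_scenario(metacommunity_taxa = 50, local_size = 100,
                          migration = 0.001, burn_in = 2000, n_samples = 10,
                          seed = 5)
  tab0 <- simulate_neutral_assembly(ns0)
  dom <- apply(tab0, 2, max) / colSums(tab0)
  expect_gte(mean(dom > 0.9), 0.8)
  # bit-reproducible
  expect_identical(simulate_neutral_assembly(ns0), simulate_neutral_assembly(ns0))
})

test_that("trait generator places conserved clades and Brownian magnitudes", {
  sim <- simulate_tree_and_traits(trait_scenario(n_leaves = 64, seed = 9))
  expect_identical(sort(sim$tree$tip.label), sort(sim$traits$taxon))
  expect_equal(length(consentrait(sim$tree,
    stats::setNames(sim$traits$trait, sim$traits$taxon),
    permutations = 0 + 10, seed = 1)$clades$size), 2)
  expect_true(sum(sim$traits$trait) >= 10 && sum(sim$traits$trait) <= 24)
  # conserved traits are detected by the clade-depth test
  ct <- consentrait(sim$tree,
                    stats::setNames(sim$traits$trait, sim$traits$taxon),
                    permutations = 200, seed = 1)
  expect_lt(ct$p_value, 0.05)
  # Brownian magnitudes: pair differences grow with phylogenetic distance
  sim2 <- simulate_tree_and_traits(trait_scenario(n_leaves = 128, seed = 10))
  D <- ape::cophenetic.phylo(sim2$tree)
  mag <- stats::setNames(sim2$traits$magnitude, sim2$traits$taxon)
  M <- response_diff_matrix(mag[rownames(D)])
  lower <- lower.tri(D)
  ts <- suppressWarnings(stats::cor.test(D[lower], M[lower], method = "spearman"))
  expect_gt(ts$estimate, 0)
  expect_lt(ts$p.value, 0.05)
  # too many clades requested
  expect_error(simulate_tree_and_traits(
    trait_scenario(n_leaves = 16, n_positive_clades = 8, clade_size = 8)),
    "disjoint clades")
})

test_that("random traits give calibrated (uniform) clade-depth p-values", {
  # null calibration at reduced scale; the acceptance suite runs the full one
  pvals <- vapply(1:60, function(r) {
    sim <- simulate_tree_and_traits(
      trait_scenario(n_leaves = 32, trait_mode = "random", trait_prob = 0.3,
                     seed = 1000 + r))
    consentrait(sim$tree, stats::setNames(sim$traits$trait, sim$traits$taxon),
                permutations = 99, seed = r)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
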