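test_that("log2-fold responses match a hand-computed median-of-ratios pipeline", {
  counts <- asv_table(matrix(c(10L, 20L, 12L, 40L, 44L, 36L,
                               5L,  6L,  7L, 5L,  6L,  4L,
                               100L, 90L, 110L, 50L, 60L, 55L), nrow = 3,
                             byrow = TRUE,
                             dimnames = list(c("up", "flat", "down"),
                                             paste0("s", 1:6))))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("ref", "trt"), each = 3))
  tt <- log2_fold_response(counts, meta, "ref", "trt", pseudocount = 0.5)
  # hand pipeline
  lgm <- rowMeans(log(counts))
  sf <- apply(counts, 2, function(col) exp(stats::median(log(col) - lgm)))
  norm <- sweep(counts, 2, sf, "/")
  expected <- log2((rowMeans(norm[, 4:6]) + 0.5) / (rowMeans(norm[, 1:3]) + 0.5))
  expect_equal(tt$log2_fold_ratio, unname(expected), tolerance = 1e-10)
  expect_equal(tt$direction, ifelse(expected > 0, "positive", "negative"),
               ignore_attr = TRUE)
  expect_equal(tt$magnitude, unname(abs(expected)))
  expect_error(log2_fold_response(counts, meta[1:4, ], "ref", "trt"),
               "at least 3")
})

test_that("identical groups give zero response; doubling gives ~1", {
  set.seed(2)
  base <- matrix(rpois(11 * 6, 200), 11, 6,
                 dimnames = list(paste0("t", 1:11), paste0("s", 1:6)))
  both <- cbind(base, base)
  colnames(both) <- paste0("s", 1:12)
  tab <- asv_table(both)
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     group = rep(c("a", "b"), each = 6))
  tt <- log2_fold_response(tab, meta, "a", "b")
  expect_equal(tt$log2_fold_ratio, rep(0, 11))
  # one taxon exactly doubled at high counts: ratio ~ 1 after renormalization
  tab2 <- tab
  tab2["t1", 7:12] <- tab2["t1", 7:12] * 2L
  tt2 <- log2_fold_response(tab2, meta, "a", "b")
  expect_equal(tt2$log2_fold_ratio[tt2$taxon == "t1"], 1, tolerance = 0.05)
})

test_that("tau_D is forced on symmetric and degenerate trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  res <- consentrait(tr, c(A = 1, B = 1, C = 0, D = 0), permutations = 50,
                     seed = 1)
  expect_equal(res$tau_D, 1)              # one clade, node-to-leaf distance 1
  expect_equal(nrow(res$clades), 1)
  # trait on every leaf: single clade at the root, depth = root-to-leaf mean
  res_all <- consentrait(tr, c(A = 1, B = 1, C = 1, D = 1), permutations = 10,
                         seed = 1)
  expect_equal(res_all$tau_D, 2)
  expect_error(consentrait(tr, c(A = 0, B = 0, C = 0, D = 0)), "positive")
  expect_error(consentrait(tr, c(A = 1, B = 1, X = 0, D = 0)), "match")
})

test_that("singleton positives contribute half their terminal branch", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:3,D:1):1);")
  # A,B form a clade (depth 1); C is a lone positive -> half of 3
  res <- consentrait(tr, c(A = 1, B = 1, C = 1, D = 0), permutations = 10,
                     seed = 1)
  expect_equal(res$tau_D, mean(c(1, 1.5)))
  expect_equal(res$n_singletons, 1)
  res_nos <- consentrait(tr, c(A = 1, B = 1, C = 1, D = 0), permutations = 10,
                         seed = 1, include_singletons = FALSE)
  expect_equal(res_nos$tau_D, 1)
})

test_that("tau_D scales linearly with branch lengths and ignores leaf order", {
  sim <- simulate_tree_and_traits(trait_scenario(n_leaves = 32, seed = 12))
  trait <- stats::setNames(sim$traits$trait, sim$traits$taxon)
  r1 <- consentrait(sim$tree, trait, permutations = 30, seed = 2)
  tr_scaled <- sim$tree
  tr_scaled$edge.length <- tr_scaled$edge.length * 3
  r3 <- consentrait(tr_scaled, trait, permutations = 30, seed = 2)
  expect_equal(r3$tau_D, 3 * r1$tau_D)
  r_shuf <- consentrait(sim$tree, trait[sample(names(trait))],
                        permutations = 30, seed = 2)
  expect_equal(r_shuf$tau_D, r1$tau_D)
})

test_that("the tree ensemble pools nulls and degenerates to the single tree", {
  sim <- simulate_tree_and_traits(trait_scenario(n_leaves = 32, seed = 14))
  trait <- stats::setNames(sim$traits$trait, sim$traits$taxon)
  ens <- consentrait_ensemble(rep(list(sim$tree), 4), trait,
                              permutations_per_tree = 25, seed = 3)
  single <- consentrait(sim$tree, trait, permutations = 100, seed = 3)
  expect_equal(ens$tau_D, single$tau_D)
  expect_equal(ens$n_permutations, 100)   # 4 trees x 25
  tr2 <- ape::rphylo(10, 1, 0)
  expect_error(consentrait_ensemble(list(sim$tree, tr2), trait), "mismatched")
})

test_that("mantel correlogram respects its class partition and invariances", {
  sim <- simulate_tree_and_traits(trait_scenario(n_leaves = 40, seed = 21))
  D <- ape::cophenetic.phylo(sim$tree)
  mag <- stats::setNames(sim$traits$magnitude, sim$traits$taxon)[rownames(D)]
  M <- response_diff_matrix(mag)
  mc <- mantel_correlogram(D, M, permutations = 99, seed = 5)
  lower <- lower.tri(D)
  expect_equal(sum(mc$classes$n_pairs), sum(lower))
  expect_equal(min(mc$classes$lower), min(D[lower]))
  expect_equal(max(mc$classes$upper), max(D[lower]))
  expect_true(all(abs(mc$classes$r) <= 1, na.rm = TRUE))
  # joint relabeling of both matrices leaves every statistic unchanged
  perm <- sample(nrow(D))
  mc2 <- mantel_correlogram(D[perm, perm], M[perm, perm],
                            permutations = 99, seed = 5)
  expect_equal(mc2$classes$r, mc$classes$r)
  expect_error(mantel_correlogram(D, M * 0, permutations = 9), "constant")
  # a Brownian response on a structured tree: closest pairs differ least,
  # so the shortest class carries a negative statistic
  expect_lt(mc$classes$r[1], 0)
})

test_that("mantel statistic agrees with the classic matrix-correlation oracle", {
  sim <- simulate_tree_and_traits(trait_scenario(n_leaves = 24, seed = 31))
  D <- ape::cophenetic.phylo(sim$tree)
  mag <- stats::setNames(sim$traits$magnitude, sim$traits$taxon)[rownames(D)]
  M <- response_diff_matrix(mag)
  mc <- mantel_correlogram(D, M, n_classes = 4, permutations = 19, seed = 2)
  lower <- lower.tri(D)
  cls <- cut(D[lower], seq(min(D[lower]), max(D[lower]), length.out = 5),
             include.lowest = TRUE, labels = FALSE)
  for (k in 1:4) {
    ind <- matrix(0, nrow(D), ncol(D))
    ind[lower][cls == k] <- 1
    ind <- ind + t(ind)
    if (sum(ind) == 0 || all(ind[lower] == 1)) next
    ve <- vegan::mantel(as.dist(M), as.dist(ind), permutations = 0)
    expect_equal(mc$classes$r[k], unname(ve$statistic), tolerance = 1e-12)
  }
})
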