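#' Scenario for a block-correlated compositional community
#'
#' Describes a synthetic community whose taxa fall into correlated blocks
#' (the latent analogue of network modules). Counts are produced by a
#' Gaussian copula: a latent multivariate normal with the block correlation
#' matrix is rank-mapped through lognormal per-sample intensities and then
#' multinomially sampled at the target depth, so correlation sign/strength is
#' controlled independently of the abundance distribution.
#'
#' Negative associations are induced by giving each block taxon a latent sign:
#' two taxa correlate positively when their signs agree and negatively
#' otherwise; signs are assigned so the achieved fraction of positive
#' correlated pairs is as close as possible to `positive_fraction`.
#'
#' @param n_taxa Total taxa (block taxa plus uncorrelated background taxa).
#' @param n_samples Samples to draw.
#' @param depth Reads per sample (multinomial size).
#' @param module_blocks List of `c(size, correlation)` pairs, one per block.
#' @param cross_block_correlation Latent correlation between taxa of different
#'   blocks (signed through the same latent signs).
#' @param positive_fraction Target fraction of correlated pairs that are
#'   positive.
#' @param meanlog,sdlog Lognormal parameters of the taxon base-abundance
#'   distribution (the species abundance distribution); larger `sdlog` means
#'   stronger dominance, i.e. fewer effective taxa.
#' @param block_abundance_boost Added to `meanlog` for block taxa only:
#'   positive values make the correlated blocks the dominant community
#'   members (a bloom of co-responding taxa), concentrating mass there and
#'   lowering effective richness without inflating random background taxa.
#' @param sample_sdlog Lognormal sd of per-sample intensity variation around
#'   each taxon's base abundance (the channel through which the latent
#'   correlation becomes observable).
#' @param seed Integer seed.
#' @return A list of class `community_scenario`.
#' @export
community_scenario <- function(n_taxa = 60, n_samples = 30, depth = 10000,
                               module_blocks = list(c(12, 0.8), c(12, 0.8),
                                                    c(12, 0.8), c(12, 0.8)),
                               cross_block_correlation = 0,
                               positive_fraction = 0.7,
                               meanlog = 0, sdlog = 1, sample_sdlog = 1,
                               block_abundance_boost = 0, seed = 1) {
  blocks <- lapply(module_blocks, function(b) c(size = b[[1]], rho = b[[2]]))
  rhos <- c(vapply(blocks, `[[`, 0, "rho"), cross_block_correlation)
  if (any(abs(rhos) > 1)) stopf("correlations must lie in [-1, 1]")
  if (sum(vapply(blocks, `[[`, 0, "size")) > n_taxa)
    stopf("module blocks contain more taxa than n_taxa")
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("positive_fraction must lie in [0, 1]")
  structure(list(n_taxa = n_taxa, n_samples = n_samples, depth = depth,
                 module_blocks = blocks,
                 cross_block_correlation = cross_block_correlation,
                 positive_fraction = positive_fraction,
                 meanlog = meanlog, sdlog = sdlog, sample_sdlog = sample_sdlog,
                 block_abundance_boost = block_abundance_boost, seed = seed),
            class = "community_scenario")
}

# latent signs for one block so that the fraction of positive within-block
# pairs approximates the target
block_signs <- function(k, positive_fraction) {
  if (k < 2) return(rep(1, k))
  npairs <- choose(k, 2)
  frac <- vapply(0:k, function(kp) (choose(kp, 2) + choose(k - kp, 2)) / npairs, 0)
  kp <- which.min(abs(frac - positive_fraction)) - 1L
  # of the assignments tying on achieved fraction, prefer the majority-positive one
  if (frac[k - kp + 1L] == frac[kp + 1L] && (k - kp) > kp) kp <- k - kp
  c(rep(1, kp), rep(-1, k - kp))
}

# latent correlation matrix implied by a community_scenario (block taxa only)
latent_correlation <- function(scenario) {
  sizes <- vapply(scenario$module_blocks, `[[`, 0, "size")
  nb <- sum(sizes)
  block_of <- rep(seq_along(sizes), sizes)
  C0 <- matrix(scenario$cross_block_correlation, nb, nb)
  for (b in seq_along(sizes)) {
    idx <- which(block_of == b)
    C0[idx, idx] <- scenario$module_blocks[[b]]["rho"]
  }
  g <- unlist(lapply(sizes, block_signs, positive_fraction = scenario$positive_fraction))
  C <- C0 * tcrossprod(g)
  diag(C) <- 1
  list(C = C, signs = g, block_of = block_of)
}

# clip negative eigenvalues and rescale to unit diagonal; error if the repair
# moves any entry by more than 0.1
repair_psd <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) >= -1e-10) return(C)
  vals <- pmax(eg$values, 0)
  R <- eg$vectors %*% (vals * t(eg$vectors))
  R <- stats::cov2cor(R)
  shift <- max(abs(R - C))
  if (shift > 0.1)
    stopf("scenario infeasible: PSD repair changes a correlation by %.3f (> 0.1)", shift)
  warnf("latent correlation matrix repaired by eigenvalue clipping (max change %.3g)", shift)
  R
}

#' Simulate a block-correlated community count table
#'
#' @param scenario A [community_scenario()].
#' @param return_intensity Attach the latent per-sample intensity matrix
#'   (before compositional closure and multinomial sampling) as
#'   `attr(, "intensity")` -- useful for diagnosing how much observed
#'   correlation structure is generative vs closure-induced.
#' @return ASV table (taxa x samples integer matrix); taxa are named
#'   `taxon_<block><i>` for block members and `taxon_bg<i>` for background.
#' @seealso [community_scenario()] for the generative model.
#' @export
simulate_correlated_community <- function(scenario, return_intensity = FALSE) {
  stopifnot(inherits(scenario, "community_scenario"))
  lat <- latent_correlation(scenario)
  nb <- nrow(lat$C)
  n_bg <- scenario$n_taxa - nb
  C <- repair_psd(lat$C)
  L <- chol(C + diag(1e-8, nb))
  mlog <- rep(scenario$meanlog, scenario$n_taxa)
  mlog[seq_len(nb)] <- mlog[seq_len(nb)] + scenario$block_abundance_boost
  with_seed(scenario$seed, {
    base <- stats::rlnorm(scenario$n_taxa, mlog, scenario$sdlog)
    Z <- matrix(stats::rnorm(scenario$n_samples * nb), scenario$n_samples, nb) %*% L
    Zbg <- matrix(stats::rnorm(scenario$n_samples * n_bg), scenario$n_samples, n_bg)
    U <- stats::pnorm(cbind(Z, Zbg))
    intensity <- sweep(stats::qlnorm(U, 0, scenario$sample_sdlog), 2, base, "*")
    counts <- apply(intensity, 1, function(x) stats::rmultinom(1, scenario$depth, x / sum(x)))
  })
  within_idx <- as.integer(stats::ave(lat$block_of, lat$block_of, FUN = seq_along))
  rownames(counts) <- c(sprintf("taxon_b%d_%d", lat$block_of, within_idx),
                        if (n_bg > 0) sprintf("taxon_bg%d", seq_len(n_bg)))
  colnames(counts) <- sprintf("sample_%d", seq_len(scenario$n_samples))
  out <- asv_table(counts)
  if (return_intensity) {
    intensity <- t(intensity)
    dimnames(intensity) <- dimnames(out)
    attr(out, "intensity") <- intensity
  }
  out
}

#' Scenario for neutral community assembly
#'
#' @param metacommunity_taxa Number of taxa in the source pool.
#' @param metacommunity_abundances Optional relative abundance vector for the
#'   pool; defaults to a seeded lognormal draw (sdlog 1.5), normalized.
#' @param local_size Individuals per local community (N).
#' @param migration Immigration probability m in (0, 1): at each
#'   death-replacement event the replacement is an immigrant with probability
#'   m, otherwise locally recruited.
#' @param burn_in Generations (of N events each) before reading off counts.
#' @param n_samples Independent local communities to simulate.
#' @param seed Integer seed.
#' @return A list of class `neutral_scenario`.
#' @export
neutral_scenario <- function(metacommunity_taxa = 500,
                             metacommunity_abundances = NULL,
                             local_size = 1000, migration = 0.2,
                             burn_in = 100, n_samples = 50, seed = 1) {
  if (migration <= 0 || migration >= 1) stopf("migration m must lie in (0, 1)")
  if (local_size < 10) stopf("local_size must be at least 10")
  if (!is.null(metacommunity_abundances)) {
    if (length(metacommunity_abundances) != metacommunity_taxa)
      stopf("metacommunity_abundances length must equal metacommunity_taxa")
    if (any(metacommunity_abundances < 0) || sum(metacommunity_abundances) <= 0)
      stopf("metacommunity_abundances must be non-negative with positive sum")
    metacommunity_abundances <- metacommunity_abundances / sum(metacommunity_abundances)
  }
  structure(list(metacommunity_taxa = metacommunity_taxa,
                 metacommunity_abundances = metacommunity_abundances,
                 local_size = local_size, migration = migration,
                 burn_in = burn_in, n_samples = n_samples, seed = seed),
            class = "neutral_scenario")
}

#' Simulate neutral local communities (Hubbell death-replacement)
#'
#' Each sample is an independent local community of `local_size` individuals,
#' initialized by a multinomial draw from the metacommunity and evolved for
#' `burn_in` generations of single-individual death-replacement events, with
#' immigration probability `migration` per event.
#'
#' @param scenario A [neutral_scenario()].
#' @return ASV table (metacommunity taxa x samples); column sums equal
#'   `local_size`.
#' @export
simulate_neutral_assembly <- function(scenario) {
  stopifnot(inherits(scenario, "neutral_scenario"))
  K <- scenario$metacommunity_taxa
  N <- scenario$local_size
  with_seed(scenario$seed, {
    p <- scenario$metacommunity_abundances
    if (is.null(p)) {
      p <- stats::rlnorm(K, 0, 1.5)
      p <- p / sum(p)
    }
    cum <- cumsum(p)
    cum[K] <- 1
    steps <- scenario$burn_in * N
    counts <- vapply(seq_len(scenario$n_samples), function(s) {
      comm <- sample.int(K, N, replace = TRUE, prob = p) - 1L
      comm <- neutral_moran_steps(comm, cum, scenario$migration, steps)
      tabulate(comm + 1L, nbins = K)
    }, integer(K))
  })
  dimnames(counts) <- list(sprintf("taxon_%d", seq_len(K)),
                           sprintf("sample_%d", seq_len(scenario$n_samples)))
  asv_table(counts)
}

#' Scenario for a tree with binary traits and continuous response magnitudes
#'
#' @param n_leaves Leaves of the Yule tree.
#' @param birth_rate Yule birth rate (branch-length scale).
#' @param trait_mode `"clade_conserved"` marks every leaf of
#'   `n_positive_clades` internal clades trait-positive; `"random"` assigns
#'   the trait independently with probability `trait_prob`.
#' @param n_positive_clades,clade_size Number and approximate leaf count of
#'   conserved clades.
#' @param trait_prob Positive-trait probability in random mode.
#' @param bm_sigma Brownian-motion standard deviation per unit branch length
#'   for the response magnitudes.
#' @param seed Integer seed.
#' @return A list of class `trait_scenario`.
#' @export
trait_scenario <- function(n_leaves = 64, birth_rate = 1,
                           trait_mode = c("clade_conserved", "random"),
                           n_positive_clades = 2, clade_size = 8,
                           trait_prob = 0.3, bm_sigma = 1, seed = 1) {
  trait_mode <- match.arg(trait_mode)
  structure(list(n_leaves = n_leaves, birth_rate = birth_rate,
                 trait_mode = trait_mode, n_positive_clades = n_positive_clades,
                 clade_size = clade_size, trait_prob = trait_prob,
                 bm_sigma = bm_sigma, seed = seed),
            class = "trait_scenario")
}

#' Simulate a Yule tree with clade-conserved (or random) traits
#'
#' Response magnitudes evolve by Brownian motion along the branches, so
#' closely related leaves get similar magnitudes; the binary trait is either
#' painted onto whole clades (conserved mode) or assigned independently
#' (random mode).
#'
#' @param scenario A [trait_scenario()].
#' @return List with `tree` (an `ape` phylo) and `traits` (data.frame with
#'   columns `taxon`, `trait` in \{0, 1\}, `magnitude`).
#' @export
simulate_tree_and_traits <- function(scenario) {
  stopifnot(inherits(scenario, "trait_scenario"))
  with_seed(scenario$seed, {
    tree <- ape::rphylo(scenario$n_leaves, birth = scenario$birth_rate, death = 0)
    magnitude <- as.numeric(ape::rTraitCont(tree, model = "BM", sigma = scenario$bm_sigma))
    n <- scenario$n_leaves
    trait <- integer(n)
    if (scenario$trait_mode == "random") {
      trait <- stats::rbinom(n, 1, scenario$trait_prob)
    } else {
      clades <- ape::prop.part(tree)              # leaf sets of internal nodes
      sizes <- lengths(clades)
      ord <- order(abs(sizes - scenario$clade_size), sizes)
      chosen <- list()
      for (i in ord) {
        if (sizes[i] < 2 || sizes[i] >= n) next
        if (any(vapply(chosen, function(cl) length(intersect(cl, clades[[i]])) > 0, TRUE))) next
        chosen <- c(chosen, list(clades[[i]]))
        if (length(chosen) == scenario$n_positive_clades) break
      }
      if (length(chosen) < scenario$n_positive_clades)
        stopf("cannot place %d disjoint clades of ~%d leaves on a %d-leaf tree",
              scenario$n_positive_clades, scenario$clade_size, n)
      trait[unlist(chosen)] <- 1L
    }
  })
  list(tree = tree,
       traits = data.frame(taxon = tree$tip.label, trait = trait,
                           magnitude = magnitude, stringsAsFactors = FALSE))
}

#' Shipped scenario pair: balanced vs unbalanced community
#'
#' Two ready-made [community_scenario()]s at identical depth and sample count,
#' mirroring the contrast between a diverse, modular, competition-rich
#' community (`balanced`) and a dominance-skewed, positively coupled one
#' (`unbalanced`). Balanced: even abundances and internally cooperative
#' guilds (blocks) that compete weakly with each other (negative cross-block
#' coupling, too weak to pass the edge threshold but visible to cohesion).
#' Unbalanced: stronger dominance (fewer effective taxa), all associations
#' positive, and strong positive cross-block coupling that blurs module
#' boundaries.
#'
#' @param which `"balanced"` or `"unbalanced"`.
#' @param seed Integer seed forwarded to the scenario.
#' @return A [community_scenario()].
#' @export
reference_scenario <- function(which = c("balanced", "unbalanced"), seed = 1) {
  which <- match.arg(which)
  if (which == "balanced") {
    community_scenario(n_taxa = 60, n_samples = 30, depth = 10000,
                       module_blocks = list(c(12, 0.8), c(12, 0.8), c(12, 0.8), c(12, 0.8)),
                       cross_block_correlation = -0.25, positive_fraction = 1,
                       meanlog = 0, sdlog = 1, sample_sdlog = 1, seed = seed)
  } else {
    community_scenario(n_taxa = 60, n_samples = 30, depth = 10000,
                       module_blocks = list(c(12, 0.8), c(12, 0.8)),
                       cross_block_correlation = 0.55, positive_fraction = 1,
                       meanlog = 0, sdlog = 1, sample_sdlog = 1,
                       block_abundance_boost = 1, seed = seed)
  }
}
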