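#' Per-ASV log2-fold response between two groups
#'
#' A light normalized fold-change estimator: counts are scaled by
#' median-of-ratios size factors (geometric-mean reference over taxa with
#' all-positive counts, the DESeq-style normalization), group means are
#' taken, and the response is
#' `log2((mean_treatment + pc) / (mean_reference + pc))` with pseudocount
#' `pc`. It is a substitute for a full shrinkage estimator; externally
#' computed per-ASV log2-fold ratios can be supplied to the downstream
#' phylogenetic tests instead.
#'
#' @param counts ASV table covering both groups.
#' @param meta Metadata data.frame (`sample_id`, `group`).
#' @param reference_group,treatment_group Group labels to contrast.
#' @param pseudocount Added to both normalized group means (default 0.5).
#' @return data.frame (trait table) with `taxon`, `log2_fold_ratio`,
#'   `direction` (`"positive"` iff ratio > 0), `magnitude` (absolute ratio).
#' @export
log2_fold_response <- function(counts, meta, reference_group, treatment_group,
                               pseudocount = 0.5) {
  validate_asv_table(counts)
  ref_s <- meta$sample_id[meta$group == reference_group]
  trt_s <- meta$sample_id[meta$group == treatment_group]
  if (length(ref_s) < 3 || length(trt_s) < 3)
    stopf("both groups need at least 3 samples")
  sub <- counts[, c(ref_s, trt_s), drop = FALSE]
  allpos <- rowSums(sub == 0) == 0
  if (any(allpos)) {
    lgm <- rowMeans(log(sub[allpos, , drop = FALSE]))
    sf <- apply(sub[allpos, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - lgm)))
  } else {
    warnf("no taxon with all-positive counts; falling back to total-count size factors")
    tot <- colSums(sub)
    sf <- tot / mean(tot)
  }
  norm <- sweep(sub, 2, sf, "/")
  m_ref <- rowMeans(norm[, ref_s, drop = FALSE])
  m_trt <- rowMeans(norm[, trt_s, drop = FALSE])
  ratio <- log2((m_trt + pseudocount) / (m_ref + pseudocount))
  data.frame(taxon = rownames(counts), log2_fold_ratio = ratio,
             direction = ifelse(ratio > 0, "positive", "negative"),
             magnitude = abs(ratio), row.names = NULL, stringsAsFactors = FALSE)
}

# Precompute clade bookkeeping for fast repeated tau_D evaluation:
# tip-x-internal-node membership, clade sizes, mean root-node-to-member
# distances, a strict-ancestor incidence matrix, and terminal branch lengths.
consentrait_prep <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nall <- ntip + nnode
  depth <- ape::node.depth.edgelength(tree)       # root-to-node path length
  parent <- integer(nall)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # membership via postorder accumulation
  M <- matrix(FALSE, ntip, nall)
  M[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    M[, po[e, 1]] <- M[, po[e, 1]] | M[, po[e, 2]]
  size <- colSums(M)
  meandist <- (colSums(M * depth[seq_len(ntip)]) / size) - depth
  # strict-ancestor incidence: Anc[v, u] = 1 iff u is a strict ancestor of v
  Anc <- matrix(0, nall, nall)
  cw <- ape::reorder.phylo(tree, "cladewise")$edge # parents before children
  for (e in seq_len(nrow(cw))) {
    p <- cw[e, 1]; v <- cw[e, 2]
    Anc[v, ] <- Anc[p, ]
    Anc[v, p] <- 1
  }
  tipbranch <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  internal <- (ntip + 1L):nall
  list(ntip = ntip, internal = internal, M = M, size = size,
       meandist = meandist, Anc = Anc, tipbranch = tipbranch,
       tips = tree$tip.label)
}

# tau_D for one binary trait vector (tip order); returns NA if no clade
tau_d_eval <- function(prep, trait, share_threshold, include_singletons) {
  counts <- as.numeric(crossprod(prep$M, trait))
  qualify <- logical(prep$ntip + length(prep$internal) )
  qualify[prep$internal] <- counts[prep$internal] / prep$size[prep$internal] >= share_threshold
  covered <- as.numeric(prep$Anc %*% qualify) > 0
  maximal <- prep$internal[qualify[prep$internal] & !covered[prep$internal]]
  depths <- prep$meandist[maximal]
  if (include_singletons) {
    single <- which(trait > 0 & !covered[seq_len(prep$ntip)] & !qualify[seq_len(prep$ntip)])
    # a positive tip outside every qualifying clade counts as a size-1 clade
    depths <- c(depths, 0.5 * prep$tipbranch[single])
  }
  if (!length(depths)) return(NA_real_)
  mean(depths)
}

#' consenTRAIT: phylogenetic depth of trait conservation
#'
#' Identifies the maximal (outermost) clades in which at least
#' `share_threshold` of the leaves carry the trait, measures each clade's
#' mean root-node-to-member path length, and averages over clades:
#' `tau_D = (1/n) sum_j (1/m_j) sum_i d(S_i, R_j)`. Positive leaves that
#' fall in no qualifying clade (singletons, attributed to undersampling)
#' contribute half their terminal branch length as size-1 clades.
#' Significance is a one-sided upper-tail permutation test: conserved traits
#' yield deeper tau_D than the null of randomly shuffled leaf labels.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param trait Binary vector (0/1), named by leaf or in tip-label order.
#' @param share_threshold Minimum trait-positive fraction for a clade
#'   (default 0.9).
#' @param permutations Label permutations for the null (default 1000).
#' @param seed Integer seed.
#' @param include_singletons Count unplaced positive leaves as size-1 clades
#'   (default TRUE).
#' @return List of class `consentrait_result`: `tau_D`, `clades` (data.frame
#'   with clade root node, size, mean depth), `n_singletons`, `null`
#'   (permutation tau_D values), `p_value`, `n_permutations`.
#' @export
consentrait <- function(tree, trait, share_threshold = 0.9, permutations = 1000,
                        seed = 1, include_singletons = TRUE) {
  trait <- align_trait(tree, trait)
  if (sum(trait) == 0) stopf("no trait-positive leaf")
  prep <- consentrait_prep(tree)
  obs <- tau_d_eval(prep, trait, share_threshold, include_singletons)
  null <- with_seed(seed, vapply(seq_len(permutations), function(i)
    tau_d_eval(prep, sample(trait), share_threshold, include_singletons), 0))
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + permutations)
  # describe the observed clades
  counts <- as.numeric(crossprod(prep$M, trait))
  qualify <- logical(ncol(prep$M))
  qualify[prep$internal] <- counts[prep$internal] / prep$size[prep$internal] >= share_threshold
  covered <- as.numeric(prep$Anc %*% qualify) > 0
  maximal <- prep$internal[qualify[prep$internal] & !covered[prep$internal]]
  single <- which(trait > 0 & !covered[seq_len(prep$ntip)])
  clades <- data.frame(node = maximal, size = prep$size[maximal],
                       mean_depth = prep$meandist[maximal])
  structure(list(tau_D = obs, clades = clades,
                 n_singletons = if (include_singletons) length(single) else 0L,
                 null = null, p_value = p, n_permutations = permutations,
                 share_threshold = share_threshold, seed = seed),
            class = "consentrait_result")
}

align_trait <- function(tree, trait) {
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    extra <- setdiff(names(trait), tree$tip.label)
    if (length(missing) || length(extra))
      stopf("trait names do not match tree leaves (missing: %s; extra: %s)",
            paste(utils::head(missing, 3), collapse = ","),
            paste(utils::head(extra, 3), collapse = ","))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stopf("trait length %d does not match %d leaves", length(trait),
          length(tree$tip.label))
  }
  as.numeric(trait > 0)
}

#' consenTRAIT over an ensemble of (bootstrap) trees
#'
#' The observed `tau_D` is the mean single-tree `tau_D` over the trees; the
#' permutation null pools `permutations_per_tree` label shuffles from each
#' tree (e.g. 100 trees x 10 = a 1000-draw null).
#'
#' @param trees List of `phylo` trees with identical leaf sets.
#' @param trait Binary trait named by leaf.
#' @param permutations_per_tree Null draws per tree (default 10).
#' @inheritParams consentrait
#' @return A `consentrait_result` with the pooled null.
#' @export
consentrait_ensemble <- function(trees, trait, share_threshold = 0.9,
                                 permutations_per_tree = 10, seed = 1,
                                 include_singletons = TRUE) {
  if (!length(trees)) stopf("need at least one tree")
  leafsets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (!all(vapply(leafsets, identical, TRUE, leafsets[[1]])))
    stopf("trees have mismatched leaf sets")
  obs <- numeric(length(trees))
  null <- numeric(0)
  with_seed(seed, {
    for (k in seq_along(trees)) {
      tr <- trees[[k]]
      trt <- align_trait(tr, trait)
      prep <- consentrait_prep(tr)
      obs[k] <- tau_d_eval(prep, trt, share_threshold, include_singletons)
      null <- c(null, vapply(seq_len(permutations_per_tree), function(i)
        tau_d_eval(prep, sample(trt), share_threshold, include_singletons), 0))
    }
  })
  tau <- mean(obs, na.rm = TRUE)
  p <- (1 + sum(null >= tau, na.rm = TRUE)) / (1 + length(null))
  structure(list(tau_D = tau, per_tree = obs, clades = NULL,
                 n_singletons = NA_integer_, null = null, p_value = p,
                 n_permutations = length(null),
                 share_threshold = share_threshold, seed = seed),
            class = "consentrait_result")
}

#' Mantel correlogram of response-magnitude differences vs phylogenetic distance
#'
#' Distances are cut into equal-width classes (Sturges count by default over
#' the full observed range). For each class, the Mantel statistic is the
#' Pearson correlation between the unfolded response-difference matrix and
#' the class indicator (1 for pairs in the class), so a negative statistic in
#' a short-distance class means closely related leaves respond most alike.
#' Two-sided significance by joint leaf-label permutation, with progressive
#' Holm correction across classes in increasing-distance order.
#'
#' @param phylo_dist Symmetric leaf-pair distance matrix (e.g.
#'   [ape::cophenetic.phylo()]).
#' @param response_diff Symmetric `|magnitude_i - magnitude_j|` matrix, same
#'   leaf order.
#' @param n_classes Number of distance classes (default: Sturges).
#' @param permutations Label permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `mantel_correlogram`: data.frame `classes` with
#'   bounds, pair counts, Mantel `r`, raw and progressively corrected p, and
#'   `n_permutations`.
#' @export
mantel_correlogram <- function(phylo_dist, response_diff, n_classes = NULL,
                               permutations = 999, seed = 1) {
  phylo_dist <- as.matrix(phylo_dist)
  response_diff <- as.matrix(response_diff)
  n <- nrow(phylo_dist)
  if (n < 10) stopf("need at least 10 leaves")
  if (!isTRUE(all.equal(dim(phylo_dist), dim(response_diff))))
    stopf("matrices must have the same dimensions")
  if (max(abs(phylo_dist - t(phylo_dist))) > 1e-9 ||
      max(abs(response_diff - t(response_diff))) > 1e-9)
    stopf("matrices must be symmetric")
  lower <- lower.tri(phylo_dist)
  dv <- phylo_dist[lower]
  rv <- response_diff[lower]
  if (stats::sd(rv) == 0) stopf("constant response differences: statistic undefined")
  npairs <- length(dv)
  if (is.null(n_classes)) n_classes <- ceiling(log2(npairs) + 1)
  breaks <- seq(min(dv), max(dv), length.out = n_classes + 1)
  cls <- cut(dv, breaks, include.lowest = TRUE, labels = FALSE)
  ind <- vapply(seq_len(n_classes), function(k) as.numeric(cls == k),
                numeric(npairs))
  usable <- colSums(ind) > 0 & colSums(ind) < npairs
  r_obs <- rep(NA_real_, n_classes)
  r_obs[usable] <- as.numeric(stats::cor(rv, ind[, usable, drop = FALSE]))
  ge <- integer(n_classes)
  pair_i <- row(phylo_dist)[lower]
  pair_j <- col(phylo_dist)[lower]
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      perm <- sample.int(n)
      rp <- response_diff[cbind(perm[pair_i], perm[pair_j])]
      rk <- as.numeric(stats::cor(rp, ind[, usable, drop = FALSE]))
      ge[usable] <- ge[usable] + (abs(rk) >= abs(r_obs[usable]))
    }
  })
  p_raw <- ifelse(usable, (1 + ge) / (1 + permutations), NA_real_)
  p_corr <- rep(NA_real_, n_classes)
  seen <- which(usable)
  for (k in seq_along(seen))
    p_corr[seen[k]] <- stats::p.adjust(p_raw[seen[seq_len(k)]], "holm")[k]
  structure(list(classes = data.frame(class = seq_len(n_classes),
                                      lower = breaks[-length(breaks)],
                                      upper = breaks[-1],
                                      n_pairs = colSums(ind),
                                      r = r_obs, p_raw = p_raw,
                                      p_corrected = p_corr),
                 n_permutations = permutations, seed = seed),
            class = "mantel_correlogram")
}

#' Absolute response-magnitude difference matrix
#'
#' @param magnitude Named numeric vector of per-leaf response magnitudes.
#' @return Symmetric `|m_i - m_j|` matrix with the vector's names.
#' @export
response_diff_matrix <- function(magnitude) {
  d <- abs(outer(magnitude, magnitude, "-"))
  dimnames(d) <- list(names(magnitude), names(magnitude))
  d
}
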