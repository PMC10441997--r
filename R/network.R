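#' All pairwise Spearman correlations with BH-adjusted p-values
#'
#' Average-rank ties; p-values from the t approximation of the rank
#' correlation; Benjamini-Hochberg adjustment across all tested pairs.
#' Constant (zero-variance) taxa are skipped with a message.
#'
#' @param rel Relative abundance matrix (taxa x samples), from
#'   [to_relative_abundance()].
#' @param method Correlation backbone, `"spearman"` (default) or `"pearson"`.
#' @return data.frame with `taxon_a`, `taxon_b`, `rho`, `p_raw`, `q_fdr`.
#' @export
pairwise_spearman <- function(rel, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- ncol(rel)
  if (n < 4) warnf("only %d samples: correlation p-values are unreliable", n)
  constant <- apply(rel, 1, function(x) stats::var(x) == 0)
  if (any(constant))
    msgf("skipping %d constant taxa: %s", sum(constant),
         paste(utils::head(rownames(rel)[constant], 5), collapse = ", "))
  rel <- rel[!constant, , drop = FALSE]
  if (nrow(rel) < 2) stopf("fewer than 2 non-constant taxa")
  R <- stats::cor(t(rel), method = method)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[idx]
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  data.frame(taxon_a = rownames(R)[idx[, 1]],
             taxon_b = rownames(R)[idx[, 2]],
             rho = rho, p_raw = p, q_fdr = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Drop taxa below a prevalence cutoff
#'
#' @param counts ASV table (or relative abundances).
#' @param min_prevalence Minimum fraction of samples in which a taxon must be
#'   present (count > 0).
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.2) {
  keep <- rowMeans(counts > 0) >= min_prevalence
  counts[keep, , drop = FALSE]
}

#' Build a signed co-occurrence network from thresholded correlations
#'
#' An edge joins two taxa iff `|rho| > rho_threshold` and
#' `q_fdr < q_threshold`; the signed correlation is kept as the edge weight
#' `s_ij`. Taxa with no retained edge are excluded. Each node carries its
#' mean relative abundance `b_j` over the samples of `rel`.
#'
#' @param correlations Output of [pairwise_spearman()].
#' @param rel Relative abundance matrix the correlations came from.
#' @param rho_threshold,q_threshold Edge thresholds (defaults 0.6 and 0.01).
#' @return An `igraph` graph with vertex attributes `name` and `abundance`
#'   and edge attributes `weight` (signed rho) and `q`.
#' @export
build_network <- function(correlations, rel, rho_threshold = 0.6, q_threshold = 0.01) {
  if (rho_threshold <= 0 || rho_threshold > 1 || q_threshold <= 0 || q_threshold > 1)
    stopf("thresholds must lie in (0, 1]")
  keep <- abs(correlations$rho) > rho_threshold & correlations$q_fdr < q_threshold
  if (!any(keep))
    stopf("no edge passes |rho| > %g and q < %g; relax the thresholds",
          rho_threshold, q_threshold)
  ed <- correlations[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = unique(c(ed$taxon_a, ed$taxon_b)))
  igraph::E(g)$weight <- ed$rho
  igraph::E(g)$q <- ed$q_fdr
  igraph::V(g)$abundance <- rowMeans(rel)[igraph::V(g)$name]
  g
}

#' One-call co-occurrence network for a sample group
#'
#' Applies the prevalence filter, computes relative abundances and pairwise
#' Spearman correlations, and thresholds them into a network.
#'
#' @param counts ASV table for one group of samples.
#' @param rho_threshold,q_threshold,min_prevalence See [build_network()] and
#'   [prevalence_filter()].
#' @param method Correlation method, see [pairwise_spearman()].
#' @return An `igraph` co-occurrence network.
#' @export
co_network <- function(counts, rho_threshold = 0.6, q_threshold = 0.01,
                       min_prevalence = 0.2, method = "spearman") {
  filt <- prevalence_filter(counts, min_prevalence)
  if (nrow(filt) < 2) stopf("fewer than 2 taxa pass the prevalence filter")
  rel <- to_relative_abundance(filt)
  build_network(pairwise_spearman(rel, method = method), rel,
                rho_threshold, q_threshold)
}

# unweighted, sign-blind skeleton of a signed network
skeleton <- function(net) {
  igraph::delete_edge_attr(net, "weight")
}

#' Per-node topology metrics
#'
#' Computed on the unweighted, sign-blind skeleton. The topological
#' coefficient of node n with degree `k_n >= 2` is the mean, over nodes m
#' sharing at least one neighbor with n, of `J(n, m) / k_n`, where `J` counts
#' shared neighbors plus 1 if n and m are adjacent; nodes with `k_n < 2` get
#' 0. Neighborhood connectivity is the mean degree of a node's neighbors;
#' the clustering coefficient is the usual local triangle density.
#'
#' @param net `igraph` network.
#' @return data.frame (one row per node) with the three metrics and degree;
#'   network-level means in `attr(, "means")`.
#' @export
topology_metrics <- function(net) {
  if (igraph::gorder(net) == 0) stopf("empty network")
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  A[A != 0] <- 1
  n <- nrow(A)
  deg <- rowSums(A)
  S <- A %*% A                      # shared-neighbor counts
  tc <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    m <- which(S[i, ] > 0 & seq_len(n) != i)
    if (!length(m)) return(0)
    mean((S[i, m] + A[i, m]) / deg[i])
  }, 0)
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) return(0)
    mean(deg[nb])
  }, 0)
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  out <- data.frame(node = igraph::V(net)$name, degree = deg,
                    topological_coefficient = tc,
                    neighborhood_connectivity = nc,
                    clustering_coefficient = cc,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "means") <- c(topological_coefficient = mean(tc),
                          neighborhood_connectivity = mean(nc),
                          clustering_coefficient = mean(cc))
  out
}

#' Detect modules by greedy modularity maximization
#'
#' Clauset-Newman-Moore agglomeration on the sign-blind skeleton with
#' `|weight|` as the edge weight; deterministic (ties broken by the
#' algorithm's fixed agglomeration order over lexicographically sorted
#' nodes). Louvain is available behind `method`, seeded.
#'
#' @param net `igraph` co-occurrence network.
#' @param seed Seed (used by the Louvain method).
#' @param method `"fast_greedy"` (default) or `"louvain"`.
#' @return List with `membership` (named integer vector), `modularity` (Q for
#'   that partition, |weight|-weighted), and `network` (input graph with a
#'   `module` vertex attribute).
#' @export
detect_modules <- function(net, seed = 1, method = c("fast_greedy", "louvain")) {
  method <- match.arg(method)
  if (igraph::gorder(net) == 0) stopf("empty network")
  g <- igraph::permute(net, match(igraph::V(net)$name, sort(igraph::V(net)$name)))
  w <- abs(igraph::E(g)$weight)
  comm <- with_seed(seed, {
    if (method == "fast_greedy") igraph::cluster_fast_greedy(g, weights = w)
    else igraph::cluster_louvain(g, weights = w)
  })
  memb <- igraph::membership(comm)
  q <- igraph::modularity(g, memb, weights = w)
  if (is.na(q)) q <- 0              # edgeless graph: Q of any partition is 0
  if (q < 0) {
    # never report a partition worse than the trivial single module (Q = 0)
    memb[] <- 1
    q <- 0
  }
  memb <- memb[igraph::V(net)$name]
  igraph::V(net)$module <- as.integer(memb)
  list(membership = memb, modularity = q, network = net)
}

#' Rank module hubs by within-module degree z-score
#'
#' `z_i = (k_i_within - mean_within) / sd_within`, computed per module on the
#' sign-blind skeleton; modules of size 1 or with zero spread yield z = 0.
#'
#' @param net Network with a `module` vertex attribute (see
#'   [detect_modules()]).
#' @param n_hubs How many top nodes to flag (default 5, the usual targeted
#'   attack set).
#' @return data.frame sorted by decreasing z with columns `node`, `module`,
#'   `within_degree`, `z`, `is_hub`.
#' @export
module_hubs <- function(net, n_hubs = 5) {
  memb <- igraph::V(net)$module
  if (is.null(memb)) stopf("network has no module assignment; run detect_modules()")
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  A[A != 0] <- 1
  same <- outer(memb, memb, "==")
  kin <- rowSums(A * same)
  z <- numeric(length(kin))
  for (mod in unique(memb)) {
    i <- which(memb == mod)
    s <- stats::sd(kin[i])
    if (length(i) > 1 && !is.na(s) && s > 0) z[i] <- (kin[i] - mean(kin[i])) / s
  }
  out <- data.frame(node = igraph::V(net)$name, module = memb,
                    within_degree = kin, z = z,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$node), ]
  out$is_hub <- seq_len(nrow(out)) <= n_hubs
  rownames(out) <- NULL
  out
}
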