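# signed adjacency matrix and abundance vector of a co-occurrence network
network_matrices <- function(net) {
  S <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE))
  b <- igraph::V(net)$abundance
  if (is.null(b)) stopf("network has no 'abundance' vertex attribute")
  list(S = S, b = b, names = igraph::V(net)$name)
}

#' Abundance-weighted mean interaction strength of one node
#'
#' `wMIS_i = sum_{j != i} b_j s_ij / sum_{j != i} b_j` over the live nodes,
#' with `s_ij = 0` for non-adjacent pairs. A node with no other live node
#' (or zero remaining abundance mass) gets 0, which the cascade treats as
#' extinct/isolated.
#'
#' @param i Node index or name.
#' @param S Signed weight matrix (0 off-network).
#' @param b Relative abundance vector, aligned with `S`.
#' @param alive Logical vector of live nodes (default: all).
#' @return The wMIS value.
#' @export
wmis <- function(i, S, b, alive = rep(TRUE, length(b))) {
  if (is.character(i)) i <- match(i, rownames(S))
  if (!alive[i]) stopf("node %s is not alive", i)
  j <- which(alive)
  j <- j[j != i]
  if (!length(j)) return(0)
  den <- sum(b[j])
  if (den <= 0) return(0)
  sum(b[j] * S[i, j]) / den
}

# wMIS for every live node at once
wmis_all <- function(S, b, alive) {
  idx <- which(alive)
  num <- as.numeric(S[idx, idx, drop = FALSE] %*% b[idx])
  den <- sum(b[idx]) - b[idx]
  out <- numeric(length(idx))
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

# synchronous cascade on matrices; returns the final alive vector
cascade_alive <- function(S, b, alive) {
  repeat {
    idx <- which(alive)
    if (length(idx) == 0) break
    if (length(idx) == 1) { alive[idx] <- FALSE; break }
    w <- wmis_all(S, b, alive)
    bad <- idx[w <= 0]
    if (!length(bad)) break
    alive[bad] <- FALSE
  }
  alive
}

#' Extinction cascade after node removal
#'
#' Removes the initial set, then repeatedly removes, simultaneously in each
#' round, every node whose wMIS is zero or negative, until all survivors have
#' strictly positive wMIS. Synchronous removal makes the result independent
#' of node processing order.
#'
#' @param net `igraph` co-occurrence network with `abundance` and signed
#'   `weight` attributes.
#' @param removed Character vector of node names (or integer indices) removed
#'   by the perturbation.
#' @return Character vector of surviving node names.
#' @export
extinction_cascade <- function(net, removed = character()) {
  m <- network_matrices(net)
  alive <- rep(TRUE, length(m$b))
  if (is.character(removed)) {
    bad <- setdiff(removed, m$names)
    if (length(bad)) stopf("unknown node(s): %s", paste(bad, collapse = ", "))
    alive[match(removed, m$names)] <- FALSE
  } else {
    alive[removed] <- FALSE
  }
  alive <- cascade_alive(m$S, m$b, alive)
  m$names[alive]
}

#' Network robustness under node removal
#'
#' Random strategy: in each repetition, `floor(f * n)` uniformly chosen nodes
#' are removed and the extinction cascade is run; robustness is the
#' proportion of the original nodes that survive. The `module_hubs` strategy
#' deterministically removes the top `hub_count` within-module-degree hubs
#' once.
#'
#' @param net `igraph` co-occurrence network.
#' @param strategy `"random"` or `"module_hubs"`.
#' @param f Fraction of nodes removed by the random strategy (in \[0, 1)).
#' @param hub_count Hubs removed by the targeted strategy (default 5).
#' @param repetitions Random repetitions (default 100).
#' @param seed Integer seed.
#' @return List of class `robustness_result`: `strategy`, `proportions` (one
#'   per repetition), `mean`, `sd`, `f`/`hub_count`, `seed`.
#' @export
robustness <- function(net, strategy = c("random", "module_hubs"), f = 0.5,
                       hub_count = 5, repetitions = 100, seed = 1) {
  strategy <- match.arg(strategy)
  m <- network_matrices(net)
  n <- length(m$b)
  if (n == 0) stopf("empty network")
  if (strategy == "random") {
    if (f < 0 || f >= 1) stopf("f must lie in [0, 1)")
    k <- floor(f * n)
    props <- with_seed(seed, vapply(seq_len(repetitions), function(r) {
      alive <- rep(TRUE, n)
      if (k > 0) alive[sample.int(n, k)] <- FALSE
      sum(cascade_alive(m$S, m$b, alive)) / n
    }, 0))
  } else {
    hubs <- utils::head(module_hubs(net, n_hubs = hub_count)$node, hub_count)
    alive <- rep(TRUE, n)
    alive[match(hubs, m$names)] <- FALSE
    props <- sum(cascade_alive(m$S, m$b, alive)) / n
  }
  structure(list(strategy = strategy, proportions = props,
                 mean = mean(props), sd = stats::sd(props),
                 f = if (strategy == "random") f else NA_real_,
                 hub_count = if (strategy == "module_hubs") hub_count else NA_integer_,
                 repetitions = length(props), seed = seed),
            class = "robustness_result")
}

# global efficiency of an igraph graph (unweighted hop counts; disconnected
# ordered pairs contribute 0); NaN-free for n < 2
global_efficiency_hops <- function(g) {
  n <- igraph::gorder(g)
  if (n < 2) return(0)
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability from global efficiency
#'
#' Global efficiency `E` is the mean inverse shortest-path length over
#' ordered node pairs on the unweighted, sign-blind skeleton (disconnected
#' pairs contribute 0). Each node's vulnerability is
#' `V_i = (E - E_i) / E`, where `E_i` is the efficiency of the graph without
#' node i (over the remaining pairs); the network's vulnerability is the
#' maximum `V_i`.
#'
#' @param net `igraph` network with at least 3 nodes and one edge.
#' @return List of class `vulnerability_result`: `global_efficiency`,
#'   `per_node` (data.frame with `node`, `efficiency_without`,
#'   `vulnerability`), `network_vulnerability`.
#' @export
vulnerability <- function(net) {
  n <- igraph::gorder(net)
  if (n < 3) stopf("need at least 3 nodes")
  E <- global_efficiency_hops(net)
  if (E == 0) stopf("edgeless network: efficiency is 0")
  Ei <- vapply(seq_len(n), function(i)
    global_efficiency_hops(igraph::delete_vertices(net, i)), 0)
  Vi <- (E - Ei) / E
  structure(list(global_efficiency = E,
                 per_node = data.frame(node = igraph::V(net)$name,
                                       efficiency_without = Ei,
                                       vulnerability = Vi,
                                       row.names = NULL, stringsAsFactors = FALSE),
                 network_vulnerability = max(Vi)),
            class = "vulnerability_result")
}
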