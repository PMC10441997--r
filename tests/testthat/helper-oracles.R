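# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (explicit loops, no shared code with R/) so that
# agreement with the package is a real two-route check.

# random signed co-occurrence network on n nodes as igraph + raw matrices
rand_signed_network <- function(seed, n = 10, p_edge = 0.35, p_neg = 0.2) {
  set.seed(seed)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        w <- runif(1, 0.6, 1) * if (runif(1) < p_neg) -1 else 1
        S[i, j] <- S[j, i] <- w
      }
    }
  }
  b <- runif(n, 0.01, 1)
  b <- b / sum(b)
  nm <- sprintf("t%02d", seq_len(n))
  dimnames(S) <- list(nm, nm)
  g <- igraph::graph_from_adjacency_matrix(S != 0, mode = "undirected")
  igraph::E(g)$weight <- S[igraph::as_edgelist(g, names = FALSE)]
  igraph::V(g)$abundance <- b
  list(net = g, S = S, b = b, names = nm)
}

# wMIS of node i by explicit summation
bf_wmis <- function(i, S, b, alive) {
  num <- 0
  den <- 0
  for (j in seq_along(b)) {
    if (j != i && alive[j]) {
      num <- num + b[j] * S[i, j]
      den <- den + b[j]
    }
  }
  if (den <= 0) return(0)
  num / den
}

# synchronous extinction cascade by repeated full recomputation
bf_cascade <- function(S, b, alive) {
  repeat {
    idx <- which(alive)
    if (length(idx) == 0) break
    if (length(idx) == 1) {
      alive[idx] <- FALSE
      break
    }
    w <- vapply(idx, bf_wmis, 0, S = S, b = b, alive = alive)
    bad <- idx[w <= 0]
    if (length(bad) == 0) break
    alive[bad] <- FALSE
  }
  alive
}

# per-node topology metrics by explicit neighbourhood loops
bf_topology <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  tc <- nc <- cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) > 0) nc[i] <- mean(deg[nb])
    if (length(nb) >= 2) {
      links <- 0
      for (a in nb) for (bb in nb) if (a < bb && A[a, bb] > 0) links <- links + 1
      cc[i] <- 2 * links / (length(nb) * (length(nb) - 1))
    }
    if (deg[i] >= 2) {
      js <- c()
      for (m in seq_len(n)) {
        if (m == i) next
        shared <- sum(A[i, ] > 0 & A[m, ] > 0)
        if (shared > 0) js <- c(js, shared + (A[i, m] > 0))
      }
      if (length(js)) tc[i] <- mean(js) / deg[i]
    }
  }
  list(tc = tc, nc = nc, cc = cc)
}

# within-module degree z-scores by explicit per-module loops
bf_hub_z <- function(A, memb) {
  n <- nrow(A)
  kin <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (A[i, j] > 0 && memb[i] == memb[j]) kin[i] <- kin[i] + 1
  z <- numeric(n)
  for (mod in unique(memb)) {
    idx <- which(memb == mod)
    if (length(idx) < 2) next
    s <- stats::sd(kin[idx])
    if (is.na(s) || s == 0) next
    z[idx] <- (kin[idx] - mean(kin[idx])) / s
  }
  z
}

# all-pairs BFS shortest hops
bf_hops <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- c()
      for (v in frontier)
        for (u in which(A[v, ] > 0))
          if (D[s, u] > d) {
            D[s, u] <- d
            nxt <- c(nxt, u)
          }
      frontier <- unique(nxt)
    }
  }
  D
}

bf_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- bf_hops(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

bf_vulnerability <- function(A) {
  E0 <- bf_efficiency(A)
  vapply(seq_len(nrow(A)), function(i) {
    (E0 - bf_efficiency(A[-i, -i, drop = FALSE])) / E0
  }, 0)
}

# Levins overlap by explicit summation over states
bf_levins_overlap <- function(u, v, symmetric = TRUE) {
  p <- u / sum(u)
  q <- v / sum(v)
  num <- 0
  for (s in seq_along(p)) num <- num + p[s] * q[s]
  o_uv <- unname(num / sum(p^2))
  if (!symmetric) return(o_uv)
  unname((o_uv + num / sum(q^2)) / 2)
}

# cohesion by explicit loops, sharing the implementation's permutation stream
# (same seed, same per-iteration column-by-column sampling order)
bf_cohesion <- function(rel, iterations, seed) {
  X <- t(rel)
  nt <- nrow(rel)
  pearson <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  cmat <- function(M) {
    out <- matrix(0, nt, nt)
    for (i in seq_len(nt)) for (j in seq_len(nt))
      if (i != j) out[i, j] <- pearson(M[, i], M[, j])
    out
  }
  obs <- cmat(X)
  nullsum <- matrix(0, nt, nt)
  set.seed(seed)
  for (it in seq_len(iterations)) {
    Xp <- X
    for (j in seq_len(nt)) Xp[, j] <- sample(X[, j])
    nullsum <- nullsum + cmat(Xp)
  }
  corrected <- obs - nullsum / iterations
  pos <- neg <- numeric(nt)
  for (i in seq_len(nt)) {
    v <- corrected[i, -i]
    if (any(v > 0)) pos[i] <- mean(v[v > 0])
    if (any(v < 0)) neg[i] <- mean(v[v < 0])
  }
  cpos <- cneg <- numeric(ncol(rel))
  for (s in seq_len(ncol(rel))) {
    cpos[s] <- sum(rel[, s] * pos)
    cneg[s] <- sum(rel[, s] * neg)
  }
  list(corrected = corrected, pos = pos, neg = neg,
       cohesion_pos = cpos, cohesion_neg = cneg)
}

# small deterministic count table fixture
toy_table <- function() {
  asv_table(matrix(c(5L, 0L, 3L,
                     2L, 2L, 0L,
                     0L, 8L, 1L,
                     1L, 1L, 6L), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("t", 1:4), paste0("s", 1:3))))
}
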