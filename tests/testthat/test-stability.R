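test_that("wMIS takes its hand-computed value and scale invariances", {
  S <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  S["a", "b"] <- S["b", "a"] <- 0.8
  S["a", "c"] <- S["c", "a"] <- -0.4
  b <- c(a = 0.5, b = 0.25, c = 0.25)
  # wMIS_b... for node a over b, c: (0.25*0.8 + 0.25*(-0.4)) / 0.5 = 0.2
  expect_equal(wmis("a", S, b), (0.25 * 0.8 - 0.25 * 0.4) / 0.5)
  # spec arithmetic: b = (0.5, 0.25, 0.25) weights s = (0.8, -0.4, 0) seen
  # from a fourth node with unit remaining mass
  S4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  S4["d", c("a", "b", "c")] <- c(0.8, -0.4, 0)
  S4[c("a", "b", "c"), "d"] <- c(0.8, -0.4, 0)
  b4 <- c(a = 0.5, b = 0.25, c = 0.25, d = 0.9)
  expect_equal(wmis("d", S4, b4), 0.3)
  # rescaling all abundances cancels in the ratio
  expect_equal(wmis("d", S4, b4 * 7), 0.3)
  # all-positive incident weights give a positive wMIS
  expect_gt(wmis("a", abs(S), b), 0)
  # no other live node: 0 by convention
  expect_equal(wmis("a", S, b, alive = c(TRUE, FALSE, FALSE)), 0)
})

test_that("the cascade reproduces a hand-traced secondary extinction", {
  # cycle a-b-c-d-a; c-d is the only negative edge, d leans on a
  nm <- letters[1:4]
  S <- matrix(0, 4, 4, dimnames = list(nm, nm))
  S["a", "b"] <- S["b", "a"] <- 0.9
  S["b", "c"] <- S["c", "b"] <- 0.4
  S["c", "d"] <- S["d", "c"] <- -0.3
  S["d", "a"] <- S["a", "d"] <- 0.8
  b <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  g <- igraph::graph_from_adjacency_matrix(S != 0, mode = "undirected")
  igraph::E(g)$weight <- S[igraph::as_edgelist(g, names = FALSE)]
  igraph::V(g)$abundance <- b
  # intact network is a fixed point: every wMIS > 0
  expect_setequal(extinction_cascade(g, character()), nm)
  # removing a: d keeps only its negative edge -> wMIS_d < 0 -> d removed;
  # b and c stay positive afterwards (hand-traced)
  expect_setequal(extinction_cascade(g, "a"), c("b", "c"))
  # removing b: c keeps only its negative edge -> c removed; a and d then
  # rest on the positive a-d edge
  expect_setequal(extinction_cascade(g, "b"), c("a", "d"))
})

test_that("cascade fixed points are idempotent and match the brute force", {
  for (seed in 1:25) {
    rn <- rand_signed_network(seed, n = 10)
    set.seed(seed + 500)
    removed <- sample(rn$names, 3)
    surv <- extinction_cascade(rn$net, removed)
    alive0 <- !(rn$names %in% removed)
    expect_identical(surv, rn$names[bf_cascade(rn$S, rn$b, alive0)])
    # running the cascade on its own output removes nothing
    g2 <- igraph::delete_vertices(rn$net, setdiff(rn$names, surv))
    if (length(surv) > 0) expect_setequal(extinction_cascade(g2, character()), surv)
  }
})

test_that("robustness is exact on all-positive networks and seeded draws", {
  rn <- rand_signed_network(3, n = 10, p_neg = 0)    # all positive weights
  rob <- robustness(rn$net, "random", f = 0.5, repetitions = 20, seed = 9)
  # no negative edge -> no wMIS-driven deaths; only isolated leftovers die
  expect_true(all(rob$proportions <= 0.5))
  con <- igraph::make_full_graph(8)
  igraph::V(con)$name <- paste0("n", 1:8)
  igraph::E(con)$weight <- 0.9
  igraph::V(con)$abundance <- rep(1 / 8, 8)
  rc <- robustness(con, "random", f = 0.5, repetitions = 15, seed = 2)
  # complete positive graph: survivors always stay connected -> exactly 0.5
  expect_true(all(rc$proportions == 0.5))
  expect_equal(robustness(con, "random", f = 0, repetitions = 3, seed = 1)$mean, 1)
  expect_error(robustness(con, f = 1), "f must")
  # per-repetition survivors equal the oracle under shared removal draws
  rn2 <- rand_signed_network(13, n = 12)
  rep_n <- 10
  rob2 <- robustness(rn2$net, "random", f = 0.5, repetitions = rep_n, seed = 31)
  set.seed(31)
  oracle <- vapply(seq_len(rep_n), function(r) {
    alive <- rep(TRUE, 12)
    alive[sample.int(12, 6)] <- FALSE
    sum(bf_cascade(rn2$S, rn2$b, alive)) / 12
  }, 0)
  expect_equal(rob2$proportions, oracle)
})

test_that("hub-targeted removal is deterministic and uses the top-ranked hubs", {
  rn <- rand_signed_network(7, n = 12)
  mods <- detect_modules(rn$net, seed = 1)
  rb <- robustness(mods$network, "module_hubs", hub_count = 5)
  expect_equal(rb$repetitions, 1)
  hubs <- module_hubs(mods$network)$node[1:5]
  expect_equal(rb$proportions,
               length(extinction_cascade(mods$network, hubs)) / 12)
})

test_that("vulnerability hits its closed-form values on P3 and K3", {
  p3 <- igraph::graph_from_literal(a - b - c)
  igraph::E(p3)$weight <- 1
  v <- vulnerability(p3)
  expect_equal(v$global_efficiency, 5 / 6)
  # removing the centre disconnects the ends entirely
  expect_equal(v$per_node$vulnerability[v$per_node$node == "b"], 1)
  expect_equal(v$network_vulnerability, 1)
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  igraph::E(k3)$weight <- 1
  vk <- vulnerability(k3)
  expect_equal(vk$global_efficiency, 1)
  expect_equal(vk$network_vulnerability, 0)
  lonely <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lonely)$name <- c("a", "b", "c")
  expect_error(vulnerability(lonely), "edgeless")
})

test_that("vulnerability equals the brute-force shortest-path oracle", {
  for (seed in 1:15) {
    rn <- rand_signed_network(seed + 40, n = 12)
    if (igraph::gsize(rn$net) == 0) next
    v <- vulnerability(rn$net)
    A <- (rn$S != 0) * 1
    expect_equal(v$per_node$vulnerability, bf_vulnerability(A))
  }
})

test_that("mean robustness decreases as more of the network is removed", {
  rn <- rand_signed_network(99, n = 12, p_edge = 0.5)
  means <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(f)
    robustness(rn$net, "random", f = f, repetitions = 40, seed = 17)$mean, 0)
  # Monte-Carlo monotonicity: allow tiny inversions from sampling noise
  expect_true(all(diff(means) < 0.05))
  expect_lt(means[5], means[1])
})
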