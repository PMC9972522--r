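test_that("density objective is the average induced degree", {
  tri <- unit_triangle()
  expect_equal(density_objective(tri, c("a", "b", "c")), 1)
  two <- signed_difference_graph(sym_matrix(0.6, c("a", "b")))
  expect_equal(density_objective(two, c("a", "b")), 0.3)
  mixed <- signed_difference_graph(sym_matrix(c(1, 1, -1), c("a", "b", "c")))
  expect_equal(density_objective(mixed, c("a", "b", "c")), 1 / 3)
  expect_error(density_objective(tri, character(0)), "empty")
})

test_that("alpha objective penalizes pairs and reduces to the raw contrast at alpha 0", {
  labs <- c("a", "b", "c")
  a <- weighted_network(sym_matrix(c(1, 0, 0), labs))
  b <- weighted_network(sym_matrix(c(0, 0, 0), labs))
  expect_equal(alpha_objective(a, b, c("a", "b"), 0.5), 0.5)
  expect_equal(alpha_objective(a, b, c("a", "b"), 0), 1)
  expect_equal(alpha_objective(a, b, "a", 7), 0) # singleton: no pairs
  expect_error(alpha_objective(a, b, c("a", "b"), -1), "non-negative")
  # alpha = 0 equals e_A - e_B for arbitrary sets
  a2 <- rand_network(8, 21)
  b2 <- rand_network(8, 22)
  s <- a2$nodes[1:5]
  expect_equal(alpha_objective(a2, b2, s, 0),
               induced_edge_sum(a2, s) - induced_edge_sum(b2, s))
})

test_that("greedy peel finds planted structures verified by enumeration", {
  # all-positive unit 4-clique plus an isolated node
  labs <- c("a", "b", "c", "d", "e")
  w <- matrix(0, 5, 5, dimnames = list(labs, labs))
  w[1:4, 1:4] <- 1; diag(w) <- 0
  g <- signed_difference_graph(w)
  gp <- greedy_peel(g, 1)
  expect_setequal(gp$node_set, c("a", "b", "c", "d"))
  expect_equal(gp$objective, 1.5)
  expect_equal(brute_force_densest(g)$objective, 1.5)

  # unit triangle plus a node attached to each corner by weight -1
  labs <- c("a", "b", "c", "d")
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w[c("a", "b", "c"), c("a", "b", "c")] <- 1; diag(w) <- 0
  w["d", c("a", "b", "c")] <- -1; w[c("a", "b", "c"), "d"] <- -1
  g <- signed_difference_graph(w)
  gp <- greedy_peel(g, 1)
  expect_setequal(gp$node_set, c("a", "b", "c"))
  expect_equal(gp$objective, 1)
  bf <- brute_force_densest(g)
  expect_setequal(bf$node_set, c("a", "b", "c"))
  expect_equal(bf$objective, 1)

  # only negative edges: some singleton, objective 0
  g <- signed_difference_graph(sym_matrix(c(-1, -0.5, -2), c("a", "b", "c")))
  gp <- greedy_peel(g, 1)
  expect_length(gp$node_set, 1)
  expect_equal(gp$objective, 0)
})

test_that("peel trace shrinks by one node per iteration with no gaps", {
  g <- rand_signed_graph(12, 4)
  gp <- greedy_peel(g, 1)
  expect_equal(gp$trace$size, 12:1)
  expect_equal(gp$trace$objective[gp$argmax_iteration], max(gp$trace$objective))
  expect_equal(length(gp$node_set), gp$trace$size[gp$argmax_iteration])
  # stored objective matches recomputation on the stored set
  expect_equal(gp$objective, density_objective(g, gp$node_set), tolerance = 1e-9)
})

test_that("greedy peel is deterministic and independent of input node order", {
  set.seed(31)
  labs <- sprintf("v%02d", 1:10)
  w <- sym_matrix(runif(45, -1, 1), labs)
  perm <- sample(10)
  g1 <- signed_difference_graph(w)
  g2 <- signed_difference_graph(w[perm, perm])
  for (cv in c(0.5, 1, 2)) {
    r1 <- greedy_peel(g1, cv)
    r2 <- greedy_peel(g2, cv)
    expect_identical(r1$node_set, r2$node_set)
    expect_equal(r1$objective, r2$objective)
  }
})

test_that("C sweep keeps the best result and is a max over the grid", {
  g <- rand_signed_graph(10, 8)
  best <- sweep_c(g, c(0.5, 1, 2))
  singles <- vapply(c(0.5, 1, 2), function(cv) greedy_peel(g, cv)$objective, 0)
  expect_equal(best$objective, max(singles))
  # singleton grid equals a plain peel
  expect_identical(sweep_c(g, 1)$node_set, greedy_peel(g, 1)$node_set)
  # adding a grid point can only improve
  wider <- sweep_c(g, c(0.5, 1, 2, 3.7))
  expect_gte(wider$objective, best$objective)
  expect_error(sweep_c(g, numeric(0)), "non-empty")
  expect_error(sweep_c(g, c(1, -2)), "positive")
})

test_that("on all-positive graphs the swept objective does not depend on C", {
  for (seed in 1:10) {
    g <- rand_signed_graph(10, seed, wmin = 0, wmax = 1)
    objs <- vapply(c(0.5, 1, 2), function(cv) greedy_peel(g, cv)$objective, 0)
    expect_equal(max(objs), min(objs), tolerance = 1e-9)
  }
})

test_that("top-k recovers two node-disjoint planted cliques in rank order", {
  labs <- sprintf("v%02d", 1:20)
  wa <- matrix(0, 20, 20, dimnames = list(labs, labs))
  big <- labs[1:5]; small <- labs[6:9]
  wa[big, big] <- 1; wa[small, small] <- 1; diag(wa) <- 0
  net_a <- weighted_network(wa)
  net_b <- weighted_network(wa * 0)
  res <- top_k_contrast(net_a, net_b, c_grid = 1, k = 2, direction = "ab")
  expect_equal(nrow(res), 2)
  expect_setequal(res$nodes[[1]], big)
  expect_equal(res$objective[1], 2)
  expect_setequal(res$nodes[[2]], small)
  expect_equal(res$objective[2], 1.5)
  # verify each rank against the enumeration oracle on its residual graph
  d <- difference_graph(net_a, net_b)
  bf1 <- brute_force_densest(d)
  expect_setequal(bf1$node_set, big)
  w2 <- d$weights; w2[big, big] <- 0
  bf2 <- brute_force_densest(signed_difference_graph(w2))
  expect_setequal(bf2$node_set, small)
  # after extraction the rank-1 support is zeroed: k = 1 equals sweep_c
  one <- top_k_contrast(net_a, net_b, c_grid = 1, k = 1, direction = "ab")
  expect_identical(one$nodes[[1]], sweep_c(d, 1)$node_set)
})

test_that("top-k within-set edge supports are pairwise disjoint and extraction stops at zero signal", {
  for (seed in 1:10) {
    a <- rand_network(15, seed)
    b <- rand_network(15, seed + 500)
    res <- top_k_contrast(a, b, c_grid = c(0.5, 1, 2), k = 4, direction = "both")
    d0 <- difference_graph(a, b)
    for (dr in unique(res$direction)) {
      sets <- res$nodes[res$direction == dr]
      w <- if (dr == "A_over_B") d0$weights else -d0$weights
      supports <- list()
      for (s in sets) {
        sub <- w[s, s, drop = FALSE]
        nz <- which(upper.tri(sub) & sub != 0, arr.ind = TRUE)
        supports[[length(supports) + 1]] <- paste(s[nz[, 1]], s[nz[, 2]])
        w[s, s] <- 0 # replay the extraction
      }
      expect_equal(anyDuplicated(unlist(supports)), 0)
      # rank-r support is non-empty while mining continues
      expect_true(all(lengths(supports) > 0))
    }
    expect_true(all(res$objective > 0))
  }
})

test_that("brute force oracle applies its tie-breaking rules and its guard", {
  # single positive edge among 3 nodes: that pair at density 1/2
  w <- sym_matrix(c(1, 0, 0), c("a", "b", "c"))
  bf <- brute_force_densest(signed_difference_graph(w))
  expect_identical(bf$node_set, c("a", "b"))
  expect_equal(bf$objective, 0.5)
  # triangle +1,+1,-1: a +1 edge pair beats the whole triangle (1/2 > 1/3);
  # two pairs tie at 1/2, the lexicographically smaller wins
  tri <- signed_difference_graph(sym_matrix(c(1, 1, -1), c("a", "b", "c")))
  bf <- brute_force_densest(tri)
  expect_equal(bf$objective, 0.5)
  expect_identical(bf$node_set, c("a", "b"))
  # all-negative: a singleton at 0
  neg <- signed_difference_graph(sym_matrix(c(-1, -1, -1), c("a", "b", "c")))
  bf <- brute_force_densest(neg)
  expect_length(bf$node_set, 1)
  expect_equal(bf$objective, 0)
  expect_error(brute_force_densest(rand_signed_graph(21, 1)), "oracle")
})

test_that("greedy objective respects the rho*/2 - Delta/2 bound against enumeration", {
  for (seed in 1:50) {
    g <- rand_signed_graph(10, seed)
    rho_star <- brute_force_densest(g)$objective
    bound <- peeling_bound(g, rho_star)
    expect_gte(greedy_peel(g, 1)$objective, bound - 1e-9)
    expect_lte(greedy_peel(g, 1)$objective, rho_star + 1e-9) # oracle dominance
  }
  # bound arithmetic
  pos <- signed_difference_graph(sym_matrix(c(1, 2, 3), c("a", "b", "c")))
  expect_equal(peeling_bound(pos, 2), 1) # Delta = 0
  star <- signed_difference_graph({
    labs <- c("c", "x", "y", "z")
    w <- matrix(0, 4, 4, dimnames = list(labs, labs))
    w["c", c("x", "y", "z")] <- -2; w[c("x", "y", "z"), "c"] <- -2; w
  })
  expect_equal(peeling_bound(star, 2), -2) # Delta = 6
})

test_that("tidy and glance summarize a peel", {
  g <- rand_signed_graph(8, 3)
  gp <- greedy_peel(g, 1)
  tr <- tidy(gp)
  expect_named(tr, c("iteration", "size", "objective"))
  gl <- glance(gp)
  expect_equal(gl$objective, gp$objective)
  expect_equal(gl$size, length(gp$node_set))
})
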