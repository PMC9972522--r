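test_that("exact Mann-Whitney p matches enumeration and wilcox.test on tie-free data", {
  # frozen arithmetic case: complete separation of 3 vs 3
  mw <- mann_whitney_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 0.1) # 2 / choose(6, 3)
  expect_equal(mw$method, "exact")
  # identical samples: p = 1
  expect_equal(mann_whitney_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  # random tie-free cases against stats::wilcox.test (independent route)
  set.seed(10)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- rnorm(n); y <- rnorm(m, sample(c(0, 1.5), 1))
    ours <- mann_whitney_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$u_statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney handles ties, matching bitmask enumeration", {
  set.seed(11)
  cases <- list(
    list(x = c(1, 1, 2), y = c(1, 2, 2)),
    list(x = c(3, 3, 3, 5), y = c(3, 4, 5)),
    list(x = rep(2, 4), y = rep(2, 4))
  )
  for (i in 1:15) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    cases[[length(cases) + 1]] <- list(x = sample(1:4, n, TRUE), y = sample(1:4, m, TRUE))
  }
  for (cs in cases) {
    ours <- mann_whitney_test(cs$x, cs$y)$p_value
    expect_equal(ours, mw_enum_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("normal-approximation path mirrors the tie-corrected continuity-corrected z test", {
  set.seed(12)
  x <- round(rnorm(30, 0, 2), 1)
  y <- round(rnorm(35, 1, 2), 1)
  ours <- mann_whitney_test(x, y, exact = FALSE)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$method, "normal")
})

test_that("degree test contrasts induced-subgraph degrees between networks", {
  # identical networks: identical degree vectors, exact p = 1
  a <- rand_network(8, 13)
  dt <- degree_distribution_test(a$nodes[1:5], a, a)
  expect_equal(dt$degrees$degree_a, dt$degrees$degree_b)
  expect_equal(dt$p_value, 1)
  # induced degrees recomputed by hand
  b <- rand_network(8, 14)
  s <- a$nodes[1:4]
  dt2 <- degree_distribution_test(s, a, b)
  expect_equal(dt2$degrees$degree_a, unname(colSums(a$weights[s, s])))
  expect_equal(dt2$degrees$degree_b, unname(colSums(b$weights[s, s])))
  # full-network flag uses total degrees
  dt3 <- degree_distribution_test(s, a, b, within = FALSE)
  expect_equal(dt3$degrees$degree_a, unname(colSums(a$weights[, s])))
  expect_error(degree_distribution_test("v01", a, b), "at least 2")
  # tidy/glance
  expect_named(glance(dt2), c("n_nodes", "u_statistic", "p_value", "method"))
  expect_equal(nrow(tidy(dt2)), 2 * length(s))
})

test_that("a planted contrast subgraph yields a strong degree shift", {
  sim <- planted_contrast_pair(60, 15, p_in_a = 0.9, p_in_b = 0.05,
                               p_background = 0.05, seed = 15)
  dt <- degree_distribution_test(sim$module, sim$net_a, sim$net_b)
  expect_lt(dt$p_value, 1e-4)
  expect_gt(mean(dt$degrees$degree_a), mean(dt$degrees$degree_b))
})

test_that("jaccard index follows the set formula", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(0), "a"), 0)
  expect_error(jaccard_index(character(0), character(0)), "undefined")
  # symmetry, and 1 iff equal
  set.seed(16)
  for (i in 1:10) {
    s1 <- sample(letters, sample(1:10, 1))
    s2 <- sample(letters, sample(1:10, 1))
    expect_equal(jaccard_index(s1, s2), jaccard_index(s2, s1))
    expect_equal(jaccard_index(s1, s2) == 1, setequal(s1, s2))
  }
})

test_that("fisher overlap equals the closed-form hypergeometric tail", {
  universe <- sprintf("u%02d", 1:40)
  s1 <- universe[1:10]
  s2 <- universe[1:10]
  fo <- fisher_overlap(s1, s2, universe)
  expect_equal(fo$overlap, 10)
  expect_equal(fo$p_value, choose(10, 10) * choose(30, 0) / choose(40, 10),
               tolerance = 1e-12)
  expect_equal(fo$p_value, hyper_tail(10, 10, 10, 40), tolerance = 1e-12)
  # expected overlap product formula (204 * 300 / 2000 = 30.6)
  big_u <- sprintf("g%04d", 1:2000)
  fo2 <- fisher_overlap(big_u[1:204], big_u[100:399], big_u)
  expect_equal(fo2$expected_overlap, 30.6)
  # identical set and universe: p = 1, expected = universe size
  fo3 <- fisher_overlap(universe, universe, universe)
  expect_equal(fo3$p_value, 1)
  expect_equal(fo3$expected_overlap, 40)
  expect_error(fisher_overlap("x", "y", character(0)), "non-empty")
  expect_error(fisher_overlap(c("u01", "zz"), s2, universe), "universe")
})

test_that("one-sided fisher p matches the hypergeometric tail on random small tables", {
  set.seed(17)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    universe <- sprintf("u%02d", 1:N)
    s1 <- sample(universe, sample(1:N, 1))
    s2 <- sample(universe, sample(1:N, 1))
    fo <- fisher_overlap(s1, s2, universe)
    expect_equal(fo$p_value,
                 hyper_tail(length(intersect(s1, s2)), length(s1), length(s2), N),
                 tolerance = 1e-12)
  }
})

test_that("enrichment ranks a perfectly matching set first with hypergeometric p and BH adjustment", {
  universe <- sprintf("g%03d", 1:100)
  sets <- c(list(target = universe[1:10]),
            setNames(lapply(0:8, function(i) universe[(11 + i * 9):(19 + i * 9)]),
                     paste0("other", 1:9)))
  coll <- gene_set_collection(sets, universe = universe)
  res <- enrich(universe[1:10], coll)
  expect_equal(res$set[1], "target")
  expect_equal(res$overlap[1], 10)
  expect_equal(res$gene_ratio[1], 1)
  expect_equal(res$p_value[1], hyper_tail(10, 10, 10, 100), tolerance = 1e-12)
  expect_true(res$significant[1])
  # disjoint sets get p = 1
  expect_true(all(res$p_value[res$overlap == 0] == 1))
  # BH: adjusted p >= p, monotone step-up against a hand implementation
  expect_true(all(res$p_adjust >= res$p_value - 1e-15))
  m <- nrow(res)
  o <- order(res$p_value)
  hand <- numeric(m)
  hand[o] <- rev(cummin(rev(res$p_value[o] * m / seq_len(m))))
  hand <- pmin(hand, 1)
  expect_equal(res$p_adjust, hand, tolerance = 1e-12)
})

test_that("enrichment is invariant to set order and BH reacts correctly to null sets", {
  universe <- sprintf("g%03d", 1:60)
  sets <- list(s1 = universe[1:12], s2 = universe[5:25], s3 = universe[30:45])
  query <- universe[1:15]
  r1 <- enrich(query, gene_set_collection(sets, universe))
  r2 <- enrich(query, gene_set_collection(rev(sets), universe))
  expect_equal(r1[order(r1$set), c("set", "p_value", "p_adjust")],
               r2[order(r2$set), c("set", "p_value", "p_adjust")])
  # adding a set that cannot overlap never decreases other adjusted p
  sets4 <- c(sets, list(nullset = universe[50:60]))
  r3 <- enrich(setdiff(query, universe[50:60]), gene_set_collection(sets4, universe))
  for (nm in names(sets)) {
    expect_gte(r3$p_adjust[r3$set == nm] + 1e-15, r1$p_adjust[r1$set == nm])
  }
  expect_error(enrich("not_in_universe", gene_set_collection(sets, universe)), "empty")
})

test_that("upregulation calls use a strict log2 fold-change boundary", {
  a <- c(g1 = 3, g2 = 7, g3 = 1)
  b <- c(g1 = 1, g2 = 1, g3 = 7)
  up <- upregulated_genes(a, b)
  expect_false("g1" %in% up) # log2(4/2) = 1 exactly -> excluded
  expect_true("g2" %in% up)  # log2(8/2) = 2
  # mirror set under argument swap
  down <- upregulated_genes(b, a)
  expect_identical(down, "g3")
  expect_length(intersect(up, down), 0)
  expect_error(upregulated_genes(a, c(g1 = 1, gX = 2, g3 = 1)), "differ")
  # data-frame input form
  up_df <- upregulated_genes(data.frame(gene = names(a), tpm = unname(a)),
                             data.frame(gene = names(b), tpm = unname(b)))
  expect_identical(up_df, up)
})

test_that("cohen's d uses pooled bessel-corrected SD and flags degenerate input", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(cohens_d(x, x), 0)
  expect_warning(d <- cohens_d(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1)), "infinite")
  expect_identical(d, Inf)
  expect_equal(suppressWarnings(cohens_d(c(0.1, 0.1), c(0.5, 0.5))), -Inf)
})

test_that("mRNA-protein agreement returns per-gene Pearson r and group-wise d", {
  set.seed(18)
  genes <- sprintf("g%02d", 1:12)
  samples <- sprintf("s%02d", 1:4)
  m <- matrix(rnorm(48, 8, 2), 12, 4, dimnames = list(genes, samples))
  # identical matrices: r = 1 everywhere, d = 0 between groups
  ag <- expression_protein_agreement(m, m, groups = list(grp = genes[1:5]))
  expect_true(all(abs(ag$correlations$r - 1) < 1e-12))
  expect_equal(ag$cohens_d$d, 0)
  # hand-computed Pearson per gene on noisy protein data
  p <- m + matrix(rnorm(48), 12, 4)
  ag2 <- expression_protein_agreement(m, p, groups = list(grp = genes[1:5]))
  for (g in genes) {
    expect_equal(ag2$correlations$r[ag2$correlations$gene == g],
                 cor(m[g, ], p[g, ]), tolerance = 1e-12)
  }
  expect_setequal(ag2$correlations$group, c("grp", "background"))
  expect_error(expression_protein_agreement(m[, 1:2], p[, 1:2], list(g = genes[1])),
               "3 shared samples")
})
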