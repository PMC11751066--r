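test_that("pair_ranks re-ranks within the set/list intersection", {
  gene_set <- data.frame(tf_id = "T", gene_id = c("gA", "gB", "gC"),
                         set_score = c(3, 2, 1), S_rank = 1:3,
                         stringsAsFactors = FALSE)
  gene_list <- data.frame(gene_id = c("gB", "gC", "gA"),
                          rde = c(5, 1, -2), L_rank = 1:3,
                          stringsAsFactors = FALSE)
  paired <- pair_ranks(gene_set, gene_list)
  expect_equal(paired$n, 3L)
  expect_equal(paired$gene_id, c("gA", "gB", "gC"))
  expect_equal(paired$R, c(3L, 1L, 2L))

  # identical order gives the identity pairing
  ident <- pair_ranks(gene_set,
                      data.frame(gene_id = c("gA", "gB", "gC"),
                                 rde = c(3, 2, 1), L_rank = 1:3))
  expect_equal(ident$R, 1:3)

  # extra genes on either side are dropped and ranks re-closed
  wide_list <- data.frame(gene_id = c("gX", "gB", "gY", "gA", "gC"),
                          rde = 5:1, L_rank = 1:5)
  sub <- pair_ranks(gene_set, wide_list)
  expect_equal(sub$n, 3L)
  expect_setequal(sub$R, 1:3)

  # insufficient overlap is a skip, not an error
  expect_message(
    skipped <- pair_ranks(gene_set[1:2, ],
                          data.frame(gene_id = "gA", rde = 1, L_rank = 1)),
    "insufficient overlap")
  expect_null(skipped)
})

test_that("compute_weights stays in (0,1) and reflects pooled mass", {
  paired <- make_paired(c(3, 1, 4, 2, 5))
  expect_equal(compute_weights(paired, "uniform"), rep(0.5, 5))
  tl <- compute_weights(paired, "top_linear")
  expect_true(all(diff(tl) < 0))
  expect_true(all(tl > 0 & tl < 1))

  set.seed(51)
  for (rep in 1:10) {
    n <- sample(10:80, 1)
    p <- make_paired(sample.int(n), rde = rnorm(n))
    for (mode in c("mixed_density", "uniform", "top_linear")) {
      v <- compute_weights(p, mode)
      expect_true(all(v > 0 & v < 1))
      expect_length(v, n)
    }
  }

  # mass concentrated at the top ranks lifts the top weights
  n <- 60
  top_heavy <- make_paired(1:n, rde = c(rep(50, 6), rep(0.01, n - 6)))
  v <- compute_weights(top_heavy, "mixed_density")
  expect_gt(v[1], v[n])
})

test_that("weighted tau matches hand-derived and brute-force values", {
  expect_equal(weighted_kendall_tau(c(0.5, 0.3, 0.2), c(1, 3, 2)),
               0.38 / 0.62, tolerance = 1e-12)
  set.seed(52)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    v <- runif(n, 0.05, 0.95)
    R <- sample.int(n)
    expect_equal(weighted_kendall_tau(v, R), brute_force_tau(v, R),
                 tolerance = 1e-12)
  }
})

test_that("constant weights reduce the weighted tau to the classical tau", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    R <- sample.int(n)
    cst <- runif(1, 0.05, 0.95)
    classical <- cor(seq_len(n), R, method = "kendall")
    expect_equal(weighted_kendall_tau(rep(cst, n), R), classical,
                 tolerance = 1e-12)
  }
})

test_that("tau is +1 on identity, -1 on reversal, bounded, scale-invariant", {
  set.seed(54)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    v <- runif(n, 0.01, 0.99)
    expect_equal(weighted_kendall_tau(v, 1:n), 1, tolerance = 1e-12)
    expect_equal(weighted_kendall_tau(v, n:1), -1, tolerance = 1e-12)
    R <- sample.int(n)
    tau <- weighted_kendall_tau(v, R)
    expect_true(tau >= -1 - 1e-12 && tau <= 1 + 1e-12)
    expect_equal(weighted_kendall_tau(v * 0.3, R), tau, tolerance = 1e-12)
  }
  expect_error(weighted_kendall_tau(c(0.5), c(1)), "at least 2")
  expect_error(weighted_kendall_tau(c(0.5, -0.1, 0.2), c(1, 2, 3)),
               "positive")
})

test_that("null_variance reduces to the classical Kendall variance", {
  for (n in 3:30) {
    cst <- 0.4
    expect_equal(null_variance(rep(cst, n)),
                 2 * (2 * n + 5) / (9 * n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("null_variance equals the full-enumeration variance for small n", {
  set.seed(55)
  for (n in 3:7) {
    for (rep in 1:3) {
      v <- runif(n, 0.05, 0.95)
      taus <- apply(tfconcord:::all_permutations(n), 2,
                    function(R) brute_force_tau(v, R))
      expect_equal(mean(taus), 0, tolerance = 1e-12)
      expect_equal(null_variance(v), mean(taus^2), tolerance = 1e-12)
    }
  }
})

test_that("null_variance matches Monte-Carlo variance at n = 200", {
  set.seed(56)
  v <- runif(200, 0.05, 0.95)
  taus <- tfconcord:::cpp_perm_taus(v, 20000)
  expect_lt(abs(var(taus) - null_variance(v)) / null_variance(v), 0.05)
})

test_that("asymptotic_p standardizes tau against N(0,1)", {
  expect_equal(asymptotic_p(0, 0.2), list(ld = 0, p = 1))
  ap <- asymptotic_p(0.38 / 0.62, 11 / 27)
  expect_equal(ap$ld, (0.38 / 0.62) / sqrt(11 / 27), tolerance = 1e-9)
  expect_equal(ap$p, 2 * pnorm(-abs(ap$ld)), tolerance = 1e-12)
  expect_equal(ap$p, 0.337, tolerance = 1e-3)
  expect_lt(asymptotic_p(-0.5, 0.01)$ld, 0)
  expect_error(asymptotic_p(0.1, 0), "positive")
})

test_that("permutation_p is reproducible, exact in exhaustive mode, and small on identity", {
  v <- runif(10, 0.2, 0.8)
  p1 <- permutation_p(v, 1:10, n_perm = 999, seed = 99)
  p2 <- permutation_p(v, 1:10, n_perm = 999, seed = 99)
  expect_identical(p1, p2)
  expect_lte(p1, 0.01)

  # n = 3 exhaustive: |tau| = 1 at identity and reversal -> p = 2/6
  v3 <- c(0.5, 0.4, 0.3)
  expect_equal(permutation_p(v3, c(1, 2, 3), exhaustive = TRUE), 2 / 6)
  # matches direct enumeration for a non-extreme ranking
  taus <- apply(tfconcord:::all_permutations(3), 2,
                function(R) brute_force_tau(v3, R))
  obs <- abs(brute_force_tau(v3, c(1, 3, 2)))
  expect_equal(permutation_p(v3, c(1, 3, 2), exhaustive = TRUE),
               mean(abs(taus) >= obs - 1e-12))
  expect_error(permutation_p(v3, c(1, 2, 3), n_perm = 10), "at least 100")
})

test_that("asymptotic and permutation p-values agree on random instances", {
  set.seed(57)
  for (rep in 1:5) {
    n <- 200
    v <- runif(n, 0.1, 0.9)
    R <- sample.int(n)
    tau <- weighted_kendall_tau(v, R)
    pa <- asymptotic_p(tau, null_variance(v))$p
    pp <- permutation_p(v, R, n_perm = 2000)
    se <- sqrt(max(pa * (1 - pa), 0.25 / 2000) / 2000)
    expect_lt(abs(pa - pp), 4 * se + 0.01)
  }
})

test_that("screen_tfs flags the planted repressor and adjusts across TFs", {
  sc <- small_screen(seed = 101)
  res <- sc$results
  expect_equal(res$tf_id[1], "FOCAL")
  expect_equal(res$direction[1], "negative")
  expect_lt(res$q_value[1], 0.05)
  expect_true(all(res$q_value >= res$p_asym - 1e-15))
  expect_equal(res$q_value, p.adjust(res$p_asym, "BH"))
  expect_true(all(res$weighting_mode == "mixed_density"))

  # one TF tested -> q equals p
  one <- screen_tfs(sc$gene_sets[sc$gene_sets$tf_id == "FOCAL", ],
                    sc$gene_list)
  expect_equal(one$q_value, one$p_asym)

  # no usable overlap -> empty result with a warning
  tiny_list <- sc$gene_list[1:2, ]
  expect_warning(
    suppressMessages(empty <- screen_tfs(sc$gene_sets, tiny_list)),
    "overlap")
  expect_equal(nrow(empty), 0L)
  expect_error(screen_tfs(sc$gene_sets, sc$gene_list[0, ]), "empty")
})
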