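test_that("methylation states follow the strict zero-threshold rule", {
  expect_equal(call_state(c(2.06, -1.29, 0, NA)),
               c("hypomethylated", "methylated", "boundary", NA))
})

test_that("the paired scan matches a closed-form oracle and reports means", {
  k <- 5
  d <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  set.seed(1)
  ctrl <- matrix(rnorm(k), 1)
  m <- toy_paired_matrix(ctrl, matrix(d, 1))
  st <- paired_t_scan(m, toy_samples(k))
  oracle <- oracle_paired_t(d)
  expect_equal(st$t, oracle$t, tolerance = 1e-12)
  expect_equal(st$p, oracle$p, tolerance = 1e-12)
  expect_equal(st$difference, mean(d), tolerance = 1e-12)
  expect_equal(st$n_pairs_used, k)

  # group means drive the reported difference (case minus control)
  m2 <- toy_paired_matrix(matrix(3.34, 1, k), matrix(2.56 - 3.34, 1, k))
  st2 <- paired_t_scan(m2, toy_samples(k))
  expect_equal(st2$mean_case, 2.56)
  expect_equal(st2$mean_control, 3.34)
  expect_equal(st2$difference, -0.78)
  expect_equal(st2$state_case, "hypomethylated")
})

test_that("identical groups give t = 0, p = 1; degeneracy is flagged", {
  # dyadic values so that adding a constant offset is exact in floating point
  ctrl <- matrix(sample(seq(-2, 2, by = 0.25), 12, TRUE), 4, 3)
  m <- toy_paired_matrix(ctrl, matrix(0, 4, 3))
  st <- paired_t_scan(m, toy_samples(3))
  expect_equal(st$t, rep(0, 4))
  expect_equal(st$p, rep(1, 4))
  expect_false(any(st$degenerate))

  # constant nonzero offset: zero spread around a nonzero mean
  m2 <- toy_paired_matrix(ctrl, matrix(0.5, 4, 3))
  st2 <- paired_t_scan(m2, toy_samples(3))
  expect_true(all(st2$degenerate))
  expect_true(all(is.na(st2$p)))

  bad <- toy_samples(3)
  bad$pair_id[2] <- "P09"
  expect_error(paired_t_scan(m, bad), "pair_id")
})

test_that("adding a constant to both members of a pair changes nothing", {
  set.seed(17)
  m <- toy_paired_matrix(matrix(rnorm(50 * 4), 50, 4),
                         matrix(rnorm(50 * 4, sd = .3), 50, 4))
  s <- toy_samples(4)
  st <- paired_t_scan(m, s)
  sc <- rank_scores(m, s)

  shifted <- m$values
  offs <- c(5, -2, 0.1, 100)
  for (j in 1:4) {
    shifted[, j] <- shifted[, j] + offs[j]
    shifted[, j + 4] <- shifted[, j + 4] + offs[j]
  }
  m2 <- methylation_matrix(shifted, m$loci)
  st2 <- paired_t_scan(m2, s)
  expect_equal(st2$t, st$t, tolerance = 1e-9)
  expect_equal(st2$p, st$p, tolerance = 1e-9)
  expect_equal(rank_scores(m2, s), sc, tolerance = 1e-9)
})

test_that("rank scores weight the fold-change and scale as the formula says", {
  set.seed(23)
  D <- matrix(rnorm(5 * 6, mean = .4, sd = .3), 5, 6)
  ctrl <- matrix(rnorm(5 * 6), 5, 6)
  m <- toy_paired_matrix(ctrl, D)
  s <- toy_samples(6)

  # zero mean difference scores zero regardless of spread
  m0 <- toy_paired_matrix(ctrl[1, , drop = FALSE],
                          matrix(c(-3, 3, -1, 1, -2, 2), 1))
  expect_equal(unname(rank_scores(m0, s, ranking_config(s0 = 0))), 0)

  # at s0 = 0 the score is a pure shape statistic: rescaling every pair
  # difference leaves it unchanged; with s0 > 0 amplification raises it
  sc1 <- rank_scores(m, s, ranking_config(s0 = 0))
  m2 <- toy_paired_matrix(ctrl, 2 * D)
  expect_equal(rank_scores(m2, s, ranking_config(s0 = 0)), sc1,
               tolerance = 1e-12)
  expect_true(all(rank_scores(m2, s, ranking_config(s0 = 0.5)) >
                    rank_scores(m, s, ranking_config(s0 = 0.5))))

  # direct brute-force recomputation, default s0 = median spread
  sds <- apply(D, 1, sd)
  expected <- abs(rowMeans(D)) / (sds + median(sds))
  expect_equal(unname(rank_scores(m, s)), expected, tolerance = 1e-12)
  expect_equal(order(-rank_scores(m, s)), order(-expected))
})

test_that("within-pair permutations enumerate exhaustively and match brute force", {
  set.seed(3)
  k <- 3
  m <- toy_paired_matrix(matrix(rnorm(6 * k), 6, k),
                         matrix(rnorm(6 * k, sd = .4), 6, k))
  s <- toy_samples(k)
  null <- permutation_null(m, s, n_perm = 100, seed = 1)
  expect_true(null$exhaustive)
  expect_equal(null$n_perm, 2^k - 1)   # non-identity sign patterns only

  # k = 5: per-locus permutation p against the all-32-pattern oracle
  k <- 5
  m <- toy_paired_matrix(matrix(rnorm(8 * k), 8, k),
                         matrix(rnorm(8 * k, mean = .3, sd = .4), 8, k))
  s <- toy_samples(k)
  D <- m$values[, 1:k] - m$values[, k + 1:k]
  null <- permutation_null(m, s, n_perm = 32, seed = 1)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
  t_obs <- apply(D, 1, function(d) mean(d) / (sd(d) / sqrt(k)))
  p_oracle <- sapply(seq_len(nrow(D)), function(i) {
    t_all <- apply(signs, 1, function(s_) {
      ds <- D[i, ] * s_
      mean(ds) / (sd(ds) / sqrt(k))
    })
    mean(abs(t_all) >= abs(t_obs[i]))
  })
  expect_equal(unname(null$perm_p), p_oracle, tolerance = 1e-12)

  # identity labelling reproduces the observed p-vector
  st <- paired_t_scan(m, s)
  expect_true(all(null$perm_p >= 1 / 32))
  expect_equal(ncol(null$p_matrix), 31)
  expect_error(permutation_null(m, s, n_perm = 0), "n_perm")
})

test_that("full relabelling permutes group labels with an unpaired test", {
  set.seed(6)
  m <- toy_paired_matrix(matrix(rnorm(30 * 4), 30, 4),
                         matrix(rnorm(30 * 4, sd = .3), 30, 4))
  null <- permutation_null(m, toy_samples(4), n_perm = 20,
                           scheme = "full_relabel", seed = 9)
  expect_equal(null$scheme, "full_relabel")
  expect_equal(null$n_perm, 20)
  expect_true(all(null$min_p > 0 & null$min_p <= 1))
  # determinism under the seed
  null2 <- permutation_null(m, toy_samples(4), n_perm = 20,
                            scheme = "full_relabel", seed = 9)
  expect_identical(null$min_p, null2$min_p)
})

test_that("the threshold ladder lands strictly below the permutation floor", {
  mk <- function(p) structure(list(min_p = p), class = "PermutationNull")
  expect_equal(significance_threshold(mk(1.5e-5))$alpha_star, 1e-5)
  expect_equal(significance_threshold(mk(0.04))$alpha_star, 1e-2)
  expect_equal(significance_threshold(mk(1))$alpha_star, 0.5)
  expect_equal(significance_threshold(mk(c(0.2, 0.007, 0.9)))$alpha_star, 5e-3)
  expect_equal(significance_threshold(mk(1.5e-5))$permutation_min_p, 1.5e-5)
  expect_error(significance_threshold(mk(numeric())), "empty")
})

test_that("candidate tiers split and count as a hand tally says", {
  set.seed(2)
  st <- paired_t_scan(toy_paired_matrix(matrix(rnorm(20 * 3), 20, 3),
                                        matrix(rnorm(20 * 3), 20, 3)),
                      toy_samples(3))
  st$p <- seq(0.0005, by = 0.005, length.out = 20)   # known spread of p
  sel <- select_candidates(st, alpha_star = 0.01, moderate_alpha = 0.05)
  expect_equal(nrow(sel$significant), sum(st$p < 0.01))
  expect_equal(nrow(sel$moderate), sum(st$p >= 0.01 & st$p < 0.05))
  expect_equal(sum(sel$histogram$count), 20)
  expect_false(is.unsorted(sel$significant$p))

  # monotone in alpha_star: raising the threshold never drops a candidate
  sel2 <- select_candidates(st, alpha_star = 0.03, moderate_alpha = 0.05)
  expect_true(all(sel$significant$locus_id %in% sel2$significant$locus_id))

  st$p <- rep(1, 20)
  sel3 <- select_candidates(st, 1e-5, 1e-4)
  expect_equal(nrow(sel3$significant) + nrow(sel3$moderate), 0L)

  expect_error(select_candidates(st, 0.01, 0.01), "moderate_alpha")
})

test_that("null scans are calibrated: tier rates near alpha", {
  co <- simulate_cohort(simulation_config(n_loci = 4000, n_pairs = 5,
                                          frac_differential = 0, seed = 14))
  st <- paired_t_scan(co$matrix, co$samples)
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(st$p < alpha)
    bound <- 2.576 * sqrt(alpha * (1 - alpha) / nrow(st))
    expect_lt(abs(frac - alpha), bound + 1e-12)
  }
})
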