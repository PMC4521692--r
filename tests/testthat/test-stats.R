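test_that("rank-sum exact mode reproduces enumeration results", {
  # hand-checkable case: complete separation of 3 vs 4 values -> 2/35
  expect_equal(rank_sum_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6, 0.7),
                             method = "exact"), 2 / 35)
  # identical groups: no separation
  expect_equal(rank_sum_test(rep(0.4, 5), rep(0.4, 6)), 1)
  # cross-check against the reference exact implementation over many
  # tie-free splits
  set.seed(42)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      for (rep in 1:3) {
        a <- runif(na)
        b <- runif(nb)
        expect_equal(
          rank_sum_test(a, b, method = "exact"),
          suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value),
          tolerance = 1e-12,
          info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
      }
    }
  }
})

test_that("rank-sum exact mode handles ties by midrank enumeration", {
  a <- c(0.2, 0.2, 0.5)
  b <- c(0.2, 0.7, 0.7)
  # direct enumeration oracle over all C(6,3) assignments of the midranks
  r <- rank(c(a, b))
  W <- sum(r[1:3])
  Wd <- combn(6, 3, FUN = function(i) sum(r[i]))
  mu <- 3 * 7 / 2
  p_oracle <- min(1, 2 * min(mean(Wd <= W + 1e-9), mean(Wd >= W - 1e-9)))
  expect_equal(rank_sum_test(a, b, method = "exact"), p_oracle)
})

test_that("rank-sum normal approximation matches the tie-corrected reference", {
  set.seed(7)
  for (rep in 1:10) {
    a <- round(runif(10), 2)  # rounding forces occasional ties
    b <- round(runif(12), 2)
    expect_equal(
      rank_sum_test(a, b, method = "normal"),
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                          correct = FALSE)$p.value),
      tolerance = 1e-10)
    expect_equal(
      rank_sum_test(a, b, method = "normal", correct = TRUE),
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                          correct = TRUE)$p.value),
      tolerance = 1e-10)
  }
})

test_that("rank-sum normal approximation agrees with a permutation oracle", {
  set.seed(11)
  a <- runif(10)
  b <- runif(12)
  p_norm <- rank_sum_test(a, b, method = "normal")
  r <- rank(c(a, b))
  W <- sum(r[1:10])
  mu <- 10 * 23 / 2
  B <- 1e5
  exceed <- 0L
  for (i in seq_len(B)) {
    Wp <- sum(r[sample.int(22, 10)])
    if (abs(Wp - mu) >= abs(W - mu) - 1e-9) exceed <- exceed + 1L
  }
  expect_lt(abs(p_norm - exceed / B), 0.01)
})

test_that("rank-sum rejects degenerate input", {
  expect_error(rank_sum_test(numeric(0), c(0.5)), "non-empty")
  expect_error(rank_sum_test(c(0.5), c(1.2)), "\\[0, 1\\]")
  expect_error(rank_sum_test(c(0.5, NA), c(0.2)), "missing")
})

test_that("BH adjustment matches hand-derived step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  # step-up from the largest p: all become m * p_(i) / i minimised
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # order of output matches order of input
  p <- c(0.04, 0.001, 0.5)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone, dominates p, and is idempotent-safe", {
  set.seed(3)
  for (rep in 1:50) {
    p <- runif(sample(2:60, 1))
    f <- bh_adjust(p)
    expect_true(all(f >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(f[o]) >= -1e-12))
    expect_true(all(bh_adjust(f) >= f - 1e-12))
  }
})

test_that("complete-case filter removes exactly the incomplete probes", {
  m <- matrix(runif(15), nrow = 5,
              dimnames = list(paste0("cg", 1:5), c("A", "B", "C")))
  g <- c(A = "MBC", B = "MBC", C = "CVS")
  bm0 <- beta_matrix(m, g)
  r0 <- complete_case_filter(bm0)
  expect_equal(r0$removed, 0)
  expect_identical(r0$matrix$values, m)

  m[2, "B"] <- NA
  bm1 <- beta_matrix(m, g)
  r1 <- complete_case_filter(bm1)
  expect_equal(r1$removed, 1)
  expect_equal(rownames(r1$matrix$values), paste0("cg", c(1, 3:5)))
})

test_that("simulated missingness lands in the binomial range of the filter", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 1000, n_planted_dmc = 0, missing_probe_fraction = 0.1,
    n_snp_probes = 0, n_replicate_pairs = 0, seed = 1))
  r <- complete_case_filter(sim$beta)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(r$removed, ci[1])
  expect_lte(r$removed, ci[2])
})

test_that("probe_stats reproduces printed group means and deltas", {
  bm <- const_beta_matrix(0.86, 0.09, probe = "cg00674220")
  st <- probe_stats(bm)
  expect_equal(st$mbc_mean, 0.86)
  expect_equal(st$cvs_mean, 0.09)
  expect_equal(st$delta, 0.77)

  st2 <- probe_stats(const_beta_matrix(0.97, 0.10, probe = "cg25951288"))
  expect_equal(st2$delta, 0.87)

  st3 <- probe_stats(const_beta_matrix(0.5, 0.5))
  expect_equal(st3$delta, 0)
})

test_that("probe_stats excludes QC replicate columns and errors on NA", {
  m <- matrix(c(0.1, 0.2, 0.9, 0.8, 0.99), nrow = 1,
              dimnames = list("cg1", c("M1", "M2", "C1", "C2", "C1r")))
  g <- c(M1 = "MBC", M2 = "MBC", C1 = "CVS", C2 = "CVS", C1r = "CVS")
  bm <- beta_matrix(m, g, data.frame(sample_a = "C2", sample_b = "C1r"))
  st <- probe_stats(bm)
  # CVS mean over C1 only: C2/C1r form a QC pair
  expect_equal(st$cvs_mean, 0.9)
  m[1, "M1"] <- NA
  expect_error(probe_stats(beta_matrix(m, g)), "complete_case_filter")
})

test_that("delta is invariant under relabelling the groups", {
  set.seed(5)
  m <- matrix(runif(40), nrow = 4,
              dimnames = list(paste0("cg", 1:4),
                              c(paste0("M", 1:4), paste0("C", 1:6))))
  g1 <- c(rep("MBC", 4), rep("CVS", 6))
  g2 <- c(rep("CVS", 4), rep("MBC", 6))
  s1 <- probe_stats(beta_matrix(m, g1))
  s2 <- probe_stats(beta_matrix(m, g2))
  expect_equal(s1$delta, s2$delta)
  expect_equal(s1$p_value, s2$p_value)
})

test_that("type-I error is calibrated under the global null", {
  for (seed in 1:3) {
    sim <- simulate_dataset(simulation_config(
      n_probes = 2000, n_planted_dmc = 0, missing_probe_fraction = 0,
      n_snp_probes = 0, n_replicate_pairs = 0, seed = seed))
    st <- probe_stats(sim$beta, method = "normal")
    frac <- mean(st$p_value < 0.05)
    expect_gt(frac, 0.03)
    expect_lt(frac, 0.07)
  }
})
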