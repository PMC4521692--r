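test_that("DMC stage uses strict inequalities on FDR and delta", {
  t <- funnel_thresholds()
  s <- data.frame(fdr = c(0.04, 0.05, 0.01), delta = c(0.25, 0.5, 0.2))
  expect_equal(stage_dmc(s, t), c(TRUE, FALSE, FALSE))
})

test_that("strict stage assigns directions from group means", {
  t <- funnel_thresholds()
  s <- data.frame(mbc_mean = c(0.86, 0.06, 0.5), cvs_mean = c(0.09, 0.86, 0.5))
  expect_equal(stage_strict(s, t),
               c("cvs_hypo_mbc_hyper", "mbc_hypo_cvs_hyper", "none"))
  # boundary values give no call
  s2 <- data.frame(mbc_mean = c(0.25, 0.1), cvs_mean = c(0.9, 0.75))
  expect_equal(stage_strict(s2, t), c("none", "none"))
})

test_that("consistency stage counts per-sample threshold passes", {
  t <- funnel_thresholds()  # min 10 MBC, min 10 CVS
  mbc <- rep(0.1, 10)
  cvs <- c(rep(0.9, 10), 0.5, 0.5)   # 10 of 12 pass
  beta <- c(mbc, cvs)
  groups <- c(rep("MBC", 10), rep("CVS", 12))
  expect_true(stage_consistency(beta, groups, "mbc_hypo_cvs_hyper", t))
  # 9 of 10 MBC passing fails the absolute minimum of 10
  beta2 <- c(0.5, rep(0.1, 9), rep(0.9, 12))
  expect_false(stage_consistency(beta2, groups, "mbc_hypo_cvs_hyper", t))
  # 12 of 12 CVS passing is fine
  beta3 <- c(mbc, rep(0.9, 12))
  expect_true(stage_consistency(beta3, groups, "mbc_hypo_cvs_hyper", t))
  expect_error(stage_consistency(beta, groups, "none", t), "direction")
})

test_that("funnel recovers planted markers and keeps counts nested", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 1000, n_planted_dmc = 50, missing_probe_fraction = 0,
    seed = 1))
  res <- run_funnel(sim$beta, sim$manifest)
  co <- res$counts
  expect_equal(unname(co["input"]), 1000)
  expect_equal(unname(co["complete"]), 1000)
  expect_true(all(diff(co) <= 0))
  rec <- res$records
  # nested stage flags
  expect_true(all(rec$passed_dmc[rec$passed_strict]))
  expect_true(all(rec$passed_strict[rec$passed_msre]))
  expect_true(all(rec$passed_msre[rec$passed_consistency]))
  # direction iff strict
  expect_equal(rec$direction != "none", rec$passed_strict)
  # all planted probes with sites recovered, essentially no false hits
  r <- planted_recovery(res, sim$truth)
  expect_gte(r$sensitivity, 0.9)
  expect_lte(r$fdp, 0.05)
})

test_that("an all-background dataset yields an empty final set", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 2000, n_planted_dmc = 0, missing_probe_fraction = 0,
    seed = 2))
  res <- run_funnel(sim$beta, sim$manifest)
  expect_equal(unname(res$counts["consistent"]), 0)
})

test_that("planted probes without MSRE sites fall exactly at the MSRE stage", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 400, n_planted_dmc = 30, frac_planted_with_msre = 0,
    missing_probe_fraction = 0, seed = 3))
  res <- run_funnel(sim$beta, sim$manifest)
  planted <- sim$truth$probe_id[sim$truth$is_planted_dmc]
  rec <- res$records[res$records$probe_id %in% planted, ]
  expect_true(all(rec$passed_strict))
  expect_false(any(rec$passed_msre))
  expect_equal(unname(res$counts["msre"]), 0)
})

test_that("relabelling MBC and CVS flips directions, keeps the final set", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 300, n_planted_dmc = 20, missing_probe_fraction = 0,
    n_replicate_pairs = 0, seed = 4))
  bm <- sim$beta
  flipped <- beta_matrix(bm$values,
                         ifelse(bm$groups == "MBC", "CVS", "MBC"),
                         bm$replicate_pairs)
  r1 <- run_funnel(bm, sim$manifest)
  r2 <- run_funnel(flipped, sim$manifest)
  f1 <- r1$records$probe_id[r1$records$passed_consistency]
  f2 <- r2$records$probe_id[r2$records$passed_consistency]
  expect_setequal(f1, f2)
  d1 <- r1$records$direction[r1$records$passed_strict]
  d2 <- r2$records$direction[r2$records$passed_strict]
  expect_equal(d2, ifelse(d1 == "mbc_hypo_cvs_hyper",
                          "cvs_hypo_mbc_hyper", "mbc_hypo_cvs_hyper"))
})

test_that("missing flank annotation is reported for strict survivors", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 200, n_planted_dmc = 10, missing_probe_fraction = 0,
    seed = 5))
  man <- sim$manifest
  planted <- sim$truth$probe_id[sim$truth$is_planted_dmc][1]
  man$flank[man$probe_id == planted] <- NA
  man$cpg_site[man$probe_id == planted] <- NA
  expect_error(run_funnel(sim$beta, man), planted)
})

test_that("candidate tables round-trip through the report layout", {
  cm <- candidate_markers()
  expect_equal(nrow(cm), 44)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dmc_table(cm, p)
  cm2 <- read_candidates(p)
  expect_equal(cm2$probe_id, cm$probe_id)
  expect_equal(cm2$mbc_mean, cm$mbc_mean)
  expect_equal(cm2$direction, cm$direction)
})
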