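test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(n_planted_dmc = 10, n_probes = 5),
               "n_planted_dmc")
  expect_error(simulation_config(missing_probe_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(flank_length = 60), "odd")
  expect_error(simulation_config(flank_length = 5), "odd")
  expect_error(simulation_config(hypo_beta_params = c(1, -2)), "positive")
  # flank must host the longest enzyme pattern around the centre
  cfg <- simulation_config(flank_length = 9)
  expect_error(simulate_dataset(cfg), "flank_length too short")
})

test_that("the empty configuration yields empty outputs", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 0, n_planted_dmc = 0, n_snp_probes = 0,
    n_replicate_pairs = 0, seed = 1))
  expect_equal(nrow(sim$beta$values), 0)
  expect_equal(ncol(sim$beta$values), 22)
  expect_equal(nrow(sim$manifest), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("planted counts and directions are exactly as configured", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 1000, n_planted_dmc = 50, missing_probe_fraction = 0,
    n_snp_probes = 0, n_replicate_pairs = 0, seed = 1))
  tr <- sim$truth
  expect_equal(sum(tr$is_planted_dmc), 50)
  expect_equal(sum(tr$planted_direction == "none"), 950)
  # direction is none iff not planted
  expect_equal(tr$planted_direction != "none", tr$is_planted_dmc)
  # no missing cells requested, none produced
  expect_false(anyNA(sim$beta$values))
})

test_that("identical seeds reproduce the dataset exactly", {
  cfg <- simulation_config(n_probes = 300, n_planted_dmc = 10, seed = 7)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$beta$values, b$beta$values)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_dataset(simulation_config(n_probes = 300,
                                           n_planted_dmc = 10, seed = 8))
  expect_false(identical(a$beta$values, c_$beta$values))
})

test_that("all generated values are beta fractions or missing", {
  sim <- simulate_dataset(simulation_config(n_probes = 500, seed = 2))
  v <- sim$beta$values
  expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  expect_equal(ncol(v), 10 + 12 + 2 * 4)
  # sample sheet structure
  expect_equal(sum(sim$beta$groups[primary_samples(sim$beta)] == "MBC"), 10)
  expect_equal(sum(sim$beta$groups[primary_samples(sim$beta)] == "CVS"), 12)
  expect_equal(nrow(sim$beta$replicate_pairs), 4)
})

test_that("planted probes clear the strict thresholds with high probability", {
  # simulation-based check of the generator contract: the default planted
  # distributions make an n=10/12 probe pass group means and per-sample
  # counts essentially always
  sim <- simulate_dataset(simulation_config(
    n_probes = 500, n_planted_dmc = 500, missing_probe_fraction = 0,
    n_snp_probes = 0, n_replicate_pairs = 0, seed = 3))
  bm <- sim$beta
  mbc <- primary_samples(bm, "MBC")
  cvs <- primary_samples(bm, "CVS")
  t <- funnel_thresholds()
  pass <- vapply(seq_len(nrow(bm$values)), function(i) {
    dirn <- sim$truth$planted_direction[i]
    hypo <- if (dirn == "mbc_hypo_cvs_hyper") bm$values[i, mbc]
            else bm$values[i, cvs]
    hyper <- if (dirn == "mbc_hypo_cvs_hyper") bm$values[i, cvs]
             else bm$values[i, mbc]
    mean(hypo) < 0.25 && mean(hyper) > 0.75 &&
      sum(bm$values[i, mbc] < 0.25 | bm$values[i, mbc] > 0.75) >= 10 &&
      sum(bm$values[i, cvs] < 0.25 | bm$values[i, cvs] > 0.75) >= 10
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("SNP probes are trimodal and shared across replicate columns", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 10, n_planted_dmc = 0, missing_probe_fraction = 0, seed = 4))
  snp <- sim$manifest$probe_id[sim$manifest$is_snp]
  v <- sim$beta$values[snp, ]
  # values concentrate tightly around the three genotype modes
  d <- pmin(abs(v), abs(v - 0.5), abs(v - 1))
  expect_gt(mean(d < 0.1), 0.9)
  expect_true(all(d <= 0.25))
  # replicates track their source within the configured noise scale
  pairs <- sim$beta$replicate_pairs
  for (i in seq_len(nrow(pairs))) {
    src <- sub("\\.r[12]$", "", pairs$sample_a[i])
    for (col in c(pairs$sample_a[i], pairs$sample_b[i])) {
      expect_lt(max(abs(sim$beta$values[snp, col] -
                          sim$beta$values[snp, src])), 6 * 0.01)
    }
  }
})

test_that("planted flanks carry or lack MSRE sites exactly as recorded", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 120, n_planted_dmc = 60, frac_planted_with_msre = 0.5,
    missing_probe_fraction = 0, n_snp_probes = 0, seed = 5))
  enz <- default_enzymes()
  man <- sim$manifest
  tr <- sim$truth
  for (i in which(tr$is_planted_dmc)) {
    hits <- cpg_msre_hits(man$flank[i], man$cpg_site[i], enz)
    if (tr$has_planted_msre_site[i]) {
      expect_gt(nrow(hits), 0, label = man$probe_id[i])
    } else {
      # MSRE-free flanks host no site anywhere, on either strand
      expect_equal(nrow(hits), 0)
      for (j in seq_len(nrow(enz)))
        expect_equal(nrow(oracle_find_sites(man$flank[i], enz$pattern[j])),
                     0)
    }
  }
  # non-SNP flanks always carry the central CpG
  centre <- (61 + 1) %/% 2
  expect_true(all(substr(man$flank[!man$is_snp], centre, centre + 1) == "CG"))
})

test_that("datasets round-trip through write_dataset/read_* unchanged", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 60, n_planted_dmc = 5, seed = 6))
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  bm <- read_beta_matrix(file.path(d, "beta.tsv"), file.path(d, "groups.tsv"))
  expect_equal(bm$values, sim$beta$values, tolerance = 1e-12)
  expect_identical(bm$groups, sim$beta$groups)
  expect_identical(sort(c(bm$replicate_pairs$sample_a,
                          bm$replicate_pairs$sample_b)),
                   sort(c(sim$beta$replicate_pairs$sample_a,
                          sim$beta$replicate_pairs$sample_b)))
  man <- read_manifest(file.path(d, "manifest.tsv"))
  expect_equal(man, sim$manifest)
  tr <- read_truth(file.path(d, "truth.tsv"))
  expect_equal(tr, sim$truth)
})
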