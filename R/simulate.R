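# approximate autosome lengths (bp), used to spread simulated probes
.default_chrom_lengths <- c(
  chr1 = 249e6, chr2 = 243e6, chr3 = 198e6, chr4 = 191e6, chr5 = 181e6,
  chr6 = 171e6, chr7 = 159e6, chr8 = 146e6, chr9 = 141e6, chr10 = 136e6,
  chr11 = 135e6, chr12 = 134e6, chr13 = 115e6, chr14 = 107e6,
  chr15 = 103e6, chr16 = 90e6, chr17 = 81e6, chr18 = 78e6, chr19 = 59e6,
  chr20 = 63e6, chr21 = 48e6, chr22 = 51e6)

#' Configuration of the synthetic beta-value study
#'
#' Defines a two-group 450K-style methylation dataset: `n_mbc` maternal
#' blood cell samples vs `n_cvs` chorionic villus samples, a background
#' of non-differential probes, `n_planted_dmc` planted fully-differential
#' CpGs (one group drawn from a concentrated hypomethylated Beta, the
#' other from its hypermethylated mirror), per-probe missingness, SNP
#' control probes with trimodal genotype values, technical replicate
#' column pairs, and per-probe flanking sequences that do or do not host
#' an MSRE recognition site spanning the central CpG.
#'
#' Default shapes: background `Beta(5, 5)`; planted hypo `Beta(1, 30)`
#' and hyper `Beta(30, 1)`, concentrated enough that a planted probe
#' clears the strict per-sample thresholds (all 10 MBC below 0.25, at
#' least 10 of 12 CVS above 0.75, or vice versa) with probability
#' around 0.998 while remaining stochastic.  Noise scales
#' (`snp_noise_sd` 0.05, `replicate_noise_sd` 0.01) are calibrated so
#' replicate SNP-probe Spearman correlations fall in the 0.96-0.98
#' regime typical of well-behaved arrays.
#'
#' @param n_probes number of non-SNP probes
#' @param n_mbc,n_cvs primary samples per group
#' @param n_planted_dmc number of planted fully-differential probes
#' @param frac_planted_mbc_hypo fraction of planted probes with
#'   direction MBC-hypo/CVS-hyper (the rest are reversed)
#' @param background_beta_params,hypo_beta_params,hyper_beta_params
#'   shape pairs of the Beta distributions
#' @param missing_probe_fraction per-probe probability of carrying at
#'   least one missing primary-sample cell (default 0.0285, the
#'   incomplete-probe rate of a 485,777 -> 471,956 complete-case filter)
#' @param n_snp_probes number of SNP control probes (default 65)
#' @param n_replicate_pairs number of technical replicate pairs (two
#'   extra QC columns each, alternating MBC/CVS source individuals)
#' @param snp_noise_sd measurement noise sd around the genotype value of
#'   a SNP probe
#' @param replicate_noise_sd sd of the noise added to a source column to
#'   form each replicate column (values re-clamped to `[0, 1]`)
#' @param flank_length length of the flanking sequence (odd; the target
#'   CpG sits at the centre)
#' @param frac_planted_with_msre fraction of planted probes whose flank
#'   hosts an MSRE site spanning the central CpG; the remaining planted
#'   flanks are generated free of any configured enzyme site on either
#'   strand
#' @param chrom_lengths named vector of chromosome lengths over which
#'   probes are spread uniformly
#' @param seed integer RNG seed; identical seeds reproduce the dataset
#'   exactly
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_probes = 5000, n_mbc = 10, n_cvs = 12,
                              n_planted_dmc = 50,
                              frac_planted_mbc_hypo = 0.5,
                              background_beta_params = c(5, 5),
                              hypo_beta_params = c(1, 30),
                              hyper_beta_params = c(30, 1),
                              missing_probe_fraction = 0.0285,
                              n_snp_probes = 65,
                              n_replicate_pairs = 4,
                              snp_noise_sd = 0.05,
                              replicate_noise_sd = 0.01,
                              flank_length = 61,
                              frac_planted_with_msre = 1,
                              chrom_lengths = .default_chrom_lengths,
                              seed = 1L) {
  cfg <- list(n_probes = n_probes, n_mbc = n_mbc, n_cvs = n_cvs,
              n_planted_dmc = n_planted_dmc,
              frac_planted_mbc_hypo = frac_planted_mbc_hypo,
              background_beta_params = background_beta_params,
              hypo_beta_params = hypo_beta_params,
              hyper_beta_params = hyper_beta_params,
              missing_probe_fraction = missing_probe_fraction,
              n_snp_probes = n_snp_probes,
              n_replicate_pairs = n_replicate_pairs,
              snp_noise_sd = snp_noise_sd,
              replicate_noise_sd = replicate_noise_sd,
              flank_length = flank_length,
              frac_planted_with_msre = frac_planted_with_msre,
              chrom_lengths = chrom_lengths, seed = as.integer(seed))
  counts <- c("n_probes", "n_mbc", "n_cvs", "n_planted_dmc",
              "n_snp_probes", "n_replicate_pairs")
  for (f in counts)
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  fracs <- c("frac_planted_mbc_hypo", "missing_probe_fraction",
             "frac_planted_with_msre")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  for (f in c("background_beta_params", "hypo_beta_params",
              "hyper_beta_params"))
    if (length(cfg[[f]]) != 2 || any(cfg[[f]] <= 0))
      stop(f, " must be a pair of positive shape parameters",
           call. = FALSE)
  if (cfg$n_planted_dmc > cfg$n_probes)
    stop("n_planted_dmc must not exceed n_probes", call. = FALSE)
  if (cfg$snp_noise_sd < 0 || cfg$replicate_noise_sd < 0)
    stop("noise sds must be >= 0", call. = FALSE)
  if (cfg$flank_length %% 2 != 1 || cfg$flank_length < 7)
    stop("flank_length must be odd and >= 7 so a recognition site can span the central CpG",
         call. = FALSE)
  if (cfg$n_replicate_pairs > cfg$n_mbc + cfg$n_cvs)
    stop("more replicate pairs than primary samples", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

.clamp01 <- function(x) {  # keeps dim/dimnames, unlike pmin/pmax(scalar, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# random flank strings with the target CG forced at the centre
.random_flanks <- function(k, len, centre) {
  if (k == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
              nrow = k)
  m[, centre] <- "C"
  m[, centre + 1L] <- "G"
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# one concrete realisation of an IUPAC pattern
.concretize <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste0(vapply(chars, function(ch) {
    set <- .iupac_sets[[ch]]
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

.cg_positions <- function(s) {
  n <- nchar(s)
  if (n < 2) return(integer(0))
  which(substring(s, 1:(n - 1), 2:n) == "CG")
}

.flank_has_any_site <- function(flank, enzymes) {
  for (i in seq_len(nrow(enzymes))) {
    p <- enzymes$pattern[i]
    if (length(match_iupac(p, flank)) > 0) return(TRUE)
    if (!.is_palindromic(p) &&
        length(match_iupac(revcomp(p), flank)) > 0) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic two-group methylation dataset
#'
#' Draws a full dataset under a [simulation_config()]: beta-value matrix
#' (primary MBC/CVS columns plus QC replicate columns), probe manifest
#' with flanking sequences, and a ground-truth table recording which
#' probes were planted as fully differential and whether their flank
#' hosts an MSRE site spanning the central CpG.  Deterministic given the
#' config seed.
#'
#' @param config a [simulation_config()]
#' @param enzymes an enzyme table used for site embedding / exclusion
#' @return list with elements `beta` (a [beta_matrix()]), `manifest`
#'   (probe annotation data frame) and `truth` (data frame with columns
#'   `probe_id`, `is_planted_dmc`, `planted_direction`,
#'   `has_planted_msre_site`)
#' @export
simulate_dataset <- function(config = simulation_config(),
                             enzymes = default_enzymes()) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must come from simulation_config()", call. = FALSE)
  maxk <- if (nrow(enzymes) > 0) max(nchar(enzymes$pattern)) else 0L
  if (config$flank_length < 2 * maxk + 1)
    stop("flank_length too short to host the longest enzyme pattern ",
         "on either side of the central CpG (need >= ", 2 * maxk + 1, ")",
         call. = FALSE)
  set.seed(config$seed)

  n <- config$n_probes
  nm <- config$n_mbc
  nc <- config$n_cvs
  ns <- config$n_snp_probes
  mbc_ids <- sprintf("MBC%02d", seq_len(nm))
  cvs_ids <- sprintf("CVS%02d", seq_len(nc))
  prim_ids <- c(mbc_ids, cvs_ids)
  groups <- stats::setNames(c(rep("MBC", nm), rep("CVS", nc)), prim_ids)

  probe_ids <- if (n > 0)
    sprintf("cg%08d", sample.int(99999999L, n)) else character(0)
  snp_ids <- if (ns > 0)
    sprintf("rs%07d", sample.int(9999999L, ns)) else character(0)

  # planted probes and their directions
  planted <- logical(n)
  direction <- rep("none", n)
  if (config$n_planted_dmc > 0) {
    sel <- sample.int(n, config$n_planted_dmc)
    planted[sel] <- TRUE
    n_hypo <- round(config$frac_planted_mbc_hypo * length(sel))
    hypo_sel <- if (n_hypo > 0) sel[seq_len(n_hypo)] else integer(0)
    direction[hypo_sel] <- "mbc_hypo_cvs_hyper"
    direction[setdiff(sel, hypo_sel)] <- "cvs_hypo_mbc_hyper"
  }

  # primary beta values
  bg <- config$background_beta_params
  hypo <- config$hypo_beta_params
  hyper <- config$hyper_beta_params
  vals <- matrix(stats::rbeta(n * (nm + nc), bg[1], bg[2]), nrow = n,
                 ncol = nm + nc, dimnames = list(probe_ids, prim_ids))
  draw <- function(k, shape) stats::rbeta(k, shape[1], shape[2])
  i_h <- which(direction == "mbc_hypo_cvs_hyper")
  if (length(i_h) > 0) {
    vals[i_h, mbc_ids] <- draw(length(i_h) * nm, hypo)
    vals[i_h, cvs_ids] <- draw(length(i_h) * nc, hyper)
  }
  i_r <- which(direction == "cvs_hypo_mbc_hyper")
  if (length(i_r) > 0) {
    vals[i_r, mbc_ids] <- draw(length(i_r) * nm, hyper)
    vals[i_r, cvs_ids] <- draw(length(i_r) * nc, hypo)
  }

  # SNP control probes: per-individual genotype at {0, 0.5, 1} + noise
  snp_geno <- matrix(sample(c(0, 0.5, 1), ns * (nm + nc), replace = TRUE,
                            prob = c(0.25, 0.5, 0.25)),
                     nrow = ns, ncol = nm + nc,
                     dimnames = list(snp_ids, prim_ids))
  snp_vals <- .clamp01(snp_geno +
                         stats::rnorm(length(snp_geno), 0,
                                      config$snp_noise_sd))
  values <- rbind(vals, snp_vals)

  # technical replicate pairs: two fresh QC columns per source
  # individual, alternating MBC / CVS sources
  pairs <- NULL
  if (config$n_replicate_pairs > 0) {
    k <- config$n_replicate_pairs
    pool_len <- max(nm, nc)
    pool <- as.vector(rbind(c(mbc_ids, rep(NA, pool_len - nm)),
                            c(cvs_ids, rep(NA, pool_len - nc))))
    sources <- utils::head(pool[!is.na(pool)], k)
    rep_cols <- matrix(NA_real_, nrow = nrow(values), ncol = 2 * k)
    rep_ids <- character(2 * k)
    for (j in seq_len(k)) {
      src <- values[, sources[j]]
      rep_ids[2 * j - 1] <- paste0(sources[j], ".r1")
      rep_ids[2 * j] <- paste0(sources[j], ".r2")
      rep_cols[, 2 * j - 1] <- .clamp01(
        src + stats::rnorm(length(src), 0, config$replicate_noise_sd))
      rep_cols[, 2 * j] <- .clamp01(
        src + stats::rnorm(length(src), 0, config$replicate_noise_sd))
    }
    colnames(rep_cols) <- rep_ids
    values <- cbind(values, rep_cols)
    groups <- c(groups,
                stats::setNames(groups[sources[rep(seq_len(k), each = 2)]],
                                rep_ids))
    pairs <- data.frame(sample_a = rep_ids[seq(1, 2 * k, by = 2)],
                        sample_b = rep_ids[seq(2, 2 * k, by = 2)],
                        stringsAsFactors = FALSE)
  }

  # per-probe missingness (primary columns of non-SNP probes)
  if (config$missing_probe_fraction > 0 && n > 0) {
    miss <- which(stats::runif(n) < config$missing_probe_fraction)
    for (i in miss) {
      k_cells <- 1L + stats::rpois(1, 0.3)
      k_cells <- min(k_cells, nm + nc)
      cols <- sample(prim_ids, k_cells)
      values[i, cols] <- NA_real_
    }
  }

  # genomic placement, proportional to chromosome length
  cl <- config$chrom_lengths
  all_ids <- c(probe_ids, snp_ids)
  chrom <- sample(names(cl), length(all_ids), replace = TRUE,
                  prob = cl / sum(cl))
  position <- ceiling(stats::runif(length(all_ids)) * cl[chrom])

  # flanking sequences
  centre <- (config$flank_length + 1L) %/% 2L
  flanks <- .random_flanks(n, config$flank_length, centre)
  has_site <- logical(n)
  if (any(planted) && nrow(enzymes) > 0) {
    has_site[planted] <- stats::runif(sum(planted)) <
      config$frac_planted_with_msre
    for (i in which(planted & has_site)) {
      e <- sample.int(nrow(enzymes), 1)
      concrete <- .concretize(enzymes$pattern[e])
      cg <- .cg_positions(concrete)
      if (length(cg) == 0) {  # CpG-free pattern: cannot span the CpG
        has_site[i] <- FALSE
        next
      }
      pick <- cg[sample.int(length(cg), 1)]
      start <- centre - pick + 1L
      f <- flanks[i]
      substr(f, start, start + nchar(concrete) - 1L) <- concrete
      flanks[i] <- f
    }
    for (i in which(planted & !has_site)) {
      tries <- 0L
      repeat {
        if (!.flank_has_any_site(flanks[i], enzymes)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not generate an MSRE-free flank; enzyme set too dense",
               call. = FALSE)
        flanks[i] <- .random_flanks(1L, config$flank_length, centre)
      }
    }
  }

  manifest <- data.frame(
    probe_id = all_ids,
    chromosome = chrom,
    position = as.integer(position),
    gene = rep(NA_character_, length(all_ids)),
    refseq = rep(NA_character_, length(all_ids)),
    flank = c(flanks, rep("N", ns)),
    cpg_site = c(rep(centre, n), rep(NA_integer_, ns)),
    is_snp = c(rep(FALSE, n), rep(TRUE, ns)),
    stringsAsFactors = FALSE)
  manifest <- probe_annotation(manifest)

  truth <- data.frame(
    probe_id = all_ids,
    is_planted_dmc = c(planted, rep(FALSE, ns)),
    planted_direction = c(direction, rep("none", ns)),
    has_planted_msre_site = c(has_site, rep(FALSE, ns)),
    stringsAsFactors = FALSE)

  list(beta = beta_matrix(values, groups, pairs),
       manifest = manifest, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Writes `beta.tsv`, `groups.tsv`, `manifest.tsv` and `truth.tsv` in
#' the package's standard dialects.
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"),
                    file.path(dir, "groups.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a ground-truth table written by [write_dataset()]
#' @param path path to `truth.tsv`
#' @return data frame
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  data.frame(probe_id = df$probe_id,
             is_planted_dmc = as.logical(df$is_planted_dmc),
             planted_direction = df$planted_direction,
             has_planted_msre_site = as.logical(df$has_planted_msre_site),
             stringsAsFactors = FALSE)
}
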