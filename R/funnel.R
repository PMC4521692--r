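# canonical direction labels
.DIR_MBC_HYPO <- "mbc_hypo_cvs_hyper"
.DIR_CVS_HYPO <- "cvs_hypo_mbc_hyper"
.DIR_NONE <- "none"

#' Thresholds of the five-stage DMC funnel
#'
#' All comparisons in the funnel are strict: a probe is a DMC when
#' `fdr < fdr_cut` and `delta > delta_cut`; a group is hypomethylated
#' when its mean beta `< hypo_cut` and hypermethylated when `> hyper_cut`;
#' the consistency stage requires at least `min_pass_mbc` MBC samples and
#' `min_pass_cvs` CVS samples to individually clear the same cut values.
#' The defaults (0.05, 0.2, 0.25, 0.75, 10, 10) are the published
#' screening conditions; with 10 MBC and 12 CVS samples an absolute
#' count of 10 reproduces the "10 out of 10 MBC and 10 out of 12 CVS"
#' rule.
#'
#' @param fdr_cut FDR cut-off (strict `<`)
#' @param delta_cut delta-beta cut-off (strict `>`)
#' @param hypo_cut hypomethylation cut (strict `<`)
#' @param hyper_cut hypermethylation cut (strict `>`)
#' @param min_pass_mbc minimum MBC samples individually passing
#' @param min_pass_cvs minimum CVS samples individually passing
#' @return list of class `funnel_thresholds`
#' @export
funnel_thresholds <- function(fdr_cut = 0.05, delta_cut = 0.2,
                              hypo_cut = 0.25, hyper_cut = 0.75,
                              min_pass_mbc = 10, min_pass_cvs = 10) {
  stopifnot(fdr_cut > 0, fdr_cut < 1, delta_cut > 0, delta_cut < 1,
            hypo_cut > 0, hypo_cut < hyper_cut, hyper_cut < 1,
            min_pass_mbc >= 0, min_pass_cvs >= 0)
  structure(list(fdr_cut = fdr_cut, delta_cut = delta_cut,
                 hypo_cut = hypo_cut, hyper_cut = hyper_cut,
                 min_pass_mbc = min_pass_mbc, min_pass_cvs = min_pass_cvs),
            class = "funnel_thresholds")
}

#' DMC stage: FDR and delta-beta cut-offs
#'
#' @param stats a [probe_stats()] data frame (or any data frame with
#'   `fdr` and `delta` columns)
#' @param thresholds a [funnel_thresholds()]
#' @return logical vector: `fdr < fdr_cut & delta > delta_cut` (both
#'   strict; boundary values fail)
#' @export
stage_dmc <- function(stats, thresholds = funnel_thresholds())
  stats$fdr < thresholds$fdr_cut & stats$delta > thresholds$delta_cut

#' Strict-threshold stage: group-mean hypo/hyper calls
#'
#' @param stats a [probe_stats()] data frame
#' @param thresholds a [funnel_thresholds()]
#' @return character vector of directions: `"mbc_hypo_cvs_hyper"` when
#'   the MBC mean is `< hypo_cut` and the CVS mean `> hyper_cut`,
#'   `"cvs_hypo_mbc_hyper"` for the reverse, else `"none"`
#' @export
stage_strict <- function(stats, thresholds = funnel_thresholds()) {
  ifelse(stats$mbc_mean < thresholds$hypo_cut &
           stats$cvs_mean > thresholds$hyper_cut, .DIR_MBC_HYPO,
         ifelse(stats$cvs_mean < thresholds$hypo_cut &
                  stats$mbc_mean > thresholds$hyper_cut, .DIR_CVS_HYPO,
                .DIR_NONE))
}

#' Consistency stage: per-sample threshold passing
#'
#' A candidate is only kept when enough individual samples clear the
#' same strict cut values that the group means passed: for direction
#' `"mbc_hypo_cvs_hyper"`, at least `min_pass_mbc` MBC samples with
#' beta `< hypo_cut` and at least `min_pass_cvs` CVS samples with beta
#' `> hyper_cut` (reversed for the other direction).
#'
#' @param beta named numeric vector of one probe's beta values
#' @param groups character vector (named by sample or parallel to
#'   `beta`) of `"MBC"`/`"CVS"` labels; QC replicate samples should not
#'   be included
#' @param direction `"mbc_hypo_cvs_hyper"` or `"cvs_hypo_mbc_hyper"`
#' @param thresholds a [funnel_thresholds()]
#' @return logical
#' @export
stage_consistency <- function(beta, groups, direction,
                              thresholds = funnel_thresholds()) {
  if (length(direction) != 1 || direction == .DIR_NONE)
    stop("`direction` must be a single non-'none' direction", call. = FALSE)
  if (!direction %in% c(.DIR_MBC_HYPO, .DIR_CVS_HYPO))
    stop("unknown direction '", direction, "'", call. = FALSE)
  if (!is.null(names(groups)) && !is.null(names(beta)))
    groups <- groups[names(beta)]
  mbc <- beta[groups == "MBC"]
  cvs <- beta[groups == "CVS"]
  if (direction == .DIR_MBC_HYPO) {
    n_mbc <- sum(mbc < thresholds$hypo_cut)
    n_cvs <- sum(cvs > thresholds$hyper_cut)
  } else {
    n_mbc <- sum(mbc > thresholds$hyper_cut)
    n_cvs <- sum(cvs < thresholds$hypo_cut)
  }
  n_mbc >= thresholds$min_pass_mbc && n_cvs >= thresholds$min_pass_cvs
}

#' Run the five-stage DMC screening funnel
#'
#' Applies, in order: (1) complete-case filtering (SNP control probes
#' are set aside first — they carry genotypes, not methylation); (2) the
#' DMC stage (`fdr < fdr_cut`, `delta > delta_cut`); (3) the strict
#' group-mean stage assigning a direction; (4) the MSRE stage, keeping
#' probes whose interrogated CpG is spanned by a recognition site of at
#' least one configured enzyme; (5) the per-sample consistency stage.
#' Survivor counts are recorded after every stage and the per-probe
#' records carry nested stage flags (`passed_consistency` implies
#' `passed_msre` implies `passed_strict` implies `passed_dmc`).
#'
#' @param bm a [beta_matrix()] (incomplete probes are filtered here)
#' @param manifest a probe annotation data frame covering the probes
#'   (see [probe_annotation()]); flank annotation is required for every
#'   probe that reaches the MSRE stage
#' @param enzymes an enzyme table (see [enzyme_table()])
#' @param thresholds a [funnel_thresholds()]
#' @param p_method p-value mode passed to [rank_sum_test()]
#' @return object of class `funnel_result`: list with `records` (one row
#'   per analysed probe: annotation, statistics, `direction`, stage
#'   flags, `msre` hit label), `counts` (named survivor counts:
#'   `input`, `complete`, `dmc`, `strict`, `msre`, `consistent`) and
#'   `thresholds`
#' @export
run_funnel <- function(bm, manifest, enzymes = default_enzymes(),
                       thresholds = funnel_thresholds(),
                       p_method = c("auto", "exact", "normal")) {
  p_method <- match.arg(p_method)
  manifest <- probe_annotation(manifest)
  ann <- manifest[match(rownames(bm$values), manifest$probe_id), ]

  snp_ids <- manifest$probe_id[manifest$is_snp]
  analysed <- setdiff(rownames(bm$values), snp_ids)
  bm2 <- subset_probes(bm, analysed)
  counts <- c(input = length(analysed))

  cc <- complete_case_filter(bm2)
  bm2 <- cc$matrix
  counts["complete"] <- n_probes(bm2)

  st <- probe_stats(bm2, method = p_method)
  passed_dmc <- stage_dmc(st, thresholds)
  counts["dmc"] <- sum(passed_dmc)

  dir_all <- stage_strict(st, thresholds)
  direction <- ifelse(passed_dmc, dir_all, .DIR_NONE)
  passed_strict <- direction != .DIR_NONE
  counts["strict"] <- sum(passed_strict)

  # MSRE stage: only strict survivors need flank annotation
  idx <- which(passed_strict)
  ann2 <- manifest[match(st$probe_id, manifest$probe_id), ]
  lack <- idx[is.na(ann2$flank[idx]) | is.na(ann2$cpg_site[idx])]
  if (length(lack) > 0)
    stop("flank annotation required for MSRE stage but missing for probe(s): ",
         paste(utils::head(st$probe_id[lack], 10), collapse = ", "),
         call. = FALSE)
  msre_label <- rep(NA_character_, nrow(st))
  passed_msre <- rep(FALSE, nrow(st))
  if (length(idx) > 0) {
    hits <- msre_annotate(ann2[idx, , drop = FALSE], enzymes)
    lab <- .msre_label(hits, st$probe_id[idx])
    msre_label[idx] <- lab
    passed_msre[idx] <- !is.na(lab)
  }
  counts["msre"] <- sum(passed_msre)

  # consistency stage on MSRE survivors
  prim <- c(primary_samples(bm2, "MBC"), primary_samples(bm2, "CVS"))
  grp <- bm2$groups[prim]
  passed_consistency <- rep(FALSE, nrow(st))
  for (i in which(passed_msre)) {
    passed_consistency[i] <- stage_consistency(
      bm2$values[i, prim], grp, direction[i], thresholds)
  }
  counts["consistent"] <- sum(passed_consistency)

  records <- data.frame(
    probe_id = st$probe_id,
    chromosome = ann2$chromosome,
    position = ann2$position,
    gene = ann2$gene,
    refseq = ann2$refseq,
    mbc_mean = st$mbc_mean, cvs_mean = st$cvs_mean, delta = st$delta,
    p_value = st$p_value, fdr = st$fdr,
    direction = direction,
    passed_dmc = passed_dmc, passed_strict = passed_strict,
    passed_msre = passed_msre, passed_consistency = passed_consistency,
    msre = msre_label,
    stringsAsFactors = FALSE)

  structure(list(records = records, counts = counts,
                 thresholds = thresholds),
            class = "funnel_result")
}

#' Planted-marker recovery of a funnel run
#'
#' Compares a [run_funnel()] result against the ground truth of
#' [simulate_dataset()].  Sensitivity is the fraction of *assessable*
#' planted DMCs recovered in the final set, where assessable means the
#' probe survived the complete-case filter — a probe with a missing
#' measurement is removed by design, not missed by the test.  The false
#' discovery proportion is the fraction of the final set that was not
#' planted.
#'
#' @param result a `funnel_result`
#' @param truth the `truth` data frame of [simulate_dataset()]
#' @return list with `sensitivity`, `fdp`, `n_final`,
#'   `n_planted_assessable`
#' @export
planted_recovery <- function(result, truth) {
  rec <- result$records
  final <- rec$probe_id[rec$passed_consistency]
  planted <- truth$probe_id[truth$is_planted_dmc]
  assessable <- intersect(planted, rec$probe_id)
  list(sensitivity = if (length(assessable) > 0)
         mean(assessable %in% final) else NA_real_,
       fdp = if (length(final) > 0)
         mean(!(final %in% planted)) else 0,
       n_final = length(final),
       n_planted_assessable = length(assessable))
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Five-stage DMC screening funnel\n")
  stages <- c(input = "probes analysed", complete = "complete cases",
              dmc = "DMCs (FDR & delta)", strict = "strict hypo/hyper",
              msre = "MSRE site over CpG", consistent = "per-sample consistent")
  for (s in names(x$counts))
    cat(sprintf("  %-22s %8d\n", stages[[s]], x$counts[[s]]))
  invisible(x)
}

# chromosome labels ordered numerically where possible ("chr" ignored)
.chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(base))
  rank <- ifelse(is.na(num), 1000 + match(base, sort(unique(base))), num)
  rank
}

#' Write the candidate report table (rounded, publication layout)
#'
#' Columns `probe_id`, `chromosome`, `gene`, `cvs_mean`, `mbc_mean`,
#' `delta`, `refseq`, `msre`, sorted by chromosome then probe ID, means
#' and delta printed to 2 decimals.  This rounding is lossy by design;
#' full precision is kept by [write_dmc_full()].
#'
#' @param records a `funnel_result$records` data frame (or compatible)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dmc_table <- function(records, path) {
  o <- order(.chrom_rank(records$chromosome), records$probe_id)
  r <- records[o, , drop = FALSE]
  out <- data.frame(probe_id = r$probe_id, chromosome = r$chromosome,
                    gene = r$gene, cvs_mean = sprintf("%.2f", r$cvs_mean),
                    mbc_mean = sprintf("%.2f", r$mbc_mean),
                    delta = sprintf("%.2f", r$delta),
                    refseq = r$refseq, msre = r$msre,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write the full-precision per-probe record table
#' @param records a `funnel_result$records` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dmc_full <- function(records, path) {
  o <- order(.chrom_rank(records$chromosome), records$probe_id)
  utils::write.table(records[o, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a candidate table in the report layout
#'
#' Reads a table written by [write_dmc_table()] (probe_id, chromosome,
#' gene, cvs_mean, mbc_mean, delta, refseq, msre), reconstructing the
#' direction from the printed group means and marking every row as a
#' final (all stages passed) candidate.
#'
#' @param path path to the TSV
#' @param thresholds a [funnel_thresholds()] used to recompute the
#'   direction from the means
#' @return data frame in the `funnel_result$records` layout (without
#'   statistics columns not present in the report)
#' @export
read_candidates <- function(path, thresholds = funnel_thresholds()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "chromosome", "gene", "cvs_mean", "mbc_mean",
            "delta", "refseq", "msre")
  absent <- setdiff(need, names(df))
  if (length(absent) > 0)
    stop("candidate file lacks column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(
    probe_id = df$probe_id, chromosome = df$chromosome,
    gene = df$gene,
    mbc_mean = as.numeric(df$mbc_mean), cvs_mean = as.numeric(df$cvs_mean),
    delta = as.numeric(df$delta), refseq = df$refseq, msre = df$msre,
    stringsAsFactors = FALSE)
  out$direction <- stage_strict(out, thresholds)
  out$passed_dmc <- TRUE
  out$passed_strict <- TRUE
  out$passed_msre <- TRUE
  out$passed_consistency <- TRUE
  out
}

#' Bundled candidate marker set (chromosomes 13, 18 and 21)
#'
#' The 44 final candidate fetal methylation markers on chromosomes 13,
#' 18 and 21 from a published genome-wide MBC/CVS screen, shipped as a
#' plain-text fixture in `inst/extdata`.  Useful as a worked example and
#' for structural checks of the region/report machinery.
#'
#' @return data frame in the layout of [read_candidates()]
#' @export
candidate_markers <- function() {
  read_candidates(system.file("extdata", "candidates_chr13_18_21.tsv",
                              package = "dmcscreen", mustWork = TRUE))
}
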