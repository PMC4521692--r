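#' Remove probes with incomplete measurements
#'
#' First stage of the screen: CpG sites for which no beta-value was
#' obtained for one or more samples are dropped so that every downstream
#' statistic sees a complete probes x samples block.  By default only
#' the primary sample columns count towards completeness; QC replicate
#' columns can be included via `include_qc`.
#'
#' @param bm a [beta_matrix()]
#' @param include_qc also require completeness over QC replicate columns
#' @return list with elements `matrix` (the filtered [beta_matrix()])
#'   and `removed` (number of probes dropped)
#' @export
complete_case_filter <- function(bm, include_qc = FALSE) {
  drop <- incomplete_probes(bm, include_qc = include_qc)
  keep <- setdiff(rownames(bm$values), drop)
  list(matrix = subset_probes(bm, keep), removed = length(drop))
}

#' Two-sided Wilcoxon rank-sum test between two groups of beta values
#'
#' Compares two unpaired groups by the rank-sum (Mann-Whitney) statistic.
#' Ties are handled by midranks.  Two modes:
#' \describe{
#'   \item{`"exact"`}{full enumeration of all assignments of the observed
#'     (mid)ranks to the two groups; valid with ties; feasible for
#'     `length(a) + length(b) <= 12`.  Two-sided p is twice the smaller
#'     tail probability (including the observed value), capped at 1.}
#'   \item{`"normal"`}{normal approximation with tie-corrected variance;
#'     no continuity correction unless `correct = TRUE`.}
#' }
#' `"auto"` picks `"exact"` when the total sample size is at most 12 and
#' `"normal"` otherwise.  When every value in both groups is identical
#' there is no separation to detect and p is 1.
#'
#' @param a,b numeric vectors of beta values in `[0, 1]`, each non-empty
#' @param method `"auto"`, `"exact"` or `"normal"`
#' @param correct apply a continuity correction in the normal mode
#' @return two-sided p-value in (0, 1]
#' @examples
#' rank_sum_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6, 0.7))  # 2/35
#' @export
rank_sum_test <- function(a, b, method = c("auto", "exact", "normal"),
                          correct = FALSE) {
  method <- match.arg(method)
  for (v in list(a, b)) {
    if (length(v) == 0) stop("both groups must be non-empty", call. = FALSE)
    if (anyNA(v)) stop("missing values: run complete_case_filter() first",
                       call. = FALSE)
    if (any(v < 0 | v > 1))
      stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  na <- length(a)
  N <- na + length(b)
  if (method == "auto") method <- if (N <= 12) "exact" else "normal"

  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2

  if (method == "exact") {
    if (N > 20)
      stop("exact enumeration is limited to small samples (total n <= 20)",
           call. = FALSE)
    Wd <- utils::combn(N, na, FUN = function(i) sum(r[i]))
    eps <- 1e-9
    lo <- mean(Wd <= W + eps)
    hi <- mean(Wd >= W - eps)
    return(min(1, 2 * min(lo, hi)))
  }

  tie <- table(r)
  sigma2 <- na * (N - na) / 12 *
    ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  if (correct) z <- sign(z) * max(0, abs(z) - 0.5)
  max(min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2))),
      .Machine$double.xmin)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; output order matches
#' input order, every adjusted value is >= its input p and the adjusted
#' values are monotone in p.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return vector of BH-adjusted values (FDRs), same length and order
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and contain no NA", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-probe two-group statistics
#'
#' For every probe: group means over the primary MBC and CVS columns,
#' the absolute group-mean difference (delta beta), a two-sided rank-sum
#' p-value and its BH-adjusted FDR (computed jointly over all probes in
#' the matrix).  QC replicate columns take no part.
#'
#' @param bm a complete [beta_matrix()] (run [complete_case_filter()]
#'   first)
#' @param method p-value mode passed to [rank_sum_test()]
#' @return data frame with columns `probe_id`, `mbc_mean`, `cvs_mean`,
#'   `delta`, `p_value`, `fdr`
#' @export
probe_stats <- function(bm, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  mbc <- primary_samples(bm, "MBC")
  cvs <- primary_samples(bm, "CVS")
  if (length(mbc) == 0 || length(cvs) == 0)
    stop("both groups need at least one primary sample", call. = FALSE)
  vm <- bm$values[, mbc, drop = FALSE]
  vc <- bm$values[, cvs, drop = FALSE]
  if (anyNA(vm) || anyNA(vc))
    stop("matrix has missing values: run complete_case_filter() first",
         call. = FALSE)
  mbc_mean <- rowMeans(vm)
  cvs_mean <- rowMeans(vc)
  p <- vapply(seq_len(nrow(vm)), function(i)
    rank_sum_test(vm[i, ], vc[i, ], method = method), numeric(1))
  data.frame(probe_id = rownames(bm$values),
             mbc_mean = unname(mbc_mean), cvs_mean = unname(cvs_mean),
             delta = unname(abs(mbc_mean - cvs_mean)),
             p_value = p, fdr = bh_adjust(p),
             stringsAsFactors = FALSE)
}
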