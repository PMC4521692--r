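#' Beta-value matrix with sample groups and replicate pairs
#'
#' The central container of the pipeline: a probes x samples matrix of
#' methylation beta-values (fraction methylated, in `[0, 1]`, `NA` for a
#' failed measurement), together with the group of every sample column
#' (`"MBC"` = maternal blood cells, `"CVS"` = chorionic villus sample) and
#' an optional set of technical-replicate pairs.  Samples that belong to a
#' replicate pair are treated as QC-only columns: they are excluded from
#' group means, tests and (by default) the complete-case filter, and are
#' used solely for reproducibility checks (see
#' [replicate_concordance()]).
#'
#' @param values numeric matrix, probes in rows (unique rownames = probe
#'   IDs), samples in columns (unique colnames = sample IDs); entries in
#'   `[0, 1]` or `NA`.
#' @param groups character vector, either named by sample ID or parallel
#'   to `colnames(values)`, with values `"MBC"` or `"CVS"`.
#' @param replicate_pairs `NULL`, or a data frame with columns `sample_a`
#'   and `sample_b` naming pairs of QC replicate columns.  Both members of
#'   a pair must exist in the matrix and carry the same group label.
#'
#' @return an object of class `beta_matrix`: a list with elements
#'   `values`, `groups` (named character) and `replicate_pairs`.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.2, 0.8, 0.15, 0.85), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("M1", "M2", "C1")))
#' bm <- beta_matrix(m, c(M1 = "MBC", M2 = "MBC", C1 = "CVS"))
#' n_probes(bm)
#' @export
beta_matrix <- function(values, groups, replicate_pairs = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0)
    values <- matrix(numeric(0), nrow = 0, ncol = ncol(values),
                     dimnames = list(character(0), colnames(values)))
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs", call. = FALSE)

  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value %g outside [0, 1] for probe '%s', sample '%s'",
                 values[bad[1, 1], bad[1, 2]],
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  }

  g <- as.character(groups)
  names(g) <- names(groups)
  if (is.null(names(g))) {
    if (length(g) != ncol(values))
      stop("`groups` must be named or match the number of samples",
           call. = FALSE)
    names(g) <- colnames(values)
  }
  groups <- g[colnames(values)]
  names(groups) <- colnames(values)
  if (anyNA(groups))
    stop("no group assigned for sample(s): ",
         paste(colnames(values)[is.na(groups)], collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(groups), c("MBC", "CVS"))
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (expected MBC or CVS)", call. = FALSE)

  if (is.null(replicate_pairs)) {
    replicate_pairs <- data.frame(sample_a = character(0),
                                  sample_b = character(0),
                                  stringsAsFactors = FALSE)
  } else {
    replicate_pairs <- as.data.frame(replicate_pairs,
                                     stringsAsFactors = FALSE)
    if (!all(c("sample_a", "sample_b") %in% names(replicate_pairs)))
      stop("`replicate_pairs` needs columns sample_a, sample_b",
           call. = FALSE)
    members <- c(replicate_pairs$sample_a, replicate_pairs$sample_b)
    absent <- setdiff(members, colnames(values))
    if (length(absent) > 0)
      stop("replicate pair member(s) not in matrix: ",
           paste(absent, collapse = ", "), call. = FALSE)
    if (anyDuplicated(members))
      stop("a sample may belong to at most one replicate pair",
           call. = FALSE)
    same <- groups[replicate_pairs$sample_a] == groups[replicate_pairs$sample_b]
    if (!all(same))
      stop("replicate pair members must share a group label", call. = FALSE)
  }

  structure(list(values = values, groups = groups,
                 replicate_pairs = replicate_pairs),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d MBC, %d CVS, %d QC replicate)\n",
              nrow(x$values), ncol(x$values),
              length(primary_samples(x, "MBC")),
              length(primary_samples(x, "CVS")),
              length(qc_samples(x))))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  %d missing cells\n", nmiss))
  invisible(x)
}

#' Number of probes in a beta matrix
#' @param bm a [beta_matrix()]
#' @return integer
#' @export
n_probes <- function(bm) nrow(bm$values)

#' QC replicate sample columns of a beta matrix
#'
#' Samples that are members of a declared replicate pair; these columns
#' carry duplicate measurements for quality control and take no part in
#' the group statistics.
#' @param bm a [beta_matrix()]
#' @return character vector of sample IDs
#' @export
qc_samples <- function(bm)
  unique(c(bm$replicate_pairs$sample_a, bm$replicate_pairs$sample_b))

#' Primary (non-QC) sample columns, optionally restricted to one group
#' @param bm a [beta_matrix()]
#' @param group `NULL`, `"MBC"` or `"CVS"`
#' @return character vector of sample IDs
#' @export
primary_samples <- function(bm, group = NULL) {
  ids <- setdiff(colnames(bm$values), qc_samples(bm))
  if (!is.null(group)) ids <- ids[bm$groups[ids] == group]
  ids
}

#' Probes with at least one missing measurement
#' @param bm a [beta_matrix()]
#' @param include_qc also require completeness over QC replicate columns
#'   (default `FALSE`: replicate columns are QC-only)
#' @return character vector of probe IDs
#' @export
incomplete_probes <- function(bm, include_qc = FALSE) {
  cols <- if (include_qc) colnames(bm$values) else primary_samples(bm)
  v <- bm$values[, cols, drop = FALSE]
  rownames(v)[rowSums(is.na(v)) > 0]
}

#' Subset a beta matrix to a set of probes
#' @param bm a [beta_matrix()]
#' @param probe_ids probe IDs to keep (order preserved)
#' @return a [beta_matrix()]
#' @export
subset_probes <- function(bm, probe_ids) {
  absent <- setdiff(probe_ids, rownames(bm$values))
  if (length(absent) > 0)
    stop("probe(s) not in matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  beta_matrix(bm$values[probe_ids, , drop = FALSE], bm$groups,
              bm$replicate_pairs)
}

# tokens accepted as missing on read; "NA" written
.missing_tokens <- c("NA", "NaN", "")

#' Read a beta-value matrix and its sample sheet
#'
#' The matrix file is tab-delimited with probe IDs in the first column and
#' a header row of sample IDs; missing cells may be encoded as `NA`,
#' `NaN` or the empty string.  The sample sheet maps each sample to its
#' group (`MBC`/`CVS`) and optionally to its replicate partner, with
#' columns `sample_id`, `group`, `replicate_partner` (empty when the
#' sample is not part of a QC pair).
#'
#' @param path path to the beta-value TSV
#' @param groups_path path to the sample-sheet TSV
#' @return a [beta_matrix()]
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, groups_path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2)
    stop("beta matrix file needs a probe column plus sample columns",
         call. = FALSE)
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ID(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells %in% .missing_tokens] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                   dimnames = list(probe_ids,
                                                   colnames(cells))))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric beta value '%s' for probe '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], probe_ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]), call. = FALSE)

  sheet <- utils::read.delim(groups_path, sep = "\t", header = TRUE,
                             colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, group", call. = FALSE)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  absent <- setdiff(colnames(values), sheet$sample_id)
  if (length(absent) > 0)
    stop("sample(s) missing from sample sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)

  pairs <- NULL
  if ("replicate_partner" %in% names(sheet)) {
    partner <- sheet$replicate_partner
    partner[partner %in% .missing_tokens] <- NA_character_
    has <- !is.na(partner)
    if (any(has)) {
      key <- t(apply(cbind(sheet$sample_id[has], partner[has]), 1, sort))
      key <- unique(as.data.frame(key, stringsAsFactors = FALSE))
      pairs <- data.frame(sample_a = key[[1]], sample_b = key[[2]],
                          stringsAsFactors = FALSE)
    }
  }
  beta_matrix(values, groups[colnames(values)], pairs)
}

#' Write a beta-value matrix (and optionally its sample sheet)
#'
#' Inverse of [read_beta_matrix()]: tab-delimited, UTF-8, LF line
#' endings, missing cells written as `NA`.
#'
#' @param bm a [beta_matrix()]
#' @param path output path for the beta-value TSV
#' @param groups_path optional output path for the sample-sheet TSV
#' @return `path`, invisibly
#' @export
write_beta_matrix <- function(bm, path, groups_path = NULL) {
  df <- data.frame(probe_id = rownames(bm$values), bm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(groups_path)) {
    partner <- rep(NA_character_, ncol(bm$values))
    names(partner) <- colnames(bm$values)
    partner[bm$replicate_pairs$sample_a] <- bm$replicate_pairs$sample_b
    partner[bm$replicate_pairs$sample_b] <- bm$replicate_pairs$sample_a
    sheet <- data.frame(sample_id = colnames(bm$values),
                        group = unname(bm$groups[colnames(bm$values)]),
                        replicate_partner = unname(partner),
                        stringsAsFactors = FALSE)
    utils::write.table(sheet, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}
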