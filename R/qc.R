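#' Spearman rank correlation
#'
#' Pearson correlation of midranks, as used for all correlation analyses
#' in the pipeline.  Errors on constant input, where the correlation is
#' undefined.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in `[-1, 1]`
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Replicate reproducibility via SNP control probes
#'
#' SNP control probes interrogate highly polymorphic sites, so their
#' beta values cluster at 0, 0.5 and 1 and act as a genotype fingerprint
#' of the individual.  For each declared technical-replicate pair the
#' Spearman correlation of the two columns over the SNP probes measures
#' array reproducibility (well-behaved arrays give rho close to 1).
#'
#' @param bm a [beta_matrix()] with at least one replicate pair
#' @param snp_probes character vector of SNP control probe IDs (at
#'   least 3 present in the matrix)
#' @return data frame with columns `sample_a`, `sample_b`, `rho`
#' @export
replicate_concordance <- function(bm, snp_probes) {
  if (nrow(bm$replicate_pairs) == 0)
    stop("no replicate pairs declared", call. = FALSE)
  snp_probes <- intersect(snp_probes, rownames(bm$values))
  if (length(snp_probes) < 3)
    stop("need at least 3 SNP control probes present in the matrix",
         call. = FALSE)
  pairs <- bm$replicate_pairs
  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- bm$values[snp_probes, pairs$sample_a[i]]
    b <- bm$values[snp_probes, pairs$sample_b[i]]
    keep <- !is.na(a) & !is.na(b)
    spearman_rho(a[keep], b[keep])
  }, numeric(1))
  data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
             rho = rho, stringsAsFactors = FALSE)
}

#' Heatmap leaf order by complete-linkage clustering
#'
#' Row and column leaf orders from agglomerative complete-linkage
#' clustering on Euclidean distances ([stats::hclust()] on
#' [stats::dist()]), computed independently for rows and columns — the
#' ordering used to lay out candidate-marker heatmaps.  Deterministic
#' for a given input; fewer than 2 rows (or columns) yields the identity
#' order.
#'
#' @param x numeric matrix with no missing values
#' @return list with integer vectors `rows` and `cols` (leaf orders) and
#'   the underlying `hclust` objects `row_hclust`, `col_hclust` (`NULL`
#'   for degenerate dimensions)
#' @export
heatmap_order <- function(x) {
  if (anyNA(x)) stop("matrix must be complete", call. = FALSE)
  cluster <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hc = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    list(order = hc$order, hc = hc)
  }
  r <- cluster(x)
  c_ <- cluster(t(x))
  list(rows = r$order, cols = c_$order,
       row_hclust = r$hc, col_hclust = c_$hc)
}

#' Render a candidate-marker heatmap
#'
#' Convenience wrapper around `pheatmap` (if installed) with
#' complete-linkage / Euclidean clustering and a blue-yellow-red
#' palette over the beta scale (low / intermediate / high methylation,
#' tercile breakpoints).
#'
#' @param x numeric matrix of beta values (probes x samples)
#' @param filename optional output file passed to `pheatmap`
#' @param ... further arguments to `pheatmap`
#' @return the `pheatmap` object, invisibly
#' @export
plot_dmc_heatmap <- function(x, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_dmc_heatmap() needs the 'pheatmap' package", call. = FALSE)
  ph <- pheatmap::pheatmap(
    x, clustering_method = "complete",
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    color = grDevices::colorRampPalette(c("blue", "yellow", "red"))(100),
    breaks = seq(0, 1, length.out = 101),
    filename = filename, ...)
  invisible(ph)
}
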