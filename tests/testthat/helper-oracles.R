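# Independent brute-force oracles, deliberately sharing no code with the
# package implementation.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# every concrete string an IUPAC pattern can take
oracle_expand <- function(pattern) {
  sets <- oracle_iupac[strsplit(pattern, "")[[1]]]
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

oracle_revcomp <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# all (start, strand) site occurrences by scanning every window
oracle_find_sites <- function(flank, pattern) {
  k <- nchar(pattern)
  L <- nchar(flank)
  if (L < k) return(data.frame(start = integer(0), strand = character(0)))
  wins <- substring(flank, 1:(L - k + 1), k:L)
  pats <- oracle_expand(pattern)
  rcp <- vapply(pats, oracle_revcomp, character(1), USE.NAMES = FALSE)
  fwd <- which(wins %in% pats)
  if (setequal(pats, rcp)) {
    return(data.frame(start = fwd, strand = rep("+", length(fwd)),
                      stringsAsFactors = FALSE))
  }
  rev <- which(wins %in% rcp)
  data.frame(start = c(fwd, rev),
             strand = c(rep("+", length(fwd)), rep("-", length(rev))),
             stringsAsFactors = FALSE)
}

# CpG-spanning hits for a whole enzyme table
oracle_cpg_hits <- function(flank, cpg, enzymes) {
  out <- lapply(seq_len(nrow(enzymes)), function(i) {
    s <- oracle_find_sites(flank, enzymes$pattern[i])
    k <- nchar(enzymes$pattern[i])
    s <- s[s$start <= cpg & s$start + k - 1 >= cpg + 1, , drop = FALSE]
    if (nrow(s) == 0) return(NULL)
    data.frame(enzyme = enzymes$name[i], site_start = s$start,
               strand = s$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(enzyme = character(0), site_start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out[order(out$enzyme, out$site_start, out$strand), , drop = FALSE]
}

# naive O(n^3) complete-linkage agglomeration; records at each merge the
# sorted member set of the newly formed cluster and its height
oracle_complete_linkage <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# member sets of each hclust merge step, comparable to the oracle
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(m)
      if (m < 0) -m else sets[[m]]))
    sets[[i]] <- sort(members)
  }
  sets
}

# random flank with a CG forced at `cpg`
random_flank <- function(len, cpg) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s[cpg] <- "C"
  s[cpg + 1] <- "G"
  paste0(s, collapse = "")
}

# tiny two-group beta matrix with constant per-group values
const_beta_matrix <- function(mbc_value, cvs_value, probe = "cg1",
                              n_mbc = 10, n_cvs = 12) {
  m <- matrix(c(rep(mbc_value, n_mbc), rep(cvs_value, n_cvs)), nrow = 1,
              dimnames = list(probe,
                              c(sprintf("M%02d", seq_len(n_mbc)),
                                sprintf("C%02d", seq_len(n_cvs)))))
  beta_matrix(m, c(rep("MBC", n_mbc), rep("CVS", n_cvs)))
}
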