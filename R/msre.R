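#' Match an IUPAC pattern against a DNA string
#'
#' Thin wrapper around [Biostrings::matchPattern()] with
#' `fixed = "subject"`, so ambiguity codes in the pattern match their
#' base sets (R = A/G, N = any base, ...) while subject letters are
#' taken literally.  All overlapping occurrences are reported.
#'
#' @param pattern IUPAC pattern
#' @param subject DNA string over A/C/G/T
#' @return integer vector of 1-based start offsets
#' @examples
#' match_iupac("CCGG", "ACCGGCCGGT")  # 2, 6
#' @export
match_iupac <- function(pattern, subject) {
  .check_iupac(toupper(pattern))
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(
    toupper(pattern), Biostrings::DNAString(subject), fixed = "subject"))
}

#' Reverse complement of a DNA / IUPAC string
#' @param x DNA string (ambiguity codes allowed)
#' @return character
#' @export
revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.is_palindromic <- function(pattern) identical(revcomp(pattern), toupper(pattern))

#' Find recognition-site occurrences of one enzyme in a flank
#'
#' Scans the forward strand for `pattern` and, for non-palindromic
#' patterns, also for its reverse complement (reported in forward
#' coordinates with strand `"-"`).  For palindromic patterns the two
#' strands give the same site, collapsed to a single `"+"` hit.
#'
#' @param flank DNA string over A/C/G/T
#' @param name enzyme name
#' @param pattern IUPAC recognition pattern
#' @return data frame with columns `enzyme`, `start` (1-based), `strand`
#' @examples
#' find_sites("TCCGGA", "HpaII", "CCGG")    # one "+" hit at 2
#' find_sites("TGCGGA", "AciI", "CCGC")     # one "-" hit at 2
#' @export
find_sites <- function(flank, name, pattern) {
  pattern <- toupper(pattern)
  fwd <- match_iupac(pattern, flank)
  if (.is_palindromic(pattern)) {
    starts <- fwd
    strands <- rep("+", length(fwd))
  } else {
    rev <- match_iupac(revcomp(pattern), flank)
    starts <- c(fwd, rev)
    strands <- c(rep("+", length(fwd)), rep("-", length(rev)))
  }
  o <- order(starts, strands)
  data.frame(enzyme = rep(name, length(starts)), start = starts[o],
             strand = strands[o], stringsAsFactors = FALSE)
}

#' MSRE recognition sites spanning the interrogated CpG
#'
#' The assay logic of MSRE-based marker selection requires that
#' methylation of the interrogated CpG blocks digestion, so a site only
#' counts when its span covers *both* bases of the CpG dinucleotide.
#' When several occurrences of the same enzyme overlap the CpG, they are
#' numbered left to right and labelled `Enzyme.1`, `Enzyme.2`, ...; a
#' single occurrence is labelled with the bare enzyme name.
#'
#' @param flank DNA string over A/C/G/T
#' @param cpg_site 1-based index of the C of the target CpG in `flank`
#' @param enzymes an enzyme table (see [enzyme_table()]); defaults to
#'   [default_enzymes()]
#' @return data frame with columns `enzyme`, `occurrence` (1-based
#'   ordinal among this enzyme's overlapping occurrences), `strand`,
#'   `site_start` (1-based), `label`.  Zero rows when no site spans the
#'   CpG; a probe "passes MSRE" iff the result is non-empty.
#' @examples
#' cpg_msre_hits("AACCGGTT", 4)          # HpaII and AgeI span the CpG
#' cpg_msre_hits("ACGCGCGT", 4)          # BstUI.1 and BstUI.2
#' @export
cpg_msre_hits <- function(flank, cpg_site, enzymes = default_enzymes()) {
  if (substr(flank, cpg_site, cpg_site + 1L) != "CG")
    stop("flank does not carry CG at cpg_site ", cpg_site, call. = FALSE)
  out <- lapply(seq_len(nrow(enzymes)), function(i) {
    sites <- find_sites(flank, enzymes$name[i], enzymes$pattern[i])
    k <- nchar(enzymes$pattern[i])
    keep <- sites$start <= cpg_site & sites$start + k - 1L >= cpg_site + 1L
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) == 0) return(NULL)
    sites$occurrence <- seq_len(nrow(sites))
    sites$label <- if (nrow(sites) == 1) sites$enzyme else
      paste0(sites$enzyme, ".", sites$occurrence)
    sites
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(enzyme = character(0), start = integer(0),
                      strand = character(0), occurrence = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  data.frame(enzyme = out$enzyme, occurrence = out$occurrence,
             strand = out$strand, site_start = out$start,
             label = out$label, stringsAsFactors = FALSE)
}

#' Annotate many probes with CpG-spanning MSRE hits
#'
#' Batch version of [cpg_msre_hits()] over a probe manifest, using
#' [Biostrings::vmatchPattern()] per enzyme/strand for speed.  SNP
#' control probes and probes without flank annotation yield no rows.
#'
#' @param manifest a probe annotation data frame (see
#'   [probe_annotation()])
#' @param enzymes an enzyme table
#' @return data frame with columns `probe_id`, `enzyme`, `occurrence`,
#'   `strand`, `site_start`, `label`
#' @export
msre_annotate <- function(manifest, enzymes = default_enzymes()) {
  manifest <- probe_annotation(manifest)
  use <- !manifest$is_snp & !is.na(manifest$flank) &
    !is.na(manifest$cpg_site)
  ids <- manifest$probe_id[use]
  empty <- data.frame(probe_id = character(0), enzyme = character(0),
                      occurrence = integer(0), strand = character(0),
                      site_start = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (length(ids) == 0) return(empty)
  flanks <- Biostrings::DNAStringSet(manifest$flank[use])
  cpg <- manifest$cpg_site[use]

  scan <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, flanks, fixed = "subject")
    st <- Biostrings::startIndex(m)
    k <- nchar(pattern)
    hits <- lapply(seq_along(st), function(j) {
      s <- st[[j]]
      if (is.null(s)) return(NULL)
      s <- s[s <= cpg[j] & s + k - 1L >= cpg[j] + 1L]
      if (length(s) == 0) return(NULL)
      data.frame(probe = j, site_start = s, strand = strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  }

  res <- lapply(seq_len(nrow(enzymes)), function(i) {
    p <- enzymes$pattern[i]
    h <- scan(p, "+")
    if (!.is_palindromic(p)) h <- rbind(h, scan(revcomp(p), "-"))
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h <- h[order(h$probe, h$site_start, h$strand), , drop = FALSE]
    occ <- stats::ave(h$site_start, h$probe, FUN = seq_along)
    tot <- stats::ave(h$site_start, h$probe, FUN = length)
    data.frame(probe_id = ids[h$probe], enzyme = enzymes$name[i],
               occurrence = as.integer(occ), strand = h$strand,
               site_start = h$site_start,
               label = ifelse(tot == 1, enzymes$name[i],
                              paste0(enzymes$name[i], ".", occ)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res[order(match(res$probe_id, ids), res$enzyme, res$occurrence), ,
      drop = FALSE]
}

# one label per probe: hits collapsed with ";" in manifest order
.msre_label <- function(hits, probe_ids) {
  lab <- vapply(probe_ids, function(id) {
    h <- hits[hits$probe_id == id, , drop = FALSE]
    if (nrow(h) == 0) NA_character_ else paste(h$label, collapse = ";")
  }, character(1))
  unname(lab)
}
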