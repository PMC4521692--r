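.norm_chrom <- function(x) sub("^chr", "", x)

.final_records <- function(records) {
  if ("passed_consistency" %in% names(records))
    records <- records[records$passed_consistency, , drop = FALSE]
  records
}

#' Count final DMCs per chromosome
#'
#' Counts only records that passed the full funnel
#' (`passed_consistency`).  Chromosome labels are counted as given
#' (a leading `"chr"` is ignored for ordering).
#'
#' @param records a `funnel_result$records` data frame (or
#'   [candidate_markers()])
#' @return named integer vector, chromosomes in genomic order
#' @export
count_by_chromosome <- function(records) {
  records <- .final_records(records)
  if (nrow(records) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(records$chromosome)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(.chrom_rank(names(out)))]
}

#' Assign final DMCs to genomic regions
#'
#' A record at 1-based position `p` falls in the 0-based half-open
#' region `[start, end)` iff `start <= p - 1 < end`.  A record may fall
#' in several overlapping regions (regions sharing an interval always
#' report identical counts).
#'
#' @param records a `funnel_result$records` data frame with 1-based
#'   `position`; only rows with `passed_consistency` are mapped
#' @param regions a region data frame (see [read_regions()] /
#'   [syndrome_regions()])
#' @return the region table with added columns `n_dmc` and `probes`
#'   (comma-separated probe IDs)
#' @export
assign_regions <- function(records, regions) {
  records <- .final_records(records)
  rc <- .norm_chrom(records$chromosome)
  p0 <- records$position - 1  # to 0-based
  res <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- !is.na(p0) & rc == .norm_chrom(regions$chromosome[i]) &
      p0 >= regions$start[i] & p0 < regions$end[i]
    list(n = sum(hit),
         probes = paste(records$probe_id[hit], collapse = ","))
  })
  regions$n_dmc <- vapply(res, function(x) as.integer(x$n), integer(1))
  regions$probes <- vapply(res, function(x) x$probes, character(1))
  regions
}

#' Ideogram track of final DMCs
#'
#' BED-like data track for ideogram rendering: one row per final DMC,
#' spanning the CpG dinucleotide, coloured by direction — `"red"` for
#' markers hypermethylated in MBC and hypomethylated in CVS
#' (`cvs_hypo_mbc_hyper`), `"blue"` for the reverse.  Rendering itself
#' is left to external ideogram tools; this produces the data track
#' only.
#'
#' @param records a `funnel_result$records` data frame with `position`
#'   and `direction`
#' @return data frame with columns `chromosome`, `start` (0-based),
#'   `end` (`start + 2`), `probe_id`, `direction`, `color`
#' @export
ideogram_track <- function(records) {
  records <- .final_records(records)
  records <- records[records$direction != "none", , drop = FALSE]
  data.frame(chromosome = records$chromosome,
             start = records$position - 1,
             end = records$position + 1,
             probe_id = records$probe_id,
             direction = records$direction,
             color = ifelse(records$direction == "cvs_hypo_mbc_hyper",
                            "red", "blue"),
             stringsAsFactors = FALSE)
}

#' Write an ideogram track
#'
#' Tab-separated with a single `#`-prefixed header line; an empty track
#' writes the header only.
#' @param track data frame from [ideogram_track()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ideogram_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chromosome\tstart\tend\tprobe_id\tdirection\tcolor", con)
  if (nrow(track) > 0)
    utils::write.table(track, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
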