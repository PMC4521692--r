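#' Micro-deletion / duplication syndrome regions
#'
#' Built-in table of twelve genomic regions harbouring well-known
#' sub-microscopic deletion or duplication syndromes, used to map final
#' DMC candidates to clinically interesting intervals.  Coordinates are
#' 0-based half-open (`[start, end)`), BED-style; note that the
#' Prader-Willi and Angelman rows intentionally share the same chr15
#' interval and therefore always report identical DMC counts.
#'
#' @return data frame with columns `chromosome`, `start`, `end`,
#'   `region_size`, `disease`
#' @export
syndrome_regions <- function() {
  df <- data.frame(
    chromosome = c("chr4", "chr5", "chr11", "chr12", "chr15", "chr15",
                   "chr17", "chr17", "chr17", "chr22", "chr22", "chr22"),
    start = c(0, 9800000, 0, 0, 8700000, 8700000,
              0, 16000000, 31800000, 14700000, 17900000, 17900000),
    end = c(4500000, 33800000, 2800000, 35800000, 33600000, 33600000,
            3300000, 22200000, 38100000, 17900000, 25900000, 25900000),
    disease = c(
      "Wolf-Hirschhorn syndrome associated region",
      "Cri-du-Chat syndrome associated region",
      "Beckwith-Wiedemann syndrome associated region",
      "Pallister-Killian syndrome associated region",
      "Prader Willi syndrome associated region",
      "Angelman syndrome associated region",
      "Miller-Dieker lissencephaly syndrome associated region",
      "Smith-Magenis /dup(17)(p11.2p11.2) syndrome associated region",
      "Renal cysts and diabetes (RCAD) associated region",
      "Cat-eye syndrome associated region",
      "dup(22)(q11.2q11.2) syndrome associated region",
      "DiGeorge syndrome 1/ Velocardiofacial syndrome associated region"),
    stringsAsFactors = FALSE)
  df$region_size <- df$end - df$start
  df[, c("chromosome", "start", "end", "region_size", "disease")]
}

.validate_regions <- function(df) {
  if (any(df$start < 0))
    stop("region starts must be >= 0 (0-based half-open)", call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0)
    stop("region start >= end for: ",
         paste(df$disease[bad], collapse = ", "), call. = FALSE)
  df$region_size <- df$end - df$start
  df
}

#' Read a BED-like region file
#'
#' Three BED columns (`chromosome`, 0-based `start`, exclusive `end`)
#' plus a fourth name column (disease / region label).  No header.
#' @param path path to the BED file
#' @return data frame with columns `chromosome`, `start`, `end`,
#'   `region_size`, `disease`
#' @export
read_regions <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !nzchar(first)) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), region_size = integer(0),
                      disease = character(0), stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 4)
    stop("region file needs 4 tab-separated columns: chrom, start, end, name",
         call. = FALSE)
  out <- data.frame(chromosome = df[[1]],
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    disease = df[[4]],
                    stringsAsFactors = FALSE)
  out <- .validate_regions(out)
  out[, c("chromosome", "start", "end", "region_size", "disease")]
}

#' Write a BED-like region file
#' @param regions region data frame (see [read_regions()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions <- function(regions, path) {
  .validate_regions(regions)
  utils::write.table(
    data.frame(regions$chromosome, format(regions$start, scientific = FALSE,
                                          trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE),
               regions$disease),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
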