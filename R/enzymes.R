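# IUPAC nucleotide ambiguity alphabet
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.check_iupac <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(.iupac_sets))
  if (length(bad) > 0)
    stop("invalid IUPAC character(s) '", paste(bad, collapse = ""),
         "' in pattern '", pattern, "'", call. = FALSE)
  invisible(pattern)
}

#' Can an IUPAC pattern resolve to a sequence containing CG?
#'
#' A methylation-sensitive restriction enzyme can only be blocked by CpG
#' methylation if its recognition site contains a CpG; patterns without
#' one are flagged on read.
#' @param pattern IUPAC recognition pattern
#' @return logical
#' @export
pattern_contains_cg <- function(pattern) {
  .check_iupac(pattern)
  chars <- strsplit(pattern, "")[[1]]
  if (length(chars) < 2) return(FALSE)
  any(vapply(seq_len(length(chars) - 1), function(i) {
    "C" %in% .iupac_sets[[chars[i]]] && "G" %in% .iupac_sets[[chars[i + 1]]]
  }, logical(1)))
}

#' Build a validated enzyme table
#'
#' @param name enzyme names
#' @param pattern IUPAC recognition patterns (length >= 4)
#' @return data frame with columns `name`, `pattern`, `cuts_cpg`
#'   (whether the pattern can contain a CG dinucleotide when resolved)
#' @export
enzyme_table <- function(name, pattern) {
  if (length(name) != length(pattern))
    stop("`name` and `pattern` must have equal length", call. = FALSE)
  pattern <- toupper(pattern)
  for (p in pattern) .check_iupac(p)
  if (any(nchar(pattern) < 4))
    stop("recognition patterns must be at least 4 nt long", call. = FALSE)
  if (anyDuplicated(name))
    stop("duplicate enzyme name(s)", call. = FALSE)
  data.frame(name = as.character(name), pattern = pattern,
             cuts_cpg = vapply(pattern, pattern_contains_cg, logical(1),
                               USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Default methylation-sensitive restriction enzyme set
#'
#' The nine CpG-containing MSREs that appear in the bundled candidate
#' marker table.  The set is deliberately configuration, not code: a
#' larger panel (e.g. the full 16-enzyme screening set) can be supplied
#' to any function that takes an `enzymes` argument via
#' [read_enzymes()] or [enzyme_table()].
#'
#' @return an enzyme table (see [enzyme_table()])
#' @export
default_enzymes <- function() {
  enzyme_table(
    name = c("AciI", "HhaI", "HpyCH4IV", "HpaII", "AatII", "BstUI",
             "ClaI", "EagI", "AgeI"),
    pattern = c("CCGC", "GCGC", "ACGT", "CCGG", "GACGTC", "CGCG",
                "ATCGAT", "CGGCCG", "ACCGGT"))
}

#' Read an enzyme table
#'
#' Tab-delimited, two header columns: `name`, `pattern` (IUPAC).
#' @param path path to the enzyme TSV
#' @return an enzyme table (see [enzyme_table()])
#' @export
read_enzymes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("name", "pattern") %in% names(df)))
    stop("enzyme file needs columns name, pattern", call. = FALSE)
  enzyme_table(df$name, df$pattern)
}

#' Write an enzyme table
#' @param enzymes an enzyme table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enzymes <- function(enzymes, path) {
  utils::write.table(enzymes[, c("name", "pattern")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
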