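#' Validate a probe annotation table
#'
#' A probe annotation (manifest) row describes one array probe: its
#' genomic location, the flanking sequence around the interrogated CpG
#' and whether the probe is a SNP control probe.  Internally the CpG is
#' addressed by `cpg_site`, the 1-based index of the C of the target CpG
#' within `flank`; on disk ([read_manifest()]/[write_manifest()]) the
#' column is the 0-based `cpg_offset`.
#'
#' @param manifest data frame with columns `probe_id`, `chromosome`,
#'   `position` (1-based coordinate of the CpG's C on the forward
#'   strand), `gene` (optional label, `NA` allowed), `refseq` (optional),
#'   `flank` (string over A/C/G/T, or `N` for SNP control probes),
#'   `cpg_site` (1-based index into `flank`), `is_snp` (logical).
#' @return the validated data frame (invisibly the same object)
#' @export
probe_annotation <- function(manifest) {
  need <- c("probe_id", "chromosome", "position", "gene", "refseq",
            "flank", "cpg_site", "is_snp")
  absent <- setdiff(need, names(manifest))
  if (length(absent) > 0)
    stop("manifest lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$probe_id))
    stop("duplicate probe ID(s) in manifest: ",
         paste(unique(manifest$probe_id[duplicated(manifest$probe_id)]),
               collapse = ", "), call. = FALSE)
  if (any(!is.na(manifest$position) & manifest$position < 1))
    stop("probe positions must be >= 1 (1-based)", call. = FALSE)
  manifest$is_snp <- as.logical(manifest$is_snp)

  chk <- !manifest$is_snp & !is.na(manifest$flank) & !is.na(manifest$cpg_site)
  dinuc <- substr(manifest$flank[chk], manifest$cpg_site[chk],
                  manifest$cpg_site[chk] + 1L)
  bad <- which(dinuc != "CG")
  if (length(bad) > 0)
    stop("flank lacks CG at the annotated CpG site for probe(s): ",
         paste(utils::head(manifest$probe_id[chk][bad], 5), collapse = ", "),
         call. = FALSE)
  manifest
}

#' Read a probe manifest
#'
#' Tab-delimited with header columns `probe_id`, `chromosome`,
#' `position`, `gene`, `refseq`, `flank`, `cpg_offset` (0-based index of
#' the C of the target CpG within `flank`), `is_snp` (0/1).  SNP control
#' probes are exempt from the CG-at-offset check (their `flank` may be
#' `N`).
#'
#' @param path path to the manifest TSV
#' @return a validated probe annotation data frame (see
#'   [probe_annotation()]; `cpg_offset` is converted to the 1-based
#'   `cpg_site` column)
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "chromosome", "position", "gene", "refseq",
            "flank", "cpg_offset", "is_snp")
  absent <- setdiff(need, names(df))
  if (length(absent) > 0)
    stop("manifest file lacks column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (col in c("gene", "refseq"))
    df[[col]][df[[col]] %in% .missing_tokens] <- NA_character_
  out <- data.frame(
    probe_id = df$probe_id,
    chromosome = df$chromosome,
    position = as.integer(df$position),
    gene = df$gene,
    refseq = df$refseq,
    flank = df$flank,
    cpg_site = as.integer(df$cpg_offset) + 1L,
    is_snp = as.integer(df$is_snp) != 0L,
    stringsAsFactors = FALSE)
  probe_annotation(out)
}

#' Write a probe manifest
#'
#' Inverse of [read_manifest()] (the in-memory 1-based `cpg_site` is
#' written back as the 0-based `cpg_offset` file column).
#' @param manifest a probe annotation data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  manifest <- probe_annotation(manifest)
  out <- data.frame(
    probe_id = manifest$probe_id,
    chromosome = manifest$chromosome,
    position = manifest$position,
    gene = manifest$gene,
    refseq = manifest$refseq,
    flank = manifest$flank,
    cpg_offset = manifest$cpg_site - 1L,
    is_snp = as.integer(manifest$is_snp),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
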