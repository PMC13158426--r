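#' Read ATAC-seq peaks from a BED file
#'
#' BED is 0-based half-open, which is also the package's internal
#' convention, so coordinates pass through unchanged. When the file has no
#' summit information the summit defaults to the interval midpoint
#' `floor((start + end) / 2)`.
#'
#' @param path Path to a BED4/BED6 file.
#' @return A data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit`.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) .fail("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) nm <- sprintf("peak_%06d", seq_along(gr))
  if (anyDuplicated(nm)) .fail("duplicate peak ids in %s", path)
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  data.frame(
    peak_id = as.character(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = s0, end = e0,
    summit = as.integer(floor((s0 + e0) / 2)),
    stringsAsFactors = FALSE
  )
}

#' Write peaks as 6-column BED
#'
#' @param peaks Peak data.frame with `peak_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", peaks$chrom,
                     as.integer(peaks$start), as.integer(peaks$end),
                     peaks$peak_id), path)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature ids; the header holds sample ids.
#'
#' @param path Path to the TSV file.
#' @param units Units tag to attach (`"raw"`, `"CPM"`, `"FPKM"`,
#'   `"log2CPM"`, `"normalized"`).
#' @return A numeric matrix with a `units` attribute.
#' @export
read_matrix <- function(path, units = "raw") {
  if (!file.exists(path)) .fail("matrix file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          fill = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) .fail("duplicate feature ids in %s", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) .fail("non-numeric values in matrix %s", path)
  rownames(m) <- ids
  .check_matrix(m, path)
  if (units == "raw" && any(m < 0)) .fail("raw counts must be non-negative: %s", path)
  .set_units(m, units)
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m Matrix with feature row names and sample column names.
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .fail("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector (or `DNAStringSet`) of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set id, description, member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .fail("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `tissue`, `sex` (male/female),
#' `timepoint_weeks` (0 = sedentary control).
#'
#' @param path Path to the sample sheet.
#' @return A validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .fail("sample sheet not found: %s", path)
  meta <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  .check_meta(meta)
  meta$timepoint_weeks <- as.numeric(meta$timepoint_weeks)
  meta
}

#' Write a sample sheet TSV
#'
#' @param meta Sample sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(meta, path) {
  .check_meta(meta)
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
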