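#' Gene annotation table
#'
#' Internally genes are kept in a data.frame with 0-based half-open
#' coordinates (BED-native), one arithmetic convention for all midpoint and
#' distance computations in the package. GTF input (1-based inclusive) is
#' converted at the boundary. Derived columns:
#' * `midpoint` = `floor((start + end) / 2)` of the gene span,
#' * `tss` = `start` on the + strand, `end - 1` (last base) on the - strand,
#' * `exonic_length` = total length of the merged exons.
#'
#' @name gene_annotation
#' @keywords internal
NULL

# internal: construct/validate a gene annotation data.frame
.make_annotation <- function(gene_id, chrom, start, end, strand, biotype, exons) {
  stopifnot(length(gene_id) == length(chrom))
  if (anyDuplicated(gene_id)) .fail("duplicate gene_id in annotation")
  if (any(end <= start)) .fail("annotation has gene(s) with end <= start")
  biotype <- ifelse(biotype %in% c("lncRNA", "protein_coding"), biotype, "other")
  exons <- lapply(seq_along(exons), function(i) {
    ex <- .merge_intervals(exons[[i]])
    if (nrow(ex) == 0L) ex <- cbind(start = start[i], end = end[i])
    if (any(ex[, 1] < start[i]) || any(ex[, 2] > end[i]))
      .fail("gene %s has exons outside the gene span", gene_id[i])
    ex
  })
  ann <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), biotype = biotype,
    stringsAsFactors = FALSE
  )
  ann$exons <- exons
  ann$exonic_length <- vapply(exons, function(e) sum(e[, 2] - e[, 1]), numeric(1))
  ann$midpoint <- as.integer(floor((ann$start + ann$end) / 2))
  ann$tss <- ifelse(ann$strand == "-", ann$end - 1L, ann$start)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# internal: sort and merge possibly-overlapping intervals (0-based half-open)
.merge_intervals <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(cbind(start = integer(0), end = integer(0)))
  x <- matrix(as.integer(x), ncol = 2, dimnames = list(NULL, c("start", "end")))
  x <- x[order(x[, 1], x[, 2]), , drop = FALSE]
  out <- x[1, , drop = FALSE]
  if (nrow(x) > 1) for (i in 2:nrow(x)) {
    j <- nrow(out)
    if (x[i, 1] <= out[j, 2]) out[j, 2] <- max(out[j, 2], x[i, 2])
    else out <- rbind(out, x[i, , drop = FALSE])
  }
  out
}

#' Read a GTF-style gene annotation
#'
#' Parses `gene` and `exon` records carrying `gene_id` and `gene_biotype`
#' attributes. 1-based inclusive GTF coordinates are converted to the
#' package's 0-based half-open convention; overlapping exons are merged;
#' biotypes other than `lncRNA`/`protein_coding` map to `"other"`.
#'
#' @param path Path to a GTF-like file.
#' @param dialect Only `"gtf_like"` is supported.
#' @return A `gene_annotation` data.frame (see [gene_annotation]).
#' @export
read_annotation <- function(path, dialect = "gtf_like") {
  dialect <- match.arg(dialect, "gtf_like")
  if (!file.exists(path)) .fail("annotation file not found: %s", path)
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  nf <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 9L))
    .fail("malformed GTF record at line %d: expected 9 tab-separated fields",
          body[which(nf < 9L)[1]])
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || anyNA(md$gene_id))
    .fail("GTF records must carry a gene_id attribute")
  type <- as.character(md$type)
  is_gene <- type == "gene"
  is_exon <- type == "exon"
  if (!any(is_gene)) .fail("no gene records in %s", path)
  gid <- as.character(md$gene_id)
  bt <- if (!is.null(md$gene_biotype)) as.character(md$gene_biotype) else rep("other", length(gr))
  g <- which(is_gene)
  exons <- split(
    cbind(GenomicRanges::start(gr)[is_exon] - 1L, GenomicRanges::end(gr)[is_exon]),
    factor(gid[is_exon], levels = gid[g])
  )
  exons <- lapply(exons, function(v) matrix(v, ncol = 2))
  .make_annotation(
    gene_id = gid[g],
    chrom = as.character(GenomicRanges::seqnames(gr))[g],
    start = GenomicRanges::start(gr)[g] - 1L,
    end = GenomicRanges::end(gr)[g],
    strand = ifelse(as.character(GenomicRanges::strand(gr))[g] == "-", "-", "+"),
    biotype = ifelse(is.na(bt[g]), "other", bt[g]),
    exons = exons
  )
}

#' Write a gene annotation as GTF-style text
#'
#' Emits one `gene` record plus its merged `exon` records per gene, in
#' 1-based inclusive GTF coordinates with `gene_id` and `gene_biotype`
#' attributes. `read_annotation(write_annotation(x))` is the identity on the
#' record set.
#'
#' @param ann A `gene_annotation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  fmt <- function(chrom, feat, s0, e0, strand, gid, bt) {
    sprintf('%s\tlnclink\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
            chrom, feat, s0 + 1L, e0, strand, gid, bt)
  }
  lines <- unlist(lapply(seq_len(nrow(ann)), function(i) {
    ex <- ann$exons[[i]]
    c(fmt(ann$chrom[i], "gene", ann$start[i], ann$end[i], ann$strand[i],
          ann$gene_id[i], ann$biotype[i]),
      fmt(ann$chrom[i], "exon", ex[, 1], ex[, 2], ann$strand[i],
          ann$gene_id[i], ann$biotype[i]))
  }))
  writeLines(lines, path)
  invisible(path)
}
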