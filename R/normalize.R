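#' Counts per million
#'
#' Scales each sample (column) to a library size of one million, so every
#' output column sums to 1e6.
#'
#' @param counts Raw count matrix (features x samples).
#' @return CPM matrix tagged with units `"CPM"`.
#' @export
cpm <- function(counts) {
  .check_matrix(counts, "counts")
  lib <- colSums(counts)
  if (any(lib <= 0))
    .fail("zero library size for sample(s): %s",
          paste(colnames(counts)[lib <= 0], collapse = ", "))
  .set_units(sweep(counts, 2, lib / 1e6, "/"), "CPM")
}

#' Fragments per kilobase per million
#'
#' `FPKM = count / (library_size / 1e6) / (length / 1e3)`. With all lengths
#' equal to 1000 bp, FPKM equals CPM.
#'
#' @param counts Raw count matrix.
#' @param exonic_lengths Named numeric vector of exonic lengths in bp,
#'   covering every row of `counts`.
#' @return FPKM matrix tagged with units `"FPKM"`.
#' @export
fpkm <- function(counts, exonic_lengths) {
  .check_matrix(counts, "counts")
  miss <- setdiff(rownames(counts), names(exonic_lengths))
  if (length(miss))
    .fail("missing exonic length for gene(s): %s", paste(head(miss, 5), collapse = ", "))
  len <- exonic_lengths[rownames(counts)]
  if (any(len <= 0)) .fail("non-positive exonic length")
  out <- cpm(counts) / (len / 1e3)
  .set_units(out, "FPKM")
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample composition normalization: for each sample against a
#' reference, the factor is the exponentiated precision-weighted mean of
#' log2 expression ratios (M-values) after trimming the most extreme 30% of
#' M-values and 5% of average-abundance (A) values on each side. Factors are
#' rescaled to geometric mean 1; they measure composition, not sequencing
#' depth, so doubling a sample's counts leaves its factor unchanged.
#'
#' @param counts Raw count matrix with at least two samples.
#' @param reference Sample id to use as reference, or `"auto"` (the sample
#'   whose upper-quartile count fraction is closest to the mean).
#' @param trim_m,trim_a Two-sided trim fractions for M and A values.
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, reference = "auto", trim_m = 0.30, trim_a = 0.05) {
  .check_matrix(counts, "counts")
  if (ncol(counts) < 2L) .fail("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    .fail("all-zero sample(s): %s", paste(colnames(counts)[lib <= 0], collapse = ", "))
  if (identical(reference, "auto")) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) .fail("reference sample %s not found", reference)
  }
  r <- counts[, ref]
  nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    y <- counts[, j]
    nj <- lib[j]
    keep <- y > 0 & r > 0
    if (!any(keep)) return(1)
    yk <- y[keep]; rk <- r[keep]
    m <- log2((yk / nj) / (rk / nr))
    a <- 0.5 * log2((yk / nj) * (rk / nr))
    if (max(abs(m)) < 1e-6) return(1)
    # precision weights from the delta method on binomial counts
    w <- (nj - yk) / (nj * yk) + (nr - rk) / (nr * rk)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra_ <- rank(a)
    keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep2)) return(1)
    fj <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
    if (!is.finite(fj) || fj <= 0) 1 else fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over genes with nonzero counts
#' in all samples, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts Raw count matrix.
#' @return Named numeric vector of size factors.
#' @export
median_of_ratios_factors <- function(counts) {
  .check_matrix(counts, "counts")
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) .fail("no gene with nonzero counts in all samples; matrix unusable")
  geo <- exp(logg[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) median(col / geo))
  setNames(sf, colnames(counts))
}

#' Detection filter on counts-per-million
#'
#' A gene is retained iff its CPM strictly exceeds `min_cpm` in at least
#' `min_samples` samples of the tissue stratum. With a `tissue` vector the
#' filter (including the CPM computation) is applied within each tissue.
#'
#' @param counts Raw count matrix.
#' @param tissue Optional tissue label per sample (column).
#' @param min_cpm Strict CPM threshold.
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return Character vector of retained gene ids, or a named list of such
#'   vectors (one per tissue) when `tissue` is given.
#' @export
filter_detected <- function(counts, tissue = NULL, min_cpm = 0.5, min_samples = 2) {
  .check_matrix(counts, "counts")
  one <- function(m) {
    keep <- rowSums(cpm(m) > min_cpm) >= min_samples
    rownames(m)[keep]
  }
  if (is.null(tissue)) return(one(counts))
  stopifnot(length(tissue) == ncol(counts))
  lapply(split(seq_len(ncol(counts)), tissue),
         function(idx) one(counts[, idx, drop = FALSE]))
}

#' Expressed-lncRNA filter on mean FPKM
#'
#' Retains lncRNA genes whose mean FPKM across the supplied samples is at
#' least `min_mean_fpkm` (inclusive, per the "adequately expressed"
#' convention). Coding and other biotypes never appear in the output.
#'
#' @param fpkm_mat FPKM matrix.
#' @param ann Gene annotation with a `biotype` column.
#' @param min_mean_fpkm Inclusive mean-FPKM threshold.
#' @return Character vector of expressed lncRNA gene ids.
#' @export
filter_expressed_lnc <- function(fpkm_mat, ann, min_mean_fpkm = 1) {
  .check_matrix(fpkm_mat, "fpkm")
  lnc <- ann$gene_id[ann$biotype == "lncRNA"]
  lnc <- intersect(lnc, rownames(fpkm_mat))
  lnc[rowMeans(fpkm_mat[lnc, , drop = FALSE]) >= min_mean_fpkm]
}
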