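#' @useDynLib lnclink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor ecdf mad median p.adjust pchisq phyper pt
#'   quantile rbinom rexp rlnorm rnbinom rnorm runif sd var setNames
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a root seed and a stream name
#'
#' All randomness in the synthetic-data generator flows from one root seed
#' through named substreams, one per emitted artifact, so that adding a new
#' artifact does not perturb the draws of existing ones. The substream seed
#' is a deterministic 31-bit hash of the root seed and the stream name.
#'
#' @param seed Integer root seed.
#' @param name Character stream name (e.g. `"rna_counts"`).
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (cc in utf8ToInt(name)) {
    h <- (h * 31 + cc) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# internal: stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# internal: validate a count/expression matrix
.check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) .fail("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    .fail("%s must have unique row (feature) names", what)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    .fail("%s must have unique column (sample) names", what)
  invisible(x)
}

# internal: tag a matrix with its expression units
.set_units <- function(x, units) {
  attr(x, "units") <- units
  x
}

#' Expression units tag of a matrix
#'
#' @param x A matrix produced by [read_matrix()], [cpm()], [fpkm()] or the
#'   simulator; raw matrices without a tag report `"raw"`.
#' @return One of `"raw"`, `"CPM"`, `"FPKM"`, `"log2CPM"`, `"normalized"`.
#' @export
matrix_units <- function(x) attr(x, "units") %||% "raw"

# internal: validate sample metadata sheet
.check_meta <- function(meta, counts = NULL) {
  need <- c("sample_id", "tissue", "sex", "timepoint_weeks")
  miss <- setdiff(need, names(meta))
  if (length(miss)) .fail("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) .fail("sample sheet has duplicate sample ids")
  bad <- setdiff(unique(meta$sex), c("male", "female"))
  if (length(bad)) .fail("unknown sex value(s): %s", paste(bad, collapse = ", "))
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), meta$sample_id)
    if (length(miss))
      .fail("count-matrix column(s) missing from sample sheet: %s",
            paste(head(miss, 5), collapse = ", "))
  }
  invisible(meta)
}
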