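# Vectorized two-sided Welch test on the rows of two group submatrices.
# Degenerate guard: when both groups have zero variance and equal means the
# statistic is 0/0; such rows report p = 1 (no evidence, not an error).
.row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  zero_se <- se2 == 0
  p[zero_se & m1 == m2] <- 1
  p[zero_se & m1 != m2] <- 1e-300
  p[!is.finite(p)] <- 1
  p <- pmax(p, 1e-300)
  list(diff = m1 - m2, p = p)
}

#' Timewise sex-stratified differential expression
#'
#' For each tissue, counts are normalized by median-of-ratios size factors
#' and transformed to `log2(normalized + pseudocount)`. Male and female
#' samples are analyzed separately, contrasting each training timepoint
#' against the sex-matched sedentary (week 0) controls: the effect size is
#' the difference of group means on the log2 scale and the p-value comes
#' from a two-sided Welch test on the same transformed values. Contrasts
#' with fewer than two replicates in either group are skipped with a
#' warning. Per-tissue BH-adjusted p-values are included.
#'
#' @param counts Raw count matrix covering all samples in `meta`.
#' @param meta Sample sheet (`sample_id`, `tissue`, `sex`,
#'   `timepoint_weeks`; week 0 = sedentary control).
#' @param engine Differential engine; only `"welch_logcpm"` is implemented.
#' @param pseudocount Pseudocount added before the log2 transform.
#' @return A `de_result` data.frame with one row per testable
#'   gene x tissue x sex x timepoint: `gene_id`, `tissue`, `sex`,
#'   `timepoint_weeks`, `log2fc`, `p`, `adj_p`, `is_differential` (NA until
#'   [call_delnc()] is applied).
#' @export
de_timewise <- function(counts, meta, engine = "welch_logcpm", pseudocount = 1) {
  engine <- match.arg(engine, "welch_logcpm")
  .check_matrix(counts, "counts")
  .check_meta(meta, counts)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  out <- list()
  for (ti in unique(meta$tissue)) {
    sel <- meta$tissue == ti
    sub <- counts[, sel, drop = FALSE]
    msub <- meta[sel, ]
    sf <- median_of_ratios_factors(sub)
    lx <- log2(sweep(sub, 2, sf, "/") + pseudocount)
    for (sx in intersect(c("male", "female"), unique(msub$sex))) {
      ctrl <- which(msub$sex == sx & msub$timepoint_weeks == 0)
      for (tp in sort(setdiff(unique(msub$timepoint_weeks[msub$sex == sx]), 0))) {
        trt <- which(msub$sex == sx & msub$timepoint_weeks == tp)
        if (length(trt) < 2L || length(ctrl) < 2L) {
          warning(sprintf("skipping %s/%s/week %s: fewer than 2 replicates",
                          ti, sx, tp), call. = FALSE)
          next
        }
        w <- .row_welch(lx[, trt, drop = FALSE], lx[, ctrl, drop = FALSE])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = rownames(counts), tissue = ti, sex = sx,
          timepoint_weeks = tp, log2fc = unname(w$diff), p = unname(w$p),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) .fail("no testable contrasts in the design")
  de <- do.call(rbind, out)
  de$adj_p <- stats::ave(de$p, de$tissue, FUN = function(p) p.adjust(p, "BH"))
  de$is_differential <- NA
  class(de) <- c("de_result", "data.frame")
  de
}

#' Import an externally computed differential-expression table
#'
#' Fidelity escape hatch: tables produced by external engines (e.g. a
#' negative-binomial GLM fit) can drive every downstream stage, which
#' consumes only (`log2fc`, `p`).
#'
#' @param path TSV with columns `gene_id`, `tissue`, `sex`, `timepoint_weeks`
#'   (or `timepoint`), `log2fc`, `p`, and optionally `adj_p`.
#' @return A `de_result` data.frame; `adj_p` is recomputed per tissue by BH
#'   when not supplied.
#' @export
import_de_table <- function(path) {
  if (!file.exists(path)) .fail("DE table not found: %s", path)
  de <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if ("timepoint" %in% names(de) && !"timepoint_weeks" %in% names(de))
    names(de)[names(de) == "timepoint"] <- "timepoint_weeks"
  need <- c("gene_id", "tissue", "sex", "timepoint_weeks", "log2fc", "p")
  miss <- setdiff(need, names(de))
  if (length(miss)) .fail("DE table missing column(s): %s", paste(miss, collapse = ", "))
  key <- do.call(paste, de[c("gene_id", "tissue", "sex", "timepoint_weeks")])
  if (anyDuplicated(key)) .fail("duplicate gene x tissue x sex x timepoint rows")
  if (any(de$p <= 0 | de$p > 1)) .fail("p-values must lie in (0, 1]")
  if (!"adj_p" %in% names(de))
    de$adj_p <- stats::ave(de$p, de$tissue, FUN = function(p) p.adjust(p, "BH"))
  if (!"is_differential" %in% names(de)) de$is_differential <- NA
  de <- de[c(need, "adj_p", "is_differential")]
  class(de) <- c("de_result", "data.frame")
  de
}

#' Export a differential-expression table as TSV
#'
#' @param de A `de_result` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
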