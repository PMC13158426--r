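#' Fisher's sum-of-logs p-value combination
#'
#' Combines k independent p-values (here: the male- and female-specific
#' training p-values of a feature) into one meta p-value via
#' `stat = -2 * sum(log(p))`, referred to the upper tail of a chi-squared
#' distribution with `2k` degrees of freedom. Zero p-values are clamped to
#' `p_floor` with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param p_floor Clamp for p = 0 (avoids `log(0)`).
#' @return List with `stat`, `df` and `meta_p`.
#' @export
fisher_combine <- function(p, p_floor = 1e-300) {
  if (!length(p)) .fail("no p-values to combine")
  if (any(p < 0 | p > 1, na.rm = TRUE)) .fail("p-values must lie in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value of 0 clamped to floor", call. = FALSE)
    p[p == 0] <- p_floor
  }
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(stat = stat, df = df, meta_p = pchisq(stat, df, lower.tail = FALSE))
}

# Vectorized Fisher combination across the rows of a p-value matrix
# (features x strata, e.g. male / female columns). NA entries are skipped.
.fisher_combine_rows <- function(pmat, p_floor = 1e-300) {
  pmat[pmat == 0] <- p_floor
  lg <- log(pmat)
  k <- rowSums(!is.na(lg))
  stat <- -2 * rowSums(lg, na.rm = TRUE)
  meta_p <- pchisq(stat, 2 * k, lower.tail = FALSE)
  meta_p[k == 0] <- NA_real_
  data.frame(stat_fisher = stat, df = 2L * k, meta_p = meta_p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Covariate-weighted BH adjustment (grouped weighting)
#'
#' Approximates covariate-informed multiple-testing weighting: hypotheses
#' are grouped by a covariate (here: tissue), each group's signal fraction
#' `1 - pi0` is estimated by Storey's method at `lambda = 0.5`, weights are
#' normalized to mean 1 across hypotheses and floored at `weight_floor`,
#' and BH is applied to `p / w`. Groups with fewer than `min_group_size`
#' hypotheses get weight 1 (no estimation) with a warning. With a single
#' group the result is identical to [bh_adjust()].
#'
#' @param p Numeric vector of p-values.
#' @param covariate_group Group label per hypothesis.
#' @param lambda Storey tuning parameter.
#' @param weight_floor Minimum weight after normalization.
#' @param min_group_size Below this size a group's weight is forced to 1.
#' @return Adjusted p-values.
#' @export
grouped_bh <- function(p, covariate_group, lambda = 0.5, weight_floor = 0.05,
                       min_group_size = 20) {
  stopifnot(length(p) == length(covariate_group))
  g <- as.character(covariate_group)
  w <- rep(1, length(p))
  raw <- vapply(split(p, g), function(pg) {
    pi0 <- min(1, mean(pg > lambda) / (1 - lambda))
    1 - pi0
  }, numeric(1))
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small) && length(sizes) > length(small))
    warning(sprintf("group(s) with < %d hypotheses get weight 1: %s",
                    min_group_size, paste(small, collapse = ", ")), call. = FALSE)
  est <- setdiff(names(sizes), small)
  if (length(est) && any(raw[est] > 0)) {
    idx <- g %in% est
    w_raw <- raw[g[idx]]
    # normalize so the mean weight over the estimated hypotheses (and hence,
    # with the forced-1 groups, over all hypotheses) is 1
    w[idx] <- w_raw * sum(idx) / sum(w_raw)
  }
  w <- pmax(w, weight_floor)
  pw <- pmin(p / w, 1)
  adj <- p.adjust(pw, method = "BH")
  pmin(adj, 1)
}

# Vectorized one-way ANOVA F-test across the rows of a matrix.
.row_ftest <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(x)
  if (k < 2L) .fail("F-test needs at least two groups")
  gm <- rowMeans(x)
  ssb <- 0; ssw <- 0
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    mi <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (mi - gm)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mi)^2)
  }
  df1 <- k - 1; df2 <- n - k
  fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 1e-300
  list(stat = fstat, p = pmax(p, 1e-300))
}

#' Any-timepoint one-way F-test
#'
#' Tests whether a feature's normalized values differ across timepoint
#' groups (sedentary week 0 plus the training weeks) with a classic
#' equal-variance one-way ANOVA F-test, the per-sex "any training response"
#' screen applied to chromatin accessibility.
#'
#' @param values Numeric vector (one feature) or matrix (features x samples).
#' @param groups Timepoint label per sample.
#' @return For a vector, the upper-tail p-value; for a matrix, a vector of
#'   p-values (one per row).
#' @export
ftest_any_timepoint <- function(values, groups) {
  if (is.matrix(values)) {
    if (any(table(groups) < 2L)) .fail("each timepoint group needs >= 2 samples")
    return(.row_ftest(values, groups)$p)
  }
  stopifnot(length(values) == length(groups))
  if (any(table(groups) < 2L)) .fail("each timepoint group needs >= 2 samples")
  .row_ftest(matrix(values, nrow = 1), groups)$p
}

#' Call differential lncRNAs / genes
#'
#' Nominal mode flags rows with `p <= p_max` and `|log2fc| >= lfc_min`
#' (both inclusive; defaults 0.01 and 1). Stringent mode instead applies
#' within-tissue BH and flags `adj_p <= fdr_max` (default 0.10) with
#' `|log2fc| >= lfc_min_stringent` (default 0.5).
#'
#' @param de A `de_result` data.frame.
#' @param mode `"nominal"` or `"stringent"`.
#' @param p_max,lfc_min Nominal thresholds (inclusive).
#' @param fdr_max,lfc_min_stringent Stringent thresholds (inclusive).
#' @return `de` with `is_differential` filled in (and `adj_p` recomputed
#'   within tissue in stringent mode).
#' @export
call_delnc <- function(de, mode = c("nominal", "stringent"), p_max = 0.01,
                       lfc_min = 1.0, fdr_max = 0.10, lfc_min_stringent = 0.5) {
  mode <- match.arg(mode)
  if (mode == "nominal") {
    de$is_differential <- de$p <= p_max & abs(de$log2fc) >= lfc_min
  } else {
    de$adj_p <- stats::ave(de$p, de$tissue, FUN = function(p) p.adjust(p, "BH"))
    de$is_differential <- de$adj_p <= fdr_max & abs(de$log2fc) >= lfc_min_stringent
  }
  de
}

#' Hypergeometric gene-set enrichment
#'
#' For each set in the collection, computes the hypergeometric upper-tail
#' probability of the observed overlap between the query and the set within
#' the universe, then BH-adjusts across sets. Sets with `adj_p < fdr_max`
#' are flagged as enriched.
#'
#' @param query Character vector of query gene ids (subset of `universe`).
#' @param universe Character vector of background gene ids.
#' @param collection Named list of gene sets.
#' @param fdr_max Strict adjusted-p threshold for the enrichment flag.
#' @return data.frame with `set_id`, `set_size`, `overlap`, `p`, `adj_p`,
#'   `is_enriched`, ordered by p.
#' @export
hypergeom_enrich <- function(query, universe, collection, fdr_max = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) .fail("empty universe")
  query <- unique(intersect(query, universe))
  n_u <- length(universe); n_q <- length(query)
  res <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(query, set))
    p <- if (length(set) == 0L) 1 else
      phyper(k - 1, length(set), n_u - length(set), n_q, lower.tail = FALSE)
    data.frame(set_id = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(set_id = character(0), set_size = integer(0),
                                      overlap = integer(0), p = numeric(0),
                                      adj_p = numeric(0), is_enriched = logical(0)))
  out$adj_p <- p.adjust(out$p, method = "BH")
  out$is_enriched <- out$adj_p < fdr_max
  out[order(out$p, out$set_id), , drop = FALSE]
}

#' Sex meta-analysis of peak (or gene) training responses
#'
#' Combines the per-sex any-timepoint F-test p-values of each feature with
#' Fisher's sum-of-logs into a single training p-value, then adjusts with
#' covariate-weighted BH (tissue as the covariate when several tissues are
#' present). Features at adjusted p <= `fdr_max` are flagged differential.
#'
#' @param pmat Matrix of per-sex p-values (features x sexes), or a
#'   data.frame with `feature_id`, per-sex p columns and optionally `tissue`.
#' @param tissue Optional tissue label per feature (weighting covariate).
#' @param fdr_max Inclusive adjusted-p threshold.
#' @return data.frame with `feature_id`, `stat_fisher`, `df`, `meta_p`,
#'   `adj_p`, `is_differential`.
#' @export
meta_training_response <- function(pmat, tissue = NULL, fdr_max = 0.05) {
  .fc <- .fisher_combine_rows(as.matrix(pmat))
  out <- data.frame(feature_id = rownames(pmat) %||% as.character(seq_len(nrow(pmat))),
                    .fc, stringsAsFactors = FALSE)
  out$adj_p <- if (is.null(tissue) || length(unique(tissue)) < 2L)
    bh_adjust(out$meta_p)
  else grouped_bh(out$meta_p, tissue)
  out$is_differential <- out$adj_p <= fdr_max
  out
}
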