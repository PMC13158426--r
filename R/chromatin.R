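#' Trim peaks to a fixed width around the summit
#'
#' Re-centers each peak to `[summit - width/2, summit + width/2)`. At
#' chromosome edges the interval is shifted (not shrunk) so the width is
#' preserved. After trimming, the interval midpoint IS the summit, so
#' summit-based and midpoint-based distance definitions coincide.
#'
#' @param peaks Peak data.frame (`peak_id`, `chrom`, `start`, `end`,
#'   `summit`).
#' @param width Target width in bp (default 200).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   edge clipping.
#' @return Trimmed peak data.frame (summit updated to the new midpoint).
#' @export
trim_peaks <- function(peaks, width = 200, chrom_lengths = NULL) {
  half <- width %/% 2
  s <- as.integer(peaks$summit - half)
  e <- s + as.integer(width)
  shift <- pmax(0L, -s)
  s <- s + shift; e <- e + shift
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths[peaks$chrom]
    if (any(!is.na(cl) & cl < width))
      .fail("chromosome shorter than the %d-bp trim width", width)
    over <- !is.na(cl) & e > cl
    s[over] <- as.integer(cl[over] - width)
    e[over] <- as.integer(cl[over])
  }
  peaks$start <- s
  peaks$end <- e
  peaks$summit <- as.integer(floor((s + e) / 2))
  peaks
}

#' Filter peaks on raw read support and chromosome policy
#'
#' A peak is kept iff it has at least `min_reads` raw reads in at least
#' `min_samples` samples (both inclusive) and, when a chromosome policy is
#' supplied, lies on an allowed chromosome.
#'
#' @param peak_counts Raw peak x sample count matrix.
#' @param peaks Optional peak data.frame (needed for the chromosome policy).
#' @param min_reads,min_samples Inclusive support thresholds.
#' @param chroms_allowed Optional character vector of allowed chromosomes.
#' @return Character vector of retained peak ids.
#' @export
filter_peaks <- function(peak_counts, peaks = NULL, min_reads = 10,
                         min_samples = 4, chroms_allowed = NULL) {
  .check_matrix(peak_counts, "peak counts")
  keep <- rowSums(peak_counts >= min_reads) >= min_samples
  ids <- rownames(peak_counts)[keep]
  if (!is.null(chroms_allowed)) {
    if (is.null(peaks)) .fail("peaks table required for the chromosome policy")
    ok <- peaks$peak_id[peaks$chrom %in% chroms_allowed]
    ids <- intersect(ids, ok)
  }
  ids
}

#' Pair lncRNAs with local differential peaks
#'
#' Forms all (lncRNA, peak) pairs on the same chromosome whose midpoints
#' lie within `window` bp of each other (inclusive: a distance of exactly
#' `window` is paired). The lncRNA midpoint is the midpoint of the gene
#' span; the peak midpoint is its summit (identical after [trim_peaks()]).
#' Callers should restrict `peaks` to training-differential peaks first.
#'
#' @param lnc Gene annotation rows for the lncRNAs of interest.
#' @param peaks Peak data.frame (differential peaks).
#' @param window Maximum midpoint distance in bp (default 500 kb).
#' @return data.frame with `lnc_id`, `peak_id`, `midpoint_distance`.
#' @export
pair_lnc_peaks <- function(lnc, peaks, window = 500000) {
  if (!nrow(lnc) || !nrow(peaks))
    return(data.frame(lnc_id = character(0), peak_id = character(0),
                      midpoint_distance = numeric(0)))
  out <- lapply(intersect(unique(lnc$chrom), unique(peaks$chrom)), function(ch) {
    li <- which(lnc$chrom == ch); pi <- which(peaks$chrom == ch)
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(start = lnc$midpoint[li], width = 1L),
      IRanges::IRanges(start = peaks$summit[pi] - window,
                       end = peaks$summit[pi] + window)
    )
    qi <- li[S4Vectors::queryHits(hit)]
    si <- pi[S4Vectors::subjectHits(hit)]
    data.frame(lnc_id = lnc$gene_id[qi], peak_id = peaks$peak_id[si],
               midpoint_distance = abs(lnc$midpoint[qi] - peaks$summit[si]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    return(data.frame(lnc_id = character(0), peak_id = character(0),
                      midpoint_distance = numeric(0)))
  out <- out[order(out$lnc_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: wide log2FC matrix (features x sex_timepoint columns) from a
# de_result-style table restricted to one tissue
.lfc_wide <- function(de, sexes = c("male", "female"), weeks = c(1, 2, 4, 8)) {
  idcol <- if ("gene_id" %in% names(de)) "gene_id" else "feature_id"
  cols <- as.vector(outer(weeks, sexes, function(w, s) paste0(s, "_w", w)))
  ids <- unique(de[[idcol]])
  m <- matrix(NA_real_, length(ids), length(cols), dimnames = list(ids, cols))
  cc <- paste0(de$sex, "_w", de$timepoint_weeks)
  ok <- cc %in% cols
  m[cbind(match(de[[idcol]][ok], ids), match(cc[ok], cols))] <- de$log2fc[ok]
  m
}

#' Correlate lncRNA and peak training trajectories
#'
#' For each pair, computes the Pearson correlation between the lncRNA's and
#' the peak's timewise log2FC values. The default `concat_sexes` mode
#' stacks the male and female timepoints (up to 8 points); `per_sex`
#' correlates within each sex separately (one output row per sex). Pairs
#' with fewer than `min_points` shared finite points, or zero variance in
#' either vector, are dropped (a message reports the count).
#'
#' @param pairs Pair table from [pair_lnc_peaks()].
#' @param lnc_de `de_result`-style table for the lncRNAs (one tissue).
#' @param peak_de `de_result`-style table for the peaks (one tissue).
#' @param mode `"concat_sexes"` or `"per_sex"`.
#' @param min_points Minimum shared points for a correlation.
#' @return `pairs` with columns `r`, `n_points` (and `sex` in `per_sex`
#'   mode) added; dropped pairs removed.
#' @export
correlate_pairs <- function(pairs, lnc_de, peak_de,
                            mode = c("concat_sexes", "per_sex"),
                            min_points = 3) {
  mode <- match.arg(mode)
  lm_ <- .lfc_wide(lnc_de)
  pm_ <- .lfc_wide(peak_de)
  sex_sets <- if (mode == "concat_sexes") list(both = colnames(lm_))
  else list(male = grep("^male_", colnames(lm_), value = TRUE),
            female = grep("^female_", colnames(lm_), value = TRUE))
  out <- list()
  n_dropped <- 0L
  for (sx in names(sex_sets)) {
    cols <- sex_sets[[sx]]
    x <- lm_[pairs$lnc_id, cols, drop = FALSE]
    y <- pm_[pairs$peak_id, cols, drop = FALSE]
    rr <- vapply(seq_len(nrow(pairs)), function(i) {
      ok <- is.finite(x[i, ]) & is.finite(y[i, ])
      if (sum(ok) < min_points) return(c(NA_real_, sum(ok)))
      xi <- x[i, ok]; yi <- y[i, ok]
      if (sd(xi) == 0 || sd(yi) == 0) return(c(NA_real_, sum(ok)))
      c(cor(xi, yi), sum(ok))
    }, numeric(2))
    res <- pairs
    res$sex <- sx
    res$r <- rr[1, ]
    res$n_points <- as.integer(rr[2, ])
    drop <- is.na(res$r)
    n_dropped <- n_dropped + sum(drop)
    out[[sx]] <- res[!drop, , drop = FALSE]
  }
  if (n_dropped > 0)
    message(sprintf("correlate_pairs: dropped %d pair(s) with < %d points or zero variance",
                    n_dropped, min_points))
  out <- do.call(rbind, out)
  if (mode == "concat_sexes") out$sex <- NULL
  rownames(out) <- NULL
  out
}

#' 2D distance-correlation density summary
#'
#' Summarizes the pair landscape as a Gaussian-kernel density on a fixed
#' grid over (signed distance of the peak summit to the lncRNA TSS, r).
#' The signed distance is positive downstream of the TSS in the lncRNA's
#' transcription direction. Bandwidths follow Scott's rule
#' (`sigma * n^(-1/6)` per axis). The grid is renormalized so that
#' `sum(z) * dx * dy = 1`. With fewer than `min_kde` pairs only a 2D
#' histogram is returned.
#'
#' @param pairs Correlated pair table (with `r`).
#' @param lnc Gene annotation rows covering the paired lncRNAs.
#' @param peaks Peak data.frame covering the paired peaks.
#' @param window Distance-axis half-width (bp).
#' @param n_grid Grid points per axis.
#' @param min_kde Minimum pairs for the KDE.
#' @return List with `points` (signed_distance, r), `kde` (list x, y, z or
#'   NULL), `hist` (counts matrix), `nbin` breaks.
#' @export
density_summary <- function(pairs, lnc, peaks, window = 500000, n_grid = 50,
                            min_kde = 10) {
  li <- match(pairs$lnc_id, lnc$gene_id)
  pi <- match(pairs$peak_id, peaks$peak_id)
  d <- peaks$summit[pi] - lnc$tss[li]
  d <- ifelse(lnc$strand[li] == "-", -d, d)
  pts <- data.frame(signed_distance = d, r = pairs$r)
  xb <- seq(-window, window, length.out = n_grid + 1)
  yb <- seq(-1, 1, length.out = n_grid + 1)
  h2 <- table(cut(pts$signed_distance, xb, include.lowest = TRUE),
              cut(pts$r, yb, include.lowest = TRUE))
  kde <- NULL
  if (nrow(pts) >= min_kde) {
    n <- nrow(pts)
    hx <- sd(pts$signed_distance) * n^(-1 / 6)
    hy <- sd(pts$r) * n^(-1 / 6)
    if (hx > 0 && hy > 0) {
      # MASS::kde2d divides the supplied bandwidth by 4 internally
      kk <- MASS::kde2d(pts$signed_distance, pts$r, h = c(4 * hx, 4 * hy),
                        n = n_grid, lims = c(-window, window, -1, 1))
      dx <- diff(kk$x[1:2]); dy <- diff(kk$y[1:2])
      kk$z <- kk$z / (sum(kk$z) * dx * dy)
      kde <- kk
    }
  }
  list(points = pts, kde = kde, hist = unclass(h2),
       x_breaks = xb, y_breaks = yb)
}

#' Assign the nearest protein-coding TSS to each peak
#'
#' Distance is `|summit - TSS|`, minimized over the protein-coding genes on
#' the peak's chromosome (TSS position is strand-aware; the distance is
#' unstranded). Ties are broken by the lexicographically smaller gene id.
#' Peaks on chromosomes without any coding gene are skipped with a warning.
#'
#' @param peaks Peak data.frame.
#' @param ann Gene annotation (protein-coding rows are used).
#' @return data.frame with `peak_id`, `gene_id`, `distance_to_tss`.
#' @export
assign_nearest_tss <- function(peaks, ann) {
  cod <- ann[ann$biotype == "protein_coding", , drop = FALSE]
  out <- lapply(unique(peaks$chrom), function(ch) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    cc <- cod[cod$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) {
      warning(sprintf("no protein-coding gene on %s; %d peak(s) skipped",
                      ch, nrow(pk)), call. = FALSE)
      return(NULL)
    }
    tss <- cc$tss; gid <- cc$gene_id
    res <- vapply(pk$summit, function(s) {
      d <- abs(s - tss)
      j <- which(d == min(d))
      if (length(j) > 1L) j <- j[order(gid[j])][1L]  # tie: smaller gene_id
      c(j, d[j])
    }, numeric(2))
    data.frame(peak_id = pk$peak_id, gene_id = gid[res[1, ]],
               distance_to_tss = res[2, ], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance_to_tss = numeric(0)))
  rownames(out) <- NULL
  out
}

#' Activity score of a lncRNA-peak-gene association
#'
#' `activity_score = r / (distance_to_tss + 1)`: the Pearson correlation of
#' the lncRNA and peak training trajectories, weighted by the inverse of
#' the peak-summit-to-TSS distance plus one base pair. High-correlation,
#' promoter-proximal associations score highest; the sign follows `r`.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param distance_to_tss Non-negative distance in bp.
#' @return Numeric score.
#' @export
activity_score <- function(r, distance_to_tss) {
  if (any(distance_to_tss < 0)) .fail("distance_to_tss must be >= 0")
  if (any(abs(r) > 1, na.rm = TRUE)) .fail("r must lie in [-1, 1]")
  r / (distance_to_tss + 1)
}

#' Build activity-score-ranked lncRNA-peak-gene triads
#'
#' Keeps correlated pairs whose correlation reaches `r_min` (default 0.5,
#' inclusive), attaches each
#' peak's nearest protein-coding gene and scores the triad with
#' [activity_score()]. When multiple triads map to the same gene only the
#' one with the highest activity score is retained (ties: smaller distance,
#' then lexicographic lnc id). The gene's training direction is the sign of
#' its log2FC at its most significant differential timepoint (`"ns"` if the
#' gene is never differential).
#'
#' @param pairs Correlated pair table (with `r`).
#' @param tss Nearest-TSS table from [assign_nearest_tss()].
#' @param de `de_result` data.frame with `is_differential` filled (used for
#'   the gene direction).
#' @param r_min Inclusive correlation threshold.
#' @return Triad data.frame ordered by decreasing activity score:
#'   `lnc_id`, `peak_id`, `gene_id`, `distance_to_tss`, `r`,
#'   `activity_score`, `gene_direction`.
#' @export
build_triads <- function(pairs, tss, de = NULL, r_min = 0.5) {
  tr <- pairs[!is.na(pairs$r) & pairs$r >= r_min, , drop = FALSE]
  tr <- merge(tr, tss, by = "peak_id")
  if (!nrow(tr))
    return(data.frame(lnc_id = character(0), peak_id = character(0),
                      gene_id = character(0), distance_to_tss = numeric(0),
                      r = numeric(0), activity_score = numeric(0),
                      gene_direction = character(0)))
  tr$activity_score <- activity_score(tr$r, tr$distance_to_tss)
  tr <- tr[order(tr$gene_id, -tr$activity_score, tr$distance_to_tss, tr$lnc_id), ]
  tr <- tr[!duplicated(tr$gene_id), , drop = FALSE]
  tr$gene_direction <- "ns"
  if (!is.null(de)) {
    dd <- de[de$is_differential %in% TRUE & de$gene_id %in% tr$gene_id, ]
    if (nrow(dd)) {
      dd <- dd[order(dd$gene_id, dd$p), ]
      top <- dd[!duplicated(dd$gene_id), ]
      hit <- match(tr$gene_id, top$gene_id)
      dir <- ifelse(top$log2fc[hit] > 0, "up", "down")
      tr$gene_direction <- ifelse(is.na(hit), "ns", dir)
    }
  }
  tr <- tr[order(-tr$activity_score, tr$distance_to_tss, tr$lnc_id), ]
  rownames(tr) <- NULL
  tr[c("lnc_id", "peak_id", "gene_id", "distance_to_tss", "r",
       "activity_score", "gene_direction")]
}
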