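#' Z-score trajectory summaries
#'
#' Standardizes each gene's timewise log2 fold-change trajectory within a
#' tissue x sex stratum (`z_t = (lfc_t - mean) / sd` over the gene's
#' available training timepoints; genes with a flat trajectory, sd = 0, get
#' an all-zero profile), then summarizes the differential-lncRNA set per
#' tissue x sex x timepoint by the mean Z-score, together with the week-8
#' minus week-1 change `delta_z_w8_w1`.
#'
#' @param de A `de_result` data.frame.
#' @param delnc Character vector of differential lncRNA gene ids to
#'   summarize over.
#' @return List with `profiles` (gene-level z-profiles) and `summary`
#'   (tissue x sex x timepoint mean Z plus `delta_z_w8_w1`).
#' @export
zscore_trajectories <- function(de, delnc) {
  key <- paste(de$gene_id, de$tissue, de$sex)
  zvec <- numeric(nrow(de))
  for (idx in split(seq_len(nrow(de)), key)) {
    v <- de$log2fc[idx]
    s <- if (length(v) < 2L) 0 else sd(v)
    zvec[idx] <- if (s == 0) 0 else (v - mean(v)) / s
  }
  prof <- de[c("gene_id", "tissue", "sex", "timepoint_weeks")]
  prof$z <- zvec
  sel <- prof$gene_id %in% delnc
  if (!any(sel)) {
    summ <- data.frame(tissue = character(0), sex = character(0),
                       timepoint_weeks = numeric(0), mean_z = numeric(0),
                       delta_z_w8_w1 = numeric(0))
    return(list(profiles = prof, summary = summ))
  }
  sub <- prof[sel, ]
  agg <- stats::aggregate(z ~ tissue + sex + timepoint_weeks, data = sub, FUN = mean)
  names(agg)[names(agg) == "z"] <- "mean_z"
  agg <- agg[order(agg$tissue, agg$sex, agg$timepoint_weeks), ]
  delta <- by(agg, paste(agg$tissue, agg$sex), function(d) {
    w8 <- d$mean_z[d$timepoint_weeks == 8]
    w1 <- d$mean_z[d$timepoint_weeks == 1]
    if (length(w8) == 1L && length(w1) == 1L) w8 - w1 else NA_real_
  })
  agg$delta_z_w8_w1 <- as.numeric(delta[paste(agg$tissue, agg$sex)])
  rownames(agg) <- NULL
  list(profiles = prof, summary = agg)
}

#' Classify the sex specificity of differential genes
#'
#' Partitions each gene differential in a tissue into mutually exclusive
#' classes: `male_only` / `female_only` when flagged in exactly one sex;
#' among both-sex genes, `shared_opposing` if any common differential
#' timepoint has opposite log2FC signs, otherwise `shared_concordant` if at
#' least one common differential timepoint exists, and
#' `shared_disjoint_timepoints` when the two sexes' differential timepoint
#' sets are disjoint.
#'
#' @param de A `de_result` data.frame with `is_differential` filled in
#'   (see [call_delnc()]).
#' @return data.frame with `gene_id`, `tissue`, `class`.
#' @export
classify_sex_patterns <- function(de) {
  if (all(is.na(de$is_differential)))
    .fail("run call_delnc() before classify_sex_patterns()")
  dd <- de[de$is_differential %in% TRUE, ]
  if (!nrow(dd))
    return(data.frame(gene_id = character(0), tissue = character(0),
                      class = character(0)))
  out <- lapply(split(dd, paste(dd$gene_id, dd$tissue, sep = "\r")), function(d) {
    sexes <- unique(d$sex)
    cls <- if (identical(sexes, "male")) "male_only"
    else if (identical(sexes, "female")) "female_only"
    else {
      tm <- d$timepoint_weeks[d$sex == "male"]
      tf <- d$timepoint_weeks[d$sex == "female"]
      common <- intersect(tm, tf)
      if (!length(common)) "shared_disjoint_timepoints"
      else {
        opposing <- any(vapply(common, function(tp) {
          sm <- sign(d$log2fc[d$sex == "male" & d$timepoint_weeks == tp])
          sf <- sign(d$log2fc[d$sex == "female" & d$timepoint_weeks == tp])
          any(outer(sm, sf, "*") < 0)
        }, logical(1)))
        if (opposing) "shared_opposing" else "shared_concordant"
      }
    }
    data.frame(gene_id = d$gene_id[1], tissue = d$tissue[1], class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$tissue, out$gene_id), , drop = FALSE]
}

#' Prepare standardized temporal profiles for clustering
#'
#' Builds a gene x training-timepoint matrix (weeks 1, 2, 4, 8), drops
#' genes observed at fewer than `min_timepoints` timepoints, fills the
#' remaining missing values by linear interpolation on the week axis (flat
#' extrapolation at the boundaries), and standardizes each row to mean 0,
#' sd 1. Rows with zero variance after interpolation are dropped.
#'
#' @param x Either a numeric matrix (genes x timepoints, columns named by
#'   week) possibly containing NAs, or a `de_result` data.frame for one
#'   tissue x sex (log2FC profiles are used).
#' @param min_timepoints Minimum observed timepoints to retain a gene.
#' @param weeks Training week axis.
#' @return Standardized numeric matrix (genes x weeks).
#' @export
prepare_profiles <- function(x, min_timepoints = 3, weeks = c(1, 2, 4, 8)) {
  if (is.data.frame(x)) {
    m <- matrix(NA_real_, nrow = length(unique(x$gene_id)), ncol = length(weeks),
                dimnames = list(unique(x$gene_id), as.character(weeks)))
    idx <- cbind(match(x$gene_id, rownames(m)),
                 match(as.character(x$timepoint_weeks), colnames(m)))
    ok <- !is.na(idx[, 2])
    m[idx[ok, , drop = FALSE]] <- x$log2fc[ok]
  } else {
    m <- as.matrix(x)
    colnames(m) <- colnames(m) %||% as.character(weeks)
  }
  wk <- as.numeric(colnames(m))
  keep <- rowSums(!is.na(m)) >= min_timepoints
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) .fail("all genes dropped by the <%d-timepoint filter", min_timepoints)
  for (i in seq_len(nrow(m))) {
    if (anyNA(m[i, ])) {
      obs <- !is.na(m[i, ])
      m[i, ] <- approx(wk[obs], m[i, obs], xout = wk, rule = 2)$y
    }
  }
  sds <- apply(m, 1, sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sprintf("dropping %d flat profile(s)", sum(flat)), call. = FALSE)
    m <- m[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  if (!nrow(m)) .fail("all profiles flat after interpolation")
  (m - rowMeans(m)) / sds
}

#' Fuzzy c-means temporal clustering
#'
#' Soft clustering of standardized temporal profiles with the standard
#' fuzzy c-means algorithm on Euclidean distance: memberships
#' `u_ij` proportional to `(1 / d_ij^2)^(1 / (m - 1))` normalized per gene
#' (a profile coinciding with a center gets membership 1 there), centers as
#' `u^m`-weighted means, iterated until the objective `sum(u^m d^2)` changes
#' by less than `tol`. Core members are genes with membership >= 0.5 in a
#' cluster.
#'
#' @param profiles Standardized profile matrix (genes x timepoints), e.g.
#'   from [prepare_profiles()].
#' @param n_clusters Number of clusters (default 6).
#' @param m Fuzzifier, > 1 (default 1.25).
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap.
#' @param seed Seed for center initialization.
#' @return A `fuzzy_cmeans` list: `centers`, `memberships`, `objective`
#'   (per-iteration trace), `core_members`, `n_clusters`, `m`.
#' @export
fuzzy_cmeans <- function(profiles, n_clusters = 6, m = 1.25, tol = 1e-6,
                         max_iter = 500, seed = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < n_clusters) .fail("need at least n_clusters genes")
  if (m <= 1) .fail("fuzzifier m must be > 1")
  set.seed(seed)
  centers <- profiles[sample.int(nrow(profiles), n_clusters), , drop = FALSE]
  obj <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(profiles^2), rep(1, n_clusters)) -
      2 * profiles %*% t(centers) +
      outer(rep(1, nrow(profiles)), rowSums(centers^2))
    d2[d2 < 0] <- 0
    u <- matrix(0, nrow(profiles), n_clusters)
    zero <- d2 <= .Machine$double.eps
    hard <- rowSums(zero) > 0
    if (any(hard)) {
      u[hard, ] <- zero[hard, , drop = FALSE] / rowSums(zero[hard, , drop = FALSE])
    }
    if (any(!hard)) {
      w <- (1 / d2[!hard, , drop = FALSE])^(1 / (m - 1))
      u[!hard, ] <- w / rowSums(w)
    }
    obj <- c(obj, sum(u^m * d2))
    um <- u^m
    centers_new <- t(um) %*% profiles / colSums(um)
    if (it > 1 && abs(obj[it] - obj[it - 1]) < tol) { centers <- centers_new; break }
    centers <- centers_new
  }
  rownames(centers) <- paste0("cluster_", seq_len(n_clusters))
  colnames(centers) <- colnames(profiles)
  dimnames(u) <- list(rownames(profiles), rownames(centers))
  core <- apply(u, 2, function(col) rownames(u)[col >= 0.5], simplify = FALSE)
  structure(list(centers = centers, memberships = u, objective = obj,
                 core_members = core, n_clusters = n_clusters, m = m),
            class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("fuzzy c-means model: %d clusters, m = %.3g, %d profiles, %d iterations\n",
              x$n_clusters, x$m, nrow(x$memberships), length(x$objective)))
  cat(sprintf("core members (membership >= 0.5) per cluster: %s\n",
              paste(vapply(x$core_members, length, integer(1)), collapse = ", ")))
  invisible(x)
}
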