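toy_peaks <- function(summits, chrom = "chr1") {
  data.frame(peak_id = sprintf("p%02d", seq_along(summits)), chrom = chrom,
             start = summits - 250L, end = summits + 250L,
             summit = as.integer(summits), stringsAsFactors = FALSE)
}

toy_ann <- function(gene_id, tss, biotype, chrom = "chr1", strand = "+") {
  start <- ifelse(strand == "+", tss, tss - 999L)
  end <- ifelse(strand == "+", tss + 1000L, tss + 1L)
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, biotype = biotype,
             midpoint = as.integer(floor((start + end) / 2)), tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

test_that("peak trimming recenters on the summit at fixed width", {
  pk <- trim_peaks(toy_peaks(1000L))
  expect_equal(pk$start, 900L)
  expect_equal(pk$end, 1100L)
  expect_equal(pk$summit, 1000L)
  # near the chromosome start the window shifts, width preserved
  edge <- trim_peaks(toy_peaks(50L), chrom_lengths = c(chr1 = 10000))
  expect_equal(edge$start, 0L)
  expect_equal(edge$end, 200L)
  many <- trim_peaks(toy_peaks(c(500L, 5000L, 9990L)),
                     chrom_lengths = c(chr1 = 10000))
  expect_true(all(many$end - many$start == 200L))
  expect_error(trim_peaks(toy_peaks(50L), chrom_lengths = c(chr1 = 150)),
               "shorter")
})

test_that("peak support filter uses inclusive thresholds and chromosome policy", {
  cnt <- rbind(
    keep = c(10, 10, 10, 10, 0),   # 10 reads in exactly 4 samples
    drop = c(9, 9, 9, 9, 9),       # never reaches 10
    scaffold = c(50, 50, 50, 50, 50)
  )
  colnames(cnt) <- paste0("s", 1:5)
  pk <- data.frame(peak_id = rownames(cnt), chrom = c("chr1", "chr1", "scaf_7"))
  kept <- filter_peaks(cnt, peaks = pk, chroms_allowed = c("chr1", "chr2"))
  expect_equal(kept, "keep")
})

test_that("pairing respects the 500-kb boundary exactly and per chromosome", {
  lnc <- toy_ann("lnc1", 0L, "lncRNA")
  lnc$midpoint <- 1000000L
  peaks <- toy_peaks(c(1500000L, 1500001L, 1000000L))
  pairs <- pair_lnc_peaks(lnc, peaks, window = 500000)
  expect_setequal(pairs$peak_id, c("p01", "p03"))  # 500000 in, 500001 out
  expect_equal(pairs$midpoint_distance[pairs$peak_id == "p01"], 500000)
  # same coordinates on another chromosome never pair
  peaks2 <- toy_peaks(1000000L, chrom = "chr2")
  expect_equal(nrow(pair_lnc_peaks(lnc, peaks2)), 0L)
})

test_that("pairing is preserved under a coordinate mirror transform", {
  set.seed(31)
  L <- 10000000L
  lnc <- toy_ann(paste0("l", 1:5), sort(sample.int(L, 5)), "lncRNA")
  peaks <- toy_peaks(sort(sample.int(L, 20)))
  fwd <- pair_lnc_peaks(lnc, peaks)
  lnc_m <- lnc; lnc_m$midpoint <- L - lnc$midpoint
  peaks_m <- peaks; peaks_m$summit <- L - peaks$summit
  mir <- pair_lnc_peaks(lnc_m, peaks_m)
  key <- function(d) sort(paste(d$lnc_id, d$peak_id, d$midpoint_distance))
  expect_equal(key(mir), key(fwd))
})

lfc_table <- function(id, vals, what = "gene_id") {
  grid <- expand.grid(timepoint_weeks = c(1, 2, 4, 8),
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  out <- data.frame(id = id, tissue = "liver", sex = grid$sex,
                    timepoint_weeks = grid$timepoint_weeks, log2fc = vals,
                    p = 0.5, stringsAsFactors = FALSE)
  names(out)[1] <- what
  out
}

test_that("trajectory correlation hits the exact endpoints", {
  v <- c(1, -2, 3, 0.5, -1, 2, 0, 1.5)
  pairs <- data.frame(lnc_id = "l1", peak_id = c("p1", "p2"),
                      midpoint_distance = c(100, 200))
  lnc_de <- lfc_table("l1", v)
  peak_de <- rbind(lfc_table("p1", v, "feature_id"),
                   lfc_table("p2", -v, "feature_id"))
  cp <- correlate_pairs(pairs, lnc_de, peak_de)
  expect_equal(cp$r[cp$peak_id == "p1"], 1)
  expect_equal(cp$r[cp$peak_id == "p2"], -1)
  expect_equal(cp$n_points, c(8L, 8L))
  # zero-variance members are excluded with a message
  peak_flat <- lfc_table("p1", rep(2, 8), "feature_id")
  expect_message(cp2 <- correlate_pairs(pairs[1, ], lnc_de, peak_flat),
                 "dropped")
  expect_equal(nrow(cp2), 0L)
  # per-sex mode returns one row per sex
  cps <- correlate_pairs(pairs[1, ], lnc_de, peak_de[peak_de$feature_id == "p1", ],
                         mode = "per_sex", min_points = 3)
  expect_setequal(cps$sex, c("male", "female"))
  expect_equal(cps$r, c(1, 1))
})

test_that("nearest-TSS assignment matches brute force and breaks ties by id", {
  ann <- toy_ann(c("gB", "gA"), c(5000L, 7000L), "protein_coding")
  hit <- assign_nearest_tss(toy_peaks(5000L), ann)
  expect_equal(hit$gene_id, "gB")
  expect_equal(hit$distance_to_tss, 0)
  tie <- assign_nearest_tss(toy_peaks(6000L), ann)
  expect_equal(tie$gene_id, "gA")  # equidistant: lexicographically smaller id
  set.seed(32)
  for (i in 1:50) {
    ann_r <- toy_ann(sprintf("g%03d", sample(900, 8)),
                     sample.int(1000000L, 8), "protein_coding")
    summits <- sample.int(1000000L, 6)
    got <- assign_nearest_tss(toy_peaks(summits), ann_r)
    for (j in seq_along(summits)) {
      bf <- bf_nearest_tss(summits[j], "chr1", ann_r)
      expect_equal(got$gene_id[j], bf$gene_id)
      expect_equal(got$distance_to_tss[j], bf$distance)
    }
  }
  lone <- toy_ann("g1", 100L, "protein_coding", chrom = "chr9")
  expect_warning(out <- assign_nearest_tss(toy_peaks(500L), lone),
                 "no protein-coding")
  expect_equal(nrow(out), 0L)
})

test_that("activity score formula and monotonicity", {
  expect_equal(activity_score(1, 0), 1.0)
  expect_equal(activity_score(0.8, 999), 0.0008)
  expect_lt(activity_score(-0.5, 12345), 0)
  d <- c(0, 10, 100, 1e4, 1e6)
  expect_true(all(diff(activity_score(0.7, d)) < 0))
  r <- c(-1, -0.2, 0.3, 0.9)
  expect_true(all(diff(activity_score(r, 50)) > 0))
  expect_error(activity_score(0.5, -1), ">= 0")
  expect_error(activity_score(1.5, 10), "-1, 1")
})

test_that("triads apply the r threshold and per-gene max-score dedup", {
  pairs <- data.frame(
    lnc_id = c("l1", "l2", "l3", "l4"),
    peak_id = c("p1", "p2", "p3", "p4"),
    midpoint_distance = 1000,
    r = c(0.49, 0.6, 0.9, 0.8), n_points = 8L)
  tss <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("gX", "gY", "gY", "gZ"),
                    distance_to_tss = c(10, 50, 800, 0))
  tri <- build_triads(pairs, tss)
  expect_false("l1" %in% tri$lnc_id)              # r = 0.49 excluded
  gy <- tri[tri$gene_id == "gY", ]
  expect_equal(gy$lnc_id, "l2")                   # 0.6/51 > 0.9/801
  expect_equal(tri$activity_score, sort(tri$activity_score, decreasing = TRUE))
  # gene direction from the most significant differential timepoint
  de <- data.frame(gene_id = c("gY", "gY", "gZ"), tissue = "liver",
                   sex = "male", timepoint_weeks = c(1, 4, 2),
                   log2fc = c(2, -3, -1.2), p = c(0.001, 0.04, 0.002),
                   adj_p = NA, is_differential = c(TRUE, TRUE, TRUE))
  tri2 <- build_triads(pairs, tss, de)
  expect_equal(tri2$gene_direction[tri2$gene_id == "gY"], "up")
  expect_equal(tri2$gene_direction[tri2$gene_id == "gZ"], "down")
})

test_that("density summary integrates to one and finds the mass", {
  set.seed(33)
  lnc <- toy_ann("l1", 1000000L, "lncRNA")
  peaks <- toy_peaks(1000000L + as.integer(rnorm(60, 2000, 30000)))
  pairs <- data.frame(lnc_id = "l1", peak_id = peaks$peak_id,
                      midpoint_distance = abs(peaks$summit - 1000000L),
                      r = pmin(pmax(rnorm(60, 0.5, 0.2), -1), 1))
  ds <- density_summary(pairs, lnc, peaks)
  expect_false(is.null(ds$kde))
  dx <- diff(ds$kde$x[1:2]); dy <- diff(ds$kde$y[1:2])
  expect_equal(sum(ds$kde$z) * dx * dy, 1, tolerance = 1e-6)
  # histogram-only mode below the KDE floor
  ds2 <- density_summary(pairs[1:5, ], lnc, peaks[1:5, ])
  expect_null(ds2$kde)
  expect_equal(sum(ds2$hist), 5)
})
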