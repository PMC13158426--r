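test_that("Fisher combination closed forms hold", {
  # all-ones: no evidence at all
  f0 <- fisher_combine(c(1, 1))
  expect_equal(f0$stat, 0)
  expect_equal(f0$meta_p, 1)
  # df = 4 closed form: meta_p = exp(-s/2) * (1 + s/2)
  f1 <- fisher_combine(c(0.5, 0.5))
  expect_equal(f1$stat, -2 * (log(0.5) + log(0.5)), tolerance = 1e-12)
  expect_equal(f1$stat, 2.77258872, tolerance = 1e-6)
  expect_equal(f1$meta_p, exp(-f1$stat / 2) * (1 + f1$stat / 2), tolerance = 1e-12)
  # single p: chi-square with 2 df identity returns the same p
  for (p in c(0.9, 0.05, 1e-8))
    expect_equal(fisher_combine(p)$meta_p, p, tolerance = 1e-12)
  # zero p is clamped, not fatal
  expect_warning(fz <- fisher_combine(c(0, 0.5)), "clamped")
  expect_lt(fz$meta_p, 1e-100)
})

test_that("Fisher combination of uniform p-values yields uniform meta p", {
  set.seed(1)
  pm <- matrix(runif(2e4), ncol = 2)
  meta <- lnclink:::.fisher_combine_rows(pm)$meta_p
  ks <- ks.test(meta, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.2, 0.2, 0.2)
  expect_equal(bh_adjust(p), p)
  set.seed(2)
  p2 <- runif(50)
  expect_true(all(bh_adjust(p2) >= p2))
})

test_that("grouped BH reduces to plain BH with one group and upweights signal", {
  set.seed(3)
  p <- runif(200)
  expect_identical(grouped_bh(p, rep("a", 200)), bh_adjust(p))

  # one null group, one signal-loaded group
  p_null <- runif(300)
  p_sig <- rbeta(300, 0.1, 1)
  pp <- c(p_null, p_sig)
  gg <- rep(c("null", "signal"), each = 300)
  # direct Storey estimate of the signal fraction drives the weight
  pi0_sig <- min(1, mean(p_sig > 0.5) / 0.5)
  pi0_null <- min(1, mean(p_null > 0.5) / 0.5)
  w_raw <- c(1 - pi0_null, 1 - pi0_sig)
  expect_gt(w_raw[2], w_raw[1])
  adj <- grouped_bh(pp, gg)
  n_weighted <- sum(adj[gg == "signal"] <= 0.05)
  n_plain <- sum(bh_adjust(pp)[gg == "signal"] <= 0.05)
  expect_gte(n_weighted, n_plain)
})

test_that("weighted BH rejects at least as much as plain BH on mixtures", {
  set.seed(4)
  extra <- vapply(1:20, function(i) {
    p <- c(runif(200), rbeta(100, 0.15, 1))
    g <- rep(c("flat", "loaded"), c(200, 100))
    sum(grouped_bh(p, g) <= 0.05) - sum(bh_adjust(p) <= 0.05)
  }, numeric(1))
  expect_gte(mean(extra), 0)
})

test_that("small covariate groups fall back to weight 1 with a warning", {
  set.seed(5)
  p <- runif(60)
  g <- rep(c("big", "tiny"), c(55, 5))
  expect_warning(adj <- grouped_bh(p, g), "weight 1")
  expect_length(adj, 60)
})

test_that("one-way F-test matches textbook values and the t-test identity", {
  # fixed toy: one group shifted far away
  x <- c(1.1, 0.9, 1.0, 5.1, 4.9, 5.0)
  g <- rep(c("w0", "w8"), each = 3)
  p <- ftest_any_timepoint(x, g)
  ref <- stats::oneway.test(x ~ factor(g), var.equal = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-12)
  expect_lt(p, 1e-4)
  # F = t^2 for two groups
  tt <- t.test(x[g == "w0"], x[g == "w8"], var.equal = TRUE)
  expect_equal(p, tt$p.value, tolerance = 1e-12)
  # five timepoint groups, vectorized over a matrix
  set.seed(6)
  m <- matrix(rnorm(100 * 25), 100, 25)
  g5 <- rep(c(0, 1, 2, 4, 8), each = 5)
  pv <- ftest_any_timepoint(m, g5)
  ref3 <- stats::oneway.test(m[37, ] ~ factor(g5), var.equal = TRUE)$p.value
  expect_equal(pv[37], ref3, tolerance = 1e-12)
})

test_that("null F-test p-values are uniform", {
  set.seed(7)
  m <- matrix(rnorm(2000 * 25), 2000, 25)
  g <- rep(c(0, 1, 2, 4, 8), each = 5)
  pv <- ftest_any_timepoint(m, g)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("differential calling applies inclusive thresholds exactly", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d"), tissue = "liver", sex = "male",
    timepoint_weeks = 1,
    log2fc = c(1.0, 0.99, -1.2, 3.0),
    p = c(0.01, 0.009, 0.005, 0.5))
  called <- call_delnc(de)
  expect_equal(called$is_differential, c(TRUE, FALSE, TRUE, FALSE))
  # brute-force row scan equivalence on a simulated table
  sim <- simulate_experiment(sim_config(seed = 2, n_tissues = 1, n_genes = 200,
                                        n_planted_triads = 0, n_decoy_peaks = 0))
  de2 <- call_delnc(de_timewise(sim$rna_counts, sim$rna_meta))
  bf <- de2$p <= 0.01 & abs(de2$log2fc) >= 1
  expect_identical(de2$is_differential, bf)
  # stringent mode: BH within tissue at 10% with |lfc| >= 0.5
  st <- call_delnc(de2, mode = "stringent")
  bf2 <- ave(st$p, st$tissue, FUN = function(p) p.adjust(p, "BH")) <= 0.10 &
    abs(st$log2fc) >= 0.5
  expect_identical(st$is_differential, bf2)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:4), other = paste0("g", 7:9))
  query <- paste0("g", 1:4)
  res <- hypergeom_enrich(query, universe, sets)
  expect_equal(res$set_id[1], "hit")
  expect_lt(res$p[1], res$p[2])
  k <- res$overlap[res$set_id == "hit"]
  expect_equal(res$p[res$set_id == "hit"],
               bf_hyper_tail(k, 4, 10, 4), tolerance = 1e-12)
  # disjoint query: upper tail from overlap 0 is exactly 1
  res2 <- hypergeom_enrich(paste0("g", 1:3), universe, list(s = paste0("g", 8:10)))
  expect_equal(res2$p, 1)
  expect_error(hypergeom_enrich("g1", character(0), sets), "empty universe")
  # larger random draw against the closed form
  set.seed(8)
  uni <- paste0("x", 1:200)
  st <- list(s1 = sample(uni, 30))
  q <- sample(uni, 25)
  r3 <- hypergeom_enrich(q, uni, st)
  expect_equal(r3$p, bf_hyper_tail(r3$overlap, 30, 200, 25), tolerance = 1e-10)
})
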