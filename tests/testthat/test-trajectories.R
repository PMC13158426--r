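de_row <- function(gene, sex, tp, lfc, p = 0.001, tissue = "muscle", diff = TRUE) {
  data.frame(gene_id = gene, tissue = tissue, sex = sex, timepoint_weeks = tp,
             log2fc = lfc, p = p, adj_p = p, is_differential = diff,
             stringsAsFactors = FALSE)
}

test_that("z-profiles match the hand computation and center to zero", {
  de <- de_row("g1", "male", c(1, 2, 4, 8), c(-1, 0, 0, 1))
  out <- zscore_trajectories(de, "g1")
  z <- out$profiles$z
  expect_equal(z, c(-1.22474487, 0, 0, 1.22474487), tolerance = 1e-8)
  expect_equal(mean(z), 0)
  summ <- out$summary
  expect_equal(summ$mean_z, z[order(summ$timepoint_weeks)])
  expect_equal(unique(summ$delta_z_w8_w1), 2.44948975, tolerance = 1e-8)
})

test_that("flat trajectories get an all-zero z-profile", {
  de <- de_row("g1", "male", c(1, 2, 4, 8), rep(0.7, 4))
  out <- zscore_trajectories(de, "g1")
  expect_equal(out$profiles$z, rep(0, 4))
})

test_that("z summaries are invariant to gene order", {
  de <- rbind(de_row("g1", "male", c(1, 2, 4, 8), c(0, 1, 2, 3)),
              de_row("g2", "male", c(1, 2, 4, 8), c(3, 1, 0, 2)))
  a <- zscore_trajectories(de, c("g1", "g2"))$summary
  b <- zscore_trajectories(de[sample(nrow(de)), ], c("g2", "g1"))$summary
  expect_equal(a, b)
})

test_that("sex-pattern truth table classifies all five classes exactly", {
  de <- rbind(
    de_row("m_only", "male", 2, 2),
    de_row("f_only", "female", 4, -1.5),
    de_row("conc", "male", 4, 2), de_row("conc", "female", 4, 1.8),
    de_row("oppo", "male", 4, 2), de_row("oppo", "female", 4, -2),
    de_row("disj", "male", 1, 2), de_row("disj", "female", 8, 2)
  )
  got <- classify_sex_patterns(de)
  expected <- c(conc = "shared_concordant", disj = "shared_disjoint_timepoints",
                f_only = "female_only", m_only = "male_only",
                oppo = "shared_opposing")
  expect_equal(setNames(got$class, got$gene_id), expected)
})

test_that("sex classification is symmetric under a sex-label swap", {
  de <- rbind(
    de_row("a", "male", 2, 2),
    de_row("b", "male", 4, 2), de_row("b", "female", 4, -2),
    de_row("c", "female", 1, 1.2)
  )
  swap <- de
  swap$sex <- ifelse(de$sex == "male", "female", "male")
  a <- classify_sex_patterns(de)
  b <- classify_sex_patterns(swap)
  flip <- c(male_only = "female_only", female_only = "male_only",
            shared_concordant = "shared_concordant",
            shared_opposing = "shared_opposing",
            shared_disjoint_timepoints = "shared_disjoint_timepoints")
  expect_equal(b$class, unname(flip[a$class]))
})

test_that("profile preparation excludes, interpolates and standardizes", {
  m <- rbind(
    two_pts = c(0, NA, 2, NA),       # < 3 timepoints: dropped
    interp = c(0, NA, 2, 4),         # w2 filled on the week axis
    full = c(1, 2, 3, 4)
  )
  colnames(m) <- c("1", "2", "4", "8")
  prof <- prepare_profiles(m)
  expect_false("two_pts" %in% rownames(prof))
  # linear interpolation at week 2 between (w1, 0) and (w4, 2): 2/3
  raw_interp <- approx(c(1, 4, 8), c(0, 2, 4), xout = c(1, 2, 4, 8), rule = 2)$y
  expect_equal(raw_interp[2], 2 / 3)
  expect_equal(prof["interp", ], (raw_interp - mean(raw_interp)) / sd(raw_interp),
               ignore_attr = TRUE)
  # standardized rows: mean 0, sd 1
  expect_equal(unname(rowMeans(prof)), rep(0, nrow(prof)), tolerance = 1e-9)
  expect_equal(unname(apply(prof, 1, sd)), rep(1, nrow(prof)), tolerance = 1e-9)
  expect_error(prepare_profiles(m[1, , drop = FALSE]), "dropped")
})

make_two_patterns <- function(n_per = 40, seed = 9, noise = 0.4) {
  set.seed(seed)
  up <- t(replicate(n_per, c(-1.5, -0.5, 0.5, 1.5) + rnorm(4, sd = noise)))
  down <- t(replicate(n_per, c(1.5, 0.5, -0.5, -1.5) + rnorm(4, sd = noise)))
  m <- rbind(up, down)
  dimnames(m) <- list(paste0("g", seq_len(2 * n_per)), c("1", "2", "4", "8"))
  list(profiles = prepare_profiles(m), truth = rep(c("up", "down"), each = n_per))
}

test_that("fuzzy c-means memberships, objective and recovery behave", {
  tp <- make_two_patterns()
  cm <- fuzzy_cmeans(tp$profiles, n_clusters = 2, seed = 1)
  expect_equal(unname(rowSums(cm$memberships)), rep(1, nrow(tp$profiles)),
               tolerance = 1e-9)
  expect_true(all(diff(cm$objective) <= 1e-9))
  hard <- colnames(cm$memberships)[max.col(cm$memberships, "first")]
  expect_gte(rand_ari(hard, tp$truth), 0.9)
})

test_that("an exact-center profile gets membership one there", {
  m <- rbind(a = c(-1, 0, 0, 1), b = c(1, 0, 0, -1))
  prof <- prepare_profiles(rbind(m, m, m + 1e-9))
  cm <- fuzzy_cmeans(prof, n_clusters = 2, seed = 2, max_iter = 5)
  expect_true(all(abs(rowSums(cm$memberships) - 1) < 1e-9))
})

test_that("small fuzzifier approaches hard assignments on separated data", {
  tp <- make_two_patterns(noise = 0.1)
  cm <- fuzzy_cmeans(tp$profiles, n_clusters = 2, m = 1.05, seed = 3)
  expect_gt(min(apply(cm$memberships, 1, max)), 0.95)
})

test_that("converged centers agree with the e1071 reference on a clean toy", {
  skip_if_not_installed("e1071")
  tp <- make_two_patterns(noise = 0.2)
  cm <- fuzzy_cmeans(tp$profiles, n_clusters = 2, m = 1.25, seed = 4)
  ref <- e1071::cmeans(tp$profiles, centers = 2, m = 1.25, iter.max = 500)
  # align clusters by nearest center before comparing
  d <- as.matrix(dist(rbind(cm$centers, ref$centers)))[1:2, 3:4]
  perm <- apply(d, 1, which.min)
  expect_true(all(perm == c(1, 2) | perm == c(2, 1)))
  expect_lt(max(abs(cm$centers - ref$centers[perm, ])), 0.05)
})
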