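test_that("binned means agree with a brute-force per-bin recomputation", {
  set.seed(20)
  n <- 20000
  a <- runif(n, -200, 400)
  b <- a + rnorm(n, 2, 10)
  pairs <- paired_voxels(a, b, "HU")
  tab <- binned_means(pairs, min_bin_count = 100)
  # independent oracle: explicit split by bin index
  idx <- floor((a + 1024) / 10)
  for (i in seq_along(tab$bin_lower)) {
    k <- (tab$bin_lower[i] + 1024) / 10
    sel <- idx == k
    expect_equal(tab$counts[i], sum(sel))
    expect_equal(tab$mean_a[i], mean(a[sel]), tolerance = 1e-12)
    expect_equal(tab$mean_b[i], mean(b[sel]), tolerance = 1e-12)
  }
  # no retained bin below the count threshold; dropped bins stay dropped
  expect_true(all(tab$counts >= 100))
  kept <- as.numeric(names(which(table(idx) >= 100)))
  expect_setequal((tab$bin_lower + 1024) / 10, kept)
})

test_that("binned means reproduce identical images and constant offsets", {
  set.seed(21)
  a <- runif(2000, 0, 50)
  tab_same <- binned_means(paired_voxels(a, a, "HU"), min_bin_count = 10)
  expect_equal(tab_same$mean_a, tab_same$mean_b)
  tab_off <- binned_means(paired_voxels(a, a + 5, "HU"), min_bin_count = 10)
  expect_equal(tab_off$mean_b - tab_off$mean_a, rep(5, length(tab_off$counts)))
  expect_error(binned_means(paired_voxels(a, a, "HU"), min_bin_count = 1e6),
               "no bins")
})

test_that("absolute errors are elementwise |mean_a - mean_b|, sorted", {
  tab <- structure(list(bin_lower = c(0, 10), counts = c(100, 100),
                        mean_a = c(10, 50), mean_b = c(12, 47),
                        value_space = "HU", bin_width = 10),
                   class = "bin_table")
  ae <- absolute_errors(tab)
  expect_equal(ae$values, c(2, 3))
  # random tables against a brute-force oracle
  set.seed(22)
  for (i in 1:20) {
    m <- length(ma <- rnorm(sample(1:30, 1)))
    mb <- rnorm(m)
    t2 <- structure(list(bin_lower = seq_len(m), counts = rep(100, m),
                         mean_a = ma, mean_b = mb, value_space = "HU",
                         bin_width = 10), class = "bin_table")
    expect_equal(absolute_errors(t2)$values, sort(abs(ma - mb)))
  }
})

test_that("MeAE matches the worked cases and a textbook median oracle", {
  expect_equal(meae(c(1, 2, 3)), 2)
  expect_equal(meae(c(1, 2, 3, 4)), 2.5)
  set.seed(23)
  for (i in 1:1000) {
    v <- abs(rnorm(sample(1:50, 1), sd = 10))
    expect_equal(meae(v), median(v))
  }
  expect_error(meae(numeric(0)), "empty")
})

test_that("MeAE is order-invariant, scales linearly and is bounded", {
  set.seed(24)
  v <- abs(rcauchy(31))
  expect_equal(meae(sample(v)), meae(v))
  expect_equal(meae(3.7 * v), 3.7 * meae(v))
  expect_lte(meae(v), max(v))
  expect_gte(meae(v), min(v))
})

test_that("MAE is the plain voxel-weighted mean absolute difference", {
  a <- c(1, 2, 3)
  expect_equal(mae(paired_voxels(a, a)), 0)
  expect_equal(mae(paired_voxels(a, a + 5)), 5)
  set.seed(25)
  x <- rnorm(1000)
  y <- rnorm(1000)
  expect_equal(mae(paired_voxels(x, y)), sum(abs(x - y)) / 1000,
               tolerance = 1e-9)
  expect_error(mae(paired_voxels(numeric(0), numeric(0))), "empty")
})

test_that("normality test flags heavy tails and honours its domain", {
  set.seed(26)
  rejections <- vapply(1:40, function(i) {
    test_normality(abs(rcauchy(500))) < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
  # approximately uniform p-values under the Gaussian null
  ps <- vapply(1:200, function(i) test_normality(rnorm(100)), 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(test_normality(c(1, 2)), "3 <= n")
  expect_error(test_normality(rep(1, 10)), "degenerate")
})

test_that("rank-sum comparison detects separation and respects the null", {
  expect_gte(compare_ae_distributions(1:20, 1:20), 0.99)
  expect_lt(compare_ae_distributions(1:20, 101:120), 0.001)
  # exact two-sided p for complete separation at n = m = 3 is 2/choose(6,3)
  expect_equal(compare_ae_distributions(c(1, 2, 3), c(10, 20, 30)), 0.1)
})

test_that("duplicating a bin's pairs moves MAE but not MeAE", {
  set.seed(27)
  a <- runif(3000, 0, 50)
  b <- a + ifelse(a < 10, 20, 2) + rnorm(3000, 0, 0.5)
  pairs <- paired_voxels(a, b, "HU")
  tab <- binned_means(pairs, min_bin_count = 50)
  ae <- absolute_errors(tab)
  m0 <- meae(ae)
  mae0 <- mae(pairs)
  # duplicate every pair of the first retained bin (the high-error one)
  sel <- a >= tab$bin_lower[1] & a < tab$bin_lower[1] + 10
  pairs_dup <- paired_voxels(c(a, a[sel]), c(b, b[sel]), "HU")
  tab_dup <- binned_means(pairs_dup, min_bin_count = 50)
  m1 <- meae(absolute_errors(tab_dup))
  mae1 <- mae(pairs_dup)
  expect_lt(abs(m1 - m0), 1e-12)
  bin_err <- abs(tab$mean_a[1] - tab$mean_b[1])
  expect_gt(abs(mae1 - bin_err), 0)
  expect_lt(abs(mae1 - bin_err), abs(mae0 - bin_err))  # moved toward it
})

test_that("qa_report assembles metrics, tests and the action-level flag", {
  cs <- tiny_null_case()
  tpsR <- tps_curve(density_space = "RED")
  tpsD <- tps_curve(density_space = "DES")
  ph <- insert_phantom(noise_sd_HU = 0)
  curves <- list(
    tps_red = tpsR, tps_des = tpsD,
    phan_red = phantom_insert_curve(ph$scan, ph$rois, "RED"),
    phan_des = phantom_insert_curve(ph$scan, ph$rois, "DES"),
    pop_red = population_curve(population_pairs(cs, tpsR), "RED",
                               min_bin_count = 50),
    pop_des = population_curve(population_pairs(cs, tpsD), "DES",
                               min_bin_count = 50))
  corr <- correct_pair(cs$ct, cs$sct)
  corr_cb <- correct_pair(cs$cbct, cs$sct)
  rep <- qa_report("null", corr$sct, corr$corrected, corr_cb$corrected,
                   curves, min_bin_count = 50)
  # perfect sCT: binned errors vanish against CT and phantom-curve CBCT
  exact <- rep$metrics$reference %in% c("CT", "CBCT_phan") |
    rep$metrics$space == "HU"
  expect_true(all(rep$metrics$meae[exact] == 0))
  # the population curve is exact at single-class bins and only limited by
  # within-bin linearization where two tissue classes share a 100 HU bin
  expect_true(all(rep$metrics$meae <= 0.02))
  expect_false(rep$flagged)
  expect_true(all(rep$tests$p >= 0 & rep$tests$p <= 1))
  expect_setequal(rep$metrics$reference[rep$metrics$space == "DES"],
                  c("CT", "CBCT_phan", "CBCT_pop"))
})
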