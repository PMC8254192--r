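test_that("TPS curve interpolates its control points piecewise-linearly", {
  cv <- tps_curve(data.frame(hu = c(-1000, 0), density = c(0.001, 1.0)))
  expect_equal(evaluate_curve(cv, -500), 0.5005)
  cv2 <- tps_curve(data.frame(hu = c(0, 1000), density = c(1.0, 1.6)))
  expect_equal(evaluate_curve(cv2, 0), 1.0)
  expect_equal(evaluate_curve(cv2, 1000), 1.6)
  # identical calls produce identical serializations
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_curve(tps_curve(density_space = "RED"), p1)
  write_curve(tps_curve(density_space = "RED"), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(tps_curve(data.frame(hu = c(0, 0), density = c(1, 1.1))),
               "increasing")
  expect_error(tps_curve(data.frame(hu = c(100, 0), density = c(1.1, 1))),
               "increasing")
  expect_error(tps_curve(data.frame(hu = 0, density = 1)), ">= 2 points")
})

test_that("population curve matches the TPS curve under an identity CBCT", {
  cs <- default_case()
  tps <- tps_curve(density_space = "RED")
  mask <- cs$truth$body$ct
  hu <- cs$ct$data[mask]
  pairs <- paired_voxels(hu, evaluate_curve(tps, hu), "HU")
  pop <- population_curve(pairs, "RED")
  # each surviving point must match the TPS value at its abscissa within
  # the bin's linearization error (within-bin slope x half the bin width)
  for (i in seq_len(nrow(pop$points))) {
    h <- pop$points$hu[i]
    lo <- floor((h + 1024) / 100) * 100 - 1024
    slope <- (evaluate_curve(tps, lo + 100) - evaluate_curve(tps, lo)) / 100
    expect_lte(abs(pop$points$density[i] - evaluate_curve(tps, h)),
               slope * 50 + 1e-9)
  }
})

test_that("bins below the pair-count threshold are disregarded", {
  a <- c(rep(-1000, 200), rep(0, 200), rep(150, 99))
  b <- rep(1, length(a))
  pop <- population_curve(paired_voxels(a, b, "HU"), "RED")
  # the 99-pair bin [76, 176) must be absent
  expect_false(any(pop$points$hu > 76 & pop$points$hu < 176))
  expect_equal(nrow(pop$points), 2L)
  # a bin with exactly 100 pairs survives
  a2 <- c(a, 150)
  pop2 <- population_curve(paired_voxels(a2, rep(1, length(a2)), "HU"), "RED")
  expect_equal(nrow(pop2$points), 3L)
  expect_error(population_curve(paired_voxels(rep(0, 500), rep(1, 500), "HU"),
                                "RED"), "underdetermined")
})

test_that("population curve is invariant to pair ordering", {
  set.seed(10)
  a <- runif(5000, -1000, 1500)
  b <- 1 + 5e-4 * a + rnorm(5000, 0, 0.01)
  b <- pmax(b, 0)
  perm <- sample.int(5000)
  c1 <- population_curve(paired_voxels(a, b, "HU"), "RED")
  c2 <- population_curve(paired_voxels(a[perm], b[perm], "HU"), "RED")
  expect_equal(c1$points, c2$points)
})

test_that("population curve inverts a constructed linear HU compression", {
  set.seed(11)
  hu <- runif(20000, 0, 1600)
  dens <- 1 + 5e-4 * hu          # linear truth
  cbct <- 0.5 * hu               # compressed CBCT scale
  pop <- population_curve(paired_voxels(cbct, dens, "HU"), "RED")
  # composing curve with the distortion recovers the true density;
  # recovered slope in CBCT HU is ~2x the TPS slope
  for (h in seq(100, 1500, by = 200)) {
    expect_lt(abs(evaluate_curve(pop, 0.5 * h) - (1 + 5e-4 * h)), 0.02)
  }
})

test_that("insert-phantom curve extracts ROI means, rejects degenerate inserts", {
  ph <- insert_phantom(noise_sd_HU = 0)
  cv <- phantom_insert_curve(ph$scan, ph$rois, "RED")
  cls <- default_tissue_classes()
  expect_equal(cv$points$hu, sort(cls$hu))
  expect_equal(cv$points$density, cls$red[order(cls$hu)])
  expect_error(phantom_insert_curve(ph$scan, ph$rois[1], "RED"), ">= 2")
  tiny_roi <- list(list(voxels = 1:5, red = 1), list(voxels = 6:11, red = 2))
  expect_error(phantom_insert_curve(ph$scan, tiny_roi, "RED"), "10 voxels")
  # indistinguishable inserts (same HU): non-monotone error
  dup <- list(list(voxels = ph$rois[[1]]$voxels, red = 0.5),
              list(voxels = ph$rois[[1]]$voxels, red = 0.7))
  expect_error(phantom_insert_curve(ph$scan, dup, "RED"), "monotone")
})

test_that("apply_curve clamps below, extrapolates above, stays monotone", {
  cv <- tps_curve(data.frame(hu = c(-1000, 0, 1000),
                             density = c(0.001, 1.0, 1.6)))
  vol0 <- volume(array(0, c(4, 4, 4)))
  expect_equal(apply_curve(vol0, cv)$data, array(1, c(4, 4, 4)))
  expect_equal(evaluate_curve(cv, -2000), 0.001)   # clamp below range
  expect_equal(evaluate_curve(cv, 1500), 1.9)      # linear extrapolation
  # negative extrapolated densities are clamped to 0
  steep <- tps_curve(data.frame(hu = c(0, 100), density = c(1, 0.1)))
  expect_equal(evaluate_curve(steep, 300), 0)
  # monotone curve gives monotone output
  set.seed(12)
  x <- sort(runif(100, -1500, 2000))
  y <- evaluate_curve(cv, x)
  expect_true(all(diff(y) >= -1e-12))
  vr <- volume(array(1, c(2, 2, 2)), value_space = "RED")
  expect_error(apply_curve(vr, cv), "HU")
  out <- apply_curve(vol0, cv)
  expect_identical(out$value_space, "RED")
})

test_that("curves round-trip through CSV and JSON", {
  cv <- tps_curve(density_space = "DES")
  pc <- tempfile(fileext = ".csv")
  pj <- tempfile(fileext = ".json")
  write_curve(cv, pc)
  write_curve(cv, pj)
  expect_equal(read_curve(pc, "TPS", "DES")$points, cv$points)
  back <- read_curve(pj)
  expect_equal(back$points, cv$points)
  expect_identical(back$kind, "TPS")
  expect_identical(back$density_space, "DES")
})
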