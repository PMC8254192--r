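test_that("NIfTI round-trip preserves data, spacing and origin", {
  set.seed(1)
  arr <- array(rnorm(16 * 16 * 8, sd = 100), c(16, 16, 8))
  arr <- clamp_hu(arr)
  vol <- volume(arr, spacing = c(0.98, 0.98, 2.0), origin = c(-10, 5, 2.5))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path, sidecar = TRUE)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, c(0.98, 0.98, 2.0), tolerance = 1e-6)
  expect_equal(back$origin, c(-10, 5, 2.5), tolerance = 1e-6)
  expect_identical(back$value_space, "HU")

  # an all-zero volume round-trips exactly
  z <- volume(array(0, c(16, 16, 8)))
  pz <- tempfile(fileext = ".nii.gz")
  write_volume(z, pz)
  expect_equal(read_volume(pz)$data, z$data)
})

test_that("read_volume rejects 4D images and invalid voxels", {
  arr4 <- array(0, c(8, 8, 4, 3))
  p <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), p)
  expect_error(read_volume(p), "expected 3D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(volume(array(c(NA, rep(0, 63)), c(4, 4, 4))), "non-finite")
})

test_that("read_volume normalizes flipped axis orientation", {
  set.seed(2)
  arr <- clamp_hu(array(rnorm(8 * 6 * 4, sd = 50), c(8, 6, 4)))
  vol <- volume(arr, spacing = c(2, 2, 3), origin = c(0, 0, 0))
  # write an LR-flipped version with the matching affine
  flipped <- arr[8:1, , ]
  img <- RNifti::asNifti(flipped)
  RNifti::pixdim(img) <- c(2, 2, 3)
  aff <- diag(4)
  aff[1, 1] <- -2
  aff[2, 2] <- 2
  aff[3, 3] <- 3
  aff[1, 4] <- 14  # world x of flipped voxel 0 = (8-1)*2
  p <- tempfile(fileext = ".nii.gz")
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, p)
  back <- read_volume(p)
  expect_equal(back$data, arr, tolerance = 1e-5)
  expect_equal(back$origin, c(0, 0, 0), tolerance = 1e-6)
})

test_that("resampling is exact on identical grids and constants", {
  set.seed(3)
  arr <- clamp_hu(array(rnorm(12 * 10 * 6, sd = 200), c(12, 10, 6)))
  vol <- volume(arr, spacing = c(2, 2, 2))
  same <- resample_to_grid(vol, vol, method = "trilinear")
  expect_equal(same$data, vol$data, tolerance = 1e-6)
  # idempotence on an already-matching grid
  again <- resample_to_grid(same, vol, method = "trilinear")
  expect_equal(again$data, same$data, tolerance = 1e-12)

  const <- volume(array(100, c(16, 16, 8)), spacing = c(1, 1, 1))
  coarse_ref <- volume(array(0, c(8, 8, 4)), spacing = c(2, 2, 2))
  out <- resample_to_grid(const, coarse_ref)
  # interior voxels (inside the moving extent) keep the constant
  inside <- out$data[2:7, 2:7, 2:3]
  expect_true(all(abs(inside - 100) < 1e-9))
})

test_that("trilinear resampling matches the analytic linear ramp", {
  # f(x, y, z) = x in mm; linear interpolation must be exact
  nx <- 20
  ramp <- array(rep((0:(nx - 1)) * 1.0, times = 10 * 6), c(nx, 10, 6))
  vol <- volume(ramp, spacing = c(1, 1, 1), value_space = "RAW")
  # reference grid offset by half a voxel in x
  ref <- volume(array(0, c(nx - 1, 10, 6)), spacing = c(1, 1, 1),
                origin = c(0.5, 0, 0), value_space = "RAW")
  out <- resample_to_grid(vol, ref)
  expected <- array(rep(0.5 + (0:(nx - 2)), times = 10 * 6),
                    c(nx - 1, 10, 6))
  expect_equal(out$data, expected, tolerance = 1e-6)
})

test_that("resampling rejects disjoint extents and fills outside with air", {
  a <- volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 1))
  far <- volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 1),
                origin = c(1000, 1000, 1000))
  expect_error(resample_to_grid(a, far), "disjoint")
  # partially overlapping: out-of-extent voxels become air
  shifted <- volume(array(200, c(8, 8, 4)), spacing = c(1, 1, 1),
                    origin = c(5, 0, 0))
  out <- resample_to_grid(shifted, a)
  expect_true(all(out$data[1:4, , ] == -1024))
  expect_true(all(out$data[6:8, , ] == 200))
})

test_that("body mask equals the generator's ground truth", {
  cs0 <- tiny_null_case()
  m <- body_mask(cs0$ct)
  expect_identical(m$mask, cs0$truth$body$ct)  # Dice = 1 noise-free

  # with acquisition noise the mask stays essentially identical
  cs <- generate_case(null_config(seed = 5, noise_scale = 1))
  mn <- body_mask(cs$ct)
  dice <- 2 * sum(mn$mask & cs$truth$body$ct) /
    (sum(mn$mask) + sum(cs$truth$body$ct))
  expect_gte(dice, 0.99)
})

test_that("body mask fills enclosed air pockets and rejects empty air", {
  cs <- generate_case(null_config(seed = 2, n_air_pockets_common = 2))
  m <- body_mask(cs$ct)
  pockets <- cs$truth$pockets$common
  expect_gt(length(pockets), 0)
  expect_true(all(m$mask[pockets]))  # inside despite being air
  expect_error(body_mask(volume(array(-1000, c(8, 8, 8)))), "no body")
  expect_error(body_mask(volume(array(1, c(8, 8, 8)), value_space = "RED")),
               "HU")
})
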