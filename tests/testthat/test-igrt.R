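test_that("rigid transforms compose and invert consistently", {
  set.seed(40)
  for (i in 1:25) {
    tf <- rigid_transform(runif(3, -10, 10), runif(3, -10, 10),
                          center = runif(3, -50, 50))
    inv <- tf_invert(tf)
    round_trip <- tf_compose(tf, inv)
    expect_lt(max(abs(round_trip$translations)), 1e-6)
    expect_lt(max(abs(round_trip$rotations)), 1e-6)
    # applying tf then inv restores points
    pts <- matrix(runif(30, -100, 100), 10, 3)
    expect_equal(tf_apply(inv, tf_apply(tf, pts)), pts, tolerance = 1e-9)
  }
  expect_error(rigid_transform(rotations = c(200, 0, 0)), "-180")
})

test_that("yaw rotates in the axial plane as expected", {
  tf <- rigid_transform(c(AP = 0, LR = 0, CC = 0),
                        c(pitch = 0, roll = 0, yaw = 90),
                        center = c(0, 0, 0))
  out <- tf_apply(tf, matrix(c(1, 0, 0), 1, 3))
  expect_equal(as.vector(out), c(0, 1, 0), tolerance = 1e-12)
})

test_that("transform JSON round-trips", {
  tf <- rigid_transform(c(AP = 1.5, LR = -0.5, CC = 3),
                        c(pitch = 1.2, roll = 0.1, yaw = -0.2),
                        center = c(10, 20, 30))
  p <- tempfile(fileext = ".json")
  write_transform(tf, p)
  back <- read_transform(p)
  expect_equal(back$translations, tf$translations)
  expect_equal(back$rotations, tf$rotations)
  expect_equal(back$center, tf$center)
})

test_that("self-registration returns the identity", {
  cs <- tiny_null_case()
  tf <- rigid_register(cs$ct, cs$ct)
  expect_lt(max(abs(tf$translations)), 0.05)
  expect_lt(max(abs(tf$rotations)), 0.05)
})

test_that("known translations and rotations are recovered (noise-free)", {
  cfg <- phantom_config(seed = 50, noise_scale = 0)
  ref <- displaced_phantom_ct(cfg, rigid_transform(), seed = 1)
  center <- ref$origin + (dim(ref$data) - 1) * ref$spacing / 2
  tf_shift <- rigid_transform(c(AP = -1, LR = 2, CC = 3),
                              c(pitch = 0, roll = 0, yaw = 0), center)
  fixed <- displaced_phantom_ct(cfg, tf_shift, seed = 2)
  got <- rigid_register(ref, fixed)
  expect_lt(max(abs(got$translations - tf_shift$translations)), 0.2)
  tf_rot <- rigid_transform(c(AP = 0, LR = 0, CC = 0),
                            c(pitch = 2, roll = 0, yaw = 0), center)
  fixed2 <- displaced_phantom_ct(cfg, tf_rot, seed = 3)
  got2 <- rigid_register(ref, fixed2)
  expect_lt(abs(got2$rotations["pitch"] - 2), 0.2)
})

test_that("registration requires sufficient bone", {
  flat <- volume(array(0, c(16, 16, 8)))
  expect_error(rigid_register(flat, flat), "bone mask")
})

test_that("deltas are differences from the CT reference", {
  dofs <- c("AP", "LR", "CC", "pitch", "roll", "yaw")
  mk_row <- function(case, mod, v) {
    cbind(data.frame(case = case, fraction = 1, modality = mod),
          stats::setNames(as.data.frame(as.list(v)), dofs))
  }
  matches <- rbind(mk_row("p1", "CT", c(1.0, 0, 0, 0, 0, 0)),
                   mk_row("p1", "sCT", c(2.5, 0, 0, 0, 0, 0)),
                   mk_row("p1", "MRI", c(1.0, 0, 0, 0, 0, 0)))
  d <- compute_deltas(matches)
  sct_row <- d$rows[d$rows$modality == "sCT", ]
  expect_equal(sct_row$AP, 1.5)
  mri_row <- d$rows[d$rows$modality == "MRI", ]
  expect_true(all(as.numeric(mri_row[, dofs]) == 0))
  ct_row <- d$rows[d$rows$modality == "CT", ]
  expect_true(all(as.numeric(ct_row[, dofs]) == 0))
  # antisymmetry: using sCT as the reference negates the deltas
  matches_swapped <- matches
  matches_swapped$modality <- c("sCT", "CT", "MRI")
  d2 <- compute_deltas(matches_swapped)
  expect_equal(d2$rows$AP[d2$rows$modality == "sCT"], -1.5)
  expect_error(compute_deltas(matches[matches$modality != "CT", ]),
               "CT reference")
})

test_that("pooled delta summaries track the generating distribution", {
  dofs <- c("AP", "LR", "CC", "pitch", "roll", "yaw")
  set.seed(41)
  n <- 10
  draws <- rnorm(n, 1.5, 2.2)   # AP offsets, Table-1-like structure
  rows <- NULL
  for (i in seq_len(n)) {
    for (mod in c("CT", "sCT")) {
      v <- c(if (mod == "sCT") draws[i] else 0, rep(0, 5))
      rows <- rbind(rows, cbind(
        data.frame(case = paste0("p", i), fraction = 1, modality = mod),
        stats::setNames(as.data.frame(as.list(v)), dofs)))
    }
  }
  d <- compute_deltas(rows)
  ap <- d$summary[d$summary$modality == "sCT" & d$summary$dof == "AP", ]
  expect_lt(abs(ap$mean - 1.5), 3 * 2.2 / sqrt(n))
  expect_equal(ap$n, n)
})

test_that("signed-rank significance matches exact enumeration", {
  dofs <- c("AP", "LR", "CC", "pitch", "roll", "yaw")
  mk <- function(ap_vals) {
    rows <- NULL
    for (i in seq_along(ap_vals)) {
      for (mod in c("CT", "sCT")) {
        v <- c(if (mod == "sCT") ap_vals[i] else 0, rep(0, 5))
        rows <- rbind(rows, cbind(
          data.frame(case = paste0("p", i), fraction = 1, modality = mod),
          stats::setNames(as.data.frame(as.list(v)), dofs)))
      }
    }
    compute_deltas(rows)
  }
  # all-positive sample of 6 untied values: two-sided exact p = 2/2^6
  sig <- delta_significance(mk(c(1, 2, 3, 4, 5, 6)))
  expect_equal(sig$p[sig$dof == "AP"], 0.03125)
  # perfectly symmetric sample: maximal p
  sig2 <- delta_significance(mk(c(-2, -1, 1, 2, -3, 3)))
  expect_gte(sig2$p[sig2$dof == "AP"], 0.99)
  # all-zero sample: documented p = 1
  expect_equal(sig2$p[sig2$dof == "CC"], 1)
  expect_error(delta_significance(mk(c(1, 2, 3))), ">= 5")
})
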