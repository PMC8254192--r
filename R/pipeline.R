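#' Build corrected CT-CBCT population pairs for one case
#'
#' Crops the CT and CBCT of a case to the CT body outline and water-fills
#' transient air in each image where the other shows soft tissue, then
#' returns the paired (CBCT HU, CT density) values used to build the
#' population calibration curve. CT densities come from the TPS curve.
#'
#' @param case a \code{phantom_case} (or any list with \code{ct},
#'   \code{cbct} HU volumes).
#' @param tps a TPS [calibration_curve()] in the target density space.
#' @return a \code{paired_voxels} object (a = CBCT HU, b = CT density).
#' @export
population_pairs <- function(case, tps) {
  mask <- body_mask(case$ct)
  ct_c <- crop_to_body(case$ct, mask)
  cbct_c <- crop_to_body(case$cbct, mask)
  cbct_f <- water_fill(cbct_c, ct_c)$corrected
  ct_f <- water_fill(ct_c, cbct_c)$corrected
  valid <- ct_f$valid & cbct_f$valid
  paired_voxels(cbct_f$data[valid],
                evaluate_curve(tps, ct_f$data[valid]),
                value_space = "HU")
}

#' Per-bin density recovery error of a CBCT calibration curve
#'
#' Measures how well a curve recovers the true densities of a (corrected)
#' CBCT: pairs of (CBCT HU, true density) are binned by CBCT HU as in
#' [population_curve()]; per retained bin the error is the difference
#' between the mean curve-converted density and the mean true density.
#'
#' @param curve a [calibration_curve()].
#' @param cbct corrected CBCT volume (HU, validity mask respected).
#' @param true_density array of ground-truth densities on the same grid.
#' @param bin_width_HU,min_bin_count binning parameters.
#' @return list: \code{rms} (root-mean-square over retained bins),
#'   \code{per_bin} (data.frame hu, converted, truth, count).
#' @export
curve_recovery_rms <- function(curve, cbct, true_density,
                               bin_width_HU = 100, min_bin_count = 100) {
  stopifnot(is_volume(cbct))
  valid <- cbct$valid %||% array(TRUE, dim(cbct$data))
  a <- cbct$data[valid]
  b <- true_density[valid]
  bin <- floor((a + 1024) / bin_width_HU)
  counts <- table(bin)
  keep <- sort(as.numeric(names(counts)[counts >= min_bin_count]))
  if (length(keep) == 0L) stopf("no retained bins")
  sel <- bin %in% keep
  bsel <- factor(bin[sel], levels = keep)
  conv <- tapply(evaluate_curve(curve, a[sel]), bsel, mean)
  truth <- tapply(b[sel], bsel, mean)
  hu <- tapply(a[sel], bsel, mean)
  per_bin <- data.frame(hu = as.numeric(hu), converted = as.numeric(conv),
                        truth = as.numeric(truth),
                        count = as.integer(table(bsel)))
  list(rms = sqrt(mean((per_bin$converted - per_bin$truth)^2)),
       per_bin = per_bin)
}

#' End-to-end phantom cohort quality assessment
#'
#' Runs the full assessment chain on a generated cohort: simulate N
#' paired cases, build per-case leave-one-out population calibration
#' curves from the corrected CT-CBCT pairs of the other cases, build the
#' insert-phantom curves once, correct each case's CT and CBCT against
#' its sCT, and produce a [qa_report()] per case plus a cohort table.
#' Deterministic given \code{seed}.
#'
#' @param n_cases number of phantom cases.
#' @param seed integer master seed; case i uses \code{seed + 101 * i}.
#' @param shape,spacing phantom grid.
#' @param sct_error a single [sct_error_params()] for all cases, or a
#'   list of length \code{n_cases} for per-case error levels.
#' @param cbct_distortion a [cbct_distortion_params()].
#' @param noise_scale phantom noise multiplier.
#' @param action_level MeAE flag threshold in DES space.
#' @param min_bin_count minimum pairs per retained bin (all binning).
#' @param out_dir optional directory for JSON reports and the cohort CSV.
#' @return list of class \code{cohort_qa}: \code{reports} (per case),
#'   \code{cohort} (data.frame, one row per case), \code{pop_curves},
#'   \code{phan_curves}, \code{tps_curves}, \code{cases}.
#' @export
run_cohort_qa <- function(n_cases = 5, seed = 1L,
                          shape = c(96, 96, 32), spacing = c(2, 2, 3),
                          sct_error = sct_error_params(),
                          cbct_distortion = cbct_distortion_params(),
                          noise_scale = 1, action_level = 0.1,
                          min_bin_count = 100, out_dir = NULL) {
  if (inherits(sct_error, "sct_error_params")) {
    sct_error <- rep(list(sct_error), n_cases)
  }
  stopifnot(length(sct_error) == n_cases)
  cases <- lapply(seq_len(n_cases), function(i) {
    generate_case(phantom_config(
      shape = shape, spacing = spacing, seed = as.integer(seed + 101L * i),
      sct_error = sct_error[[i]], cbct_distortion = cbct_distortion,
      noise_scale = noise_scale))
  })
  tps <- list(RED = tps_curve(density_space = "RED"),
              DES = tps_curve(density_space = "DES"))
  phan <- insert_phantom(noise_sd_HU = 5, seed = seed)
  phan_curves <- list(RED = phantom_insert_curve(phan$scan, phan$rois, "RED"),
                      DES = phantom_insert_curve(phan$scan, phan$rois, "DES"))
  pair_sets <- lapply(cases, function(cs) {
    list(RED = population_pairs(cs, tps$RED),
         DES = population_pairs(cs, tps$DES))
  })
  pop_curves <- lapply(seq_len(n_cases), function(i) {
    others <- setdiff(seq_len(n_cases), i)
    mk <- function(space) {
      a <- unlist(lapply(pair_sets[others], function(p) p[[space]]$a))
      b <- unlist(lapply(pair_sets[others], function(p) p[[space]]$b))
      population_curve(paired_voxels(a, b, "HU"), density_space = space,
                       min_bin_count = min_bin_count,
                       case_ids = paste0("case", others))
    }
    list(RED = mk("RED"), DES = mk("DES"))
  })
  reports <- lapply(seq_len(n_cases), function(i) {
    cs <- cases[[i]]
    corr <- correct_pair(cs$ct, cs$sct)
    corr_cb <- correct_pair(cs$cbct, cs$sct)
    qa_report(paste0("case", i), sct = corr$sct, ct = corr$corrected,
              cbct = corr_cb$corrected,
              curves = list(tps_red = tps$RED, tps_des = tps$DES,
                            phan_red = phan_curves$RED,
                            phan_des = phan_curves$DES,
                            pop_red = pop_curves[[i]]$RED,
                            pop_des = pop_curves[[i]]$DES),
              min_bin_count = min_bin_count, action_level = action_level)
  })
  cohort <- do.call(rbind, lapply(reports, qa_report_row))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_cases)) {
      write_qa_report(reports[[i]], file.path(out_dir,
                                              sprintf("case%d_qa.json", i)))
    }
    utils::write.csv(cohort, file.path(out_dir, "cohort_qa.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = seed, n_cases = n_cases),
                         file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  structure(list(reports = reports, cohort = cohort,
                 pop_curves = pop_curves, phan_curves = phan_curves,
                 tps_curves = tps, cases = cases, seed = seed),
            class = "cohort_qa")
}

#' QA response to a ladder of sCT error levels
#'
#' Evaluates how the MeAE statistic responds to increasing synthesis
#' error: one phantom case (fixed seed, hence fixed anatomy and
#' acquisition noise) is regenerated with each error level in
#' \code{sct_errors}, while the calibration curves are built once from an
#' independent support cohort. Because only the sCT differs between
#' rungs, the MeAE ordering isolates the error response.
#'
#' @param sct_errors list of [sct_error_params()], ordered by magnitude.
#' @param seed master seed; the evaluated case uses it directly, support
#'   cases use offsets of it.
#' @param n_support support cases for the population curves.
#' @param shape,spacing phantom grid.
#' @param action_level flag threshold on MeAE in DES space.
#' @return data.frame with one row per rung: \code{level},
#'   \code{meae_des_ct}, \code{meae_des_cbct_pop}, \code{flagged}.
#' @export
run_error_ladder <- function(sct_errors, seed = 1L, n_support = 4,
                             shape = c(96, 96, 32), spacing = c(2, 2, 3),
                             action_level = 0.1) {
  tps <- list(RED = tps_curve(density_space = "RED"),
              DES = tps_curve(density_space = "DES"))
  support <- lapply(seq_len(n_support), function(i) {
    generate_case(phantom_config(shape = shape, spacing = spacing,
                                 seed = as.integer(seed + 200L + i)))
  })
  mk_pop <- function(space) {
    p <- lapply(support, function(cs) population_pairs(cs, tps[[space]]))
    population_curve(paired_voxels(unlist(lapply(p, `[[`, "a")),
                                   unlist(lapply(p, `[[`, "b")), "HU"),
                     density_space = space,
                     case_ids = paste0("support", seq_len(n_support)))
  }
  pop <- list(RED = mk_pop("RED"), DES = mk_pop("DES"))
  ph <- insert_phantom(noise_sd_HU = 5, seed = seed)
  phan <- list(RED = phantom_insert_curve(ph$scan, ph$rois, "RED"),
               DES = phantom_insert_curve(ph$scan, ph$rois, "DES"))
  rows <- NULL
  for (j in seq_along(sct_errors)) {
    cs <- generate_case(phantom_config(shape = shape, spacing = spacing,
                                       seed = as.integer(seed),
                                       sct_error = sct_errors[[j]]))
    corr <- correct_pair(cs$ct, cs$sct)
    corr_cb <- correct_pair(cs$cbct, cs$sct)
    rep <- qa_report(paste0("rung", j), corr$sct, corr$corrected,
                     corr_cb$corrected,
                     curves = list(tps_red = tps$RED, tps_des = tps$DES,
                                   phan_red = phan$RED, phan_des = phan$DES,
                                   pop_red = pop$RED, pop_des = pop$DES),
                     action_level = action_level)
    m <- rep$metrics
    rows <- rbind(rows, data.frame(
      level = j,
      meae_des_ct = m$meae[m$space == "DES" & m$reference == "CT"],
      meae_des_cbct_pop = m$meae[m$space == "DES" &
                                   m$reference == "CBCT_pop"],
      flagged = rep$flagged))
  }
  rows
}

#' @export
print.cohort_qa <- function(x, ...) {
  cat(sprintf("<cohort_qa> %d cases, seed %d, %d flagged\n",
              nrow(x$cohort), x$seed, sum(x$cohort$flagged)))
  print(x$cohort[, c("case_id", "meae_hu_ct", "meae_des_ct",
                     "meae_des_cbct_phan", "meae_des_cbct_pop", "flagged")],
        row.names = FALSE)
  invisible(x)
}
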