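#' Bin paired values and compute per-bin means
#'
#' Pairs are assigned to half-open bins by the first image's value (the
#' sCT by convention, so sCT-CT and sCT-CBCT tables share one binning
#' axis). HU data uses 10 HU bins anchored at -1024; RED/DES data uses
#' 0.01 bins anchored at 0. Bins supported by fewer than
#' \code{min_bin_count} pairs are discarded.
#'
#' @param pairs a \code{paired_voxels} object.
#' @param bin_width bin width; default 10 (HU) or 0.01 (RED/DES).
#' @param min_bin_count minimum pairs per retained bin.
#' @return list of class \code{bin_table}: \code{bin_lower} (lower edges),
#'   \code{counts}, \code{mean_a}, \code{mean_b}, \code{value_space},
#'   \code{bin_width}.
#' @export
binned_means <- function(pairs, bin_width = NULL, min_bin_count = 100) {
  stopifnot(inherits(pairs, "paired_voxels"))
  space <- pairs$value_space
  if (is.null(bin_width)) bin_width <- if (space == "HU") 10 else 0.01
  anchor <- if (space == "HU") -1024 else 0
  if (pairs$n == 0L) stopf("no pairs to bin")
  bin <- floor((pairs$a - anchor) / bin_width)
  counts <- table(bin)
  keep <- sort(as.numeric(names(counts)[counts >= min_bin_count]))
  if (length(keep) == 0L) {
    stopf("no bins with >= %d pairs", min_bin_count)
  }
  sel <- bin %in% keep
  bsel <- factor(bin[sel], levels = keep)
  structure(list(
    bin_lower = anchor + keep * bin_width,
    counts = as.integer(table(bsel)),
    mean_a = as.numeric(tapply(pairs$a[sel], bsel, mean)),
    mean_b = as.numeric(tapply(pairs$b[sel], bsel, mean)),
    value_space = space, bin_width = bin_width,
    min_bin_count = min_bin_count),
    class = "bin_table")
}

#' Per-bin absolute errors
#'
#' The absolute difference between the two images' bin means,
#' \eqn{AE_i = |mean_a_i - mean_b_i|}, returned sorted ascending.
#'
#' @param table a \code{bin_table}.
#' @return list of class \code{ae_list}: \code{values} (sorted),
#'   \code{n}, \code{value_space}.
#' @export
absolute_errors <- function(table) {
  stopifnot(inherits(table, "bin_table"))
  v <- sort(abs(table$mean_a - table$mean_b))
  structure(list(values = v, n = length(v), value_space = table$value_space),
            class = "ae_list")
}

#' Median absolute binned error (MeAE)
#'
#' The median of the ordered per-bin absolute errors,
#' \deqn{MeAE = \tfrac12\left(AE_{\lfloor (n+1)/2 \rfloor} +
#'   AE_{\lceil (n+1)/2 \rceil}\right),}
#' with 1-based indexing into the sorted list. Because every retained
#' intensity bin contributes one value regardless of how many voxels it
#' holds, the whole CT range contributes equally — unlike the
#' voxel-weighted MAE, which is dominated by water-equivalent tissue.
#'
#' @param ae an \code{ae_list} or a numeric vector of absolute errors.
#' @return the MeAE, a scalar in the list's value space.
#' @export
meae <- function(ae) {
  v <- if (inherits(ae, "ae_list")) ae$values else as.numeric(ae)
  n <- length(v)
  if (n < 1L) stopf("empty absolute-error list")
  v <- sort(v)
  i1 <- floor((n + 1) / 2)
  i2 <- ceiling((n + 1) / 2)
  (v[i1] + v[i2]) / 2
}

#' Voxel-weighted mean absolute error
#'
#' The conventional comparison metric: the mean over all voxel pairs of
#' the absolute difference, with no binning.
#'
#' @param pairs a \code{paired_voxels} object.
#' @return scalar MAE.
#' @export
mae <- function(pairs) {
  stopifnot(inherits(pairs, "paired_voxels"))
  if (pairs$n < 1L) stopf("empty pair set")
  mean(abs(pairs$a - pairs$b))
}

#' Shapiro-Wilk normality test of an absolute-error distribution
#'
#' @param ae an \code{ae_list} or numeric vector, 3 <= n <= 5000.
#' @return the p-value. A constant list is a degenerate input and raises
#'   an error rather than returning a p-value.
#' @export
test_normality <- function(ae) {
  v <- if (inherits(ae, "ae_list")) ae$values else as.numeric(ae)
  if (length(v) < 3L || length(v) > 5000L) {
    stopf("Shapiro-Wilk requires 3 <= n <= 5000, got %d", length(v))
  }
  if (diff(range(v)) == 0) {
    stopf("degenerate input: all absolute errors identical")
  }
  stats::shapiro.test(v)$p.value
}

#' Compare two absolute-error distributions
#'
#' Two-sided unpaired Wilcoxon rank-sum (Mann-Whitney) test between the
#' sCT-CT and sCT-CBCT per-bin absolute errors. Exact when both samples
#' are small and untied, midranks with normal approximation otherwise.
#'
#' @param ae_ct,ae_cbct \code{ae_list} objects or numeric vectors.
#' @return the two-sided p-value.
#' @export
compare_ae_distributions <- function(ae_ct, ae_cbct) {
  x <- if (inherits(ae_ct, "ae_list")) ae_ct$values else as.numeric(ae_ct)
  y <- if (inherits(ae_cbct, "ae_list")) ae_cbct$values else as.numeric(ae_cbct)
  if (length(x) == 0L || length(y) == 0L) stopf("empty absolute-error list")
  # two identical constant samples carry no evidence of a difference
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) <= 50 && length(y) <= 50 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value)
}

#' Full quality-assessment report for one case
#'
#' Runs the whole assessment chain on corrected, co-gridded volumes:
#' binned means, absolute errors, MeAE and MAE in HU, RED and DES space
#' for sCT-CT and sCT-CBCT (the CBCT under both the insert-phantom and
#' the population calibration curve), Shapiro-Wilk normality of each
#' absolute-error distribution, rank-sum comparison of the sCT-CT and
#' sCT-CBCT distributions per value space, and the action-level flag:
#' a population-curve MeAE in mass density above
#' \code{action_level} marks the sCT for manual inspection.
#'
#' @param case_id identifier for the report.
#' @param sct,ct,cbct corrected volumes on one grid (HU, with validity
#'   masks set by the correction stage).
#' @param curves named list of calibration curves: \code{tps_red},
#'   \code{tps_des} (applied to CT and sCT), \code{phan_red},
#'   \code{phan_des}, \code{pop_red}, \code{pop_des} (applied to CBCT).
#' @param bin_width_hu,bin_width_density,min_bin_count binning parameters.
#' @param action_level flag threshold on MeAE in DES space, population
#'   curve.
#' @return list of class \code{qa_report}: \code{metrics} (data.frame with
#'   space, reference, meae, mae, n_bins, shapiro_p), \code{tests}
#'   (data.frame with space, comparison, p), \code{flagged},
#'   \code{action_level}, \code{case_id}.
#' @export
qa_report <- function(case_id, sct, ct, cbct, curves,
                      bin_width_hu = 10, bin_width_density = 0.01,
                      min_bin_count = 100, action_level = 0.1) {
  need <- c("tps_red", "tps_des", "phan_red", "phan_des",
            "pop_red", "pop_des")
  if (!all(need %in% names(curves))) {
    stopf("curves must contain: %s", paste(need, collapse = ", "))
  }
  refs <- list(
    HU = list(CT = list(a = sct, b = ct),
              CBCT = list(a = sct, b = cbct)),
    RED = list(CT = list(a = apply_curve(sct, curves$tps_red),
                         b = apply_curve(ct, curves$tps_red)),
               CBCT_phan = list(a = apply_curve(sct, curves$tps_red),
                                b = apply_curve(cbct, curves$phan_red)),
               CBCT_pop = list(a = apply_curve(sct, curves$tps_red),
                               b = apply_curve(cbct, curves$pop_red))),
    DES = list(CT = list(a = apply_curve(sct, curves$tps_des),
                         b = apply_curve(ct, curves$tps_des)),
               CBCT_phan = list(a = apply_curve(sct, curves$tps_des),
                                b = apply_curve(cbct, curves$phan_des)),
               CBCT_pop = list(a = apply_curve(sct, curves$tps_des),
                               b = apply_curve(cbct, curves$pop_des))))
  metrics <- NULL
  ae_lists <- list()
  for (space in names(refs)) {
    bw <- if (space == "HU") bin_width_hu else bin_width_density
    for (ref in names(refs[[space]])) {
      pr <- volume_pairs(refs[[space]][[ref]]$a, refs[[space]][[ref]]$b)
      tab <- binned_means(pr, bin_width = bw, min_bin_count = min_bin_count)
      ae <- absolute_errors(tab)
      ae_lists[[paste(space, ref, sep = ".")]] <- ae
      sp <- tryCatch(test_normality(ae), error = function(e) NA_real_)
      metrics <- rbind(metrics, data.frame(
        space = space, reference = ref, meae = meae(ae), mae = mae(pr),
        n_bins = ae$n, shapiro_p = sp, stringsAsFactors = FALSE))
    }
  }
  tests <- NULL
  for (space in names(refs)) {
    for (ref in setdiff(names(refs[[space]]), "CT")) {
      p <- compare_ae_distributions(ae_lists[[paste(space, "CT", sep = ".")]],
                                    ae_lists[[paste(space, ref, sep = ".")]])
      tests <- rbind(tests, data.frame(
        space = space, comparison = paste0("CT_vs_", ref), p = p,
        stringsAsFactors = FALSE))
    }
  }
  meae_des_pop <- metrics$meae[metrics$space == "DES" &
                                 metrics$reference == "CBCT_pop"]
  structure(list(case_id = case_id, metrics = metrics, tests = tests,
                 flagged = meae_des_pop > action_level,
                 action_level = action_level,
                 ae_lists = ae_lists),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> case %s%s\n", x$case_id,
              if (isTRUE(x$flagged)) "  ** FLAGGED FOR INSPECTION **" else ""))
  m <- x$metrics
  m$meae <- signif(m$meae, 4)
  m$mae <- signif(m$mae, 4)
  m$shapiro_p <- signif(m$shapiro_p, 3)
  print(m, row.names = FALSE)
  cat(sprintf("action level: MeAE[DES, pop] > %g\n", x$action_level))
  invisible(x)
}

#' Serialize a QA report
#'
#' JSON holds the full report; CSV holds one row per case in a
#' cohort-table layout (MeAE/MAE per space and reference plus the flag).
#'
#' @param report a \code{qa_report}.
#' @param path output path (.json or .csv).
#' @export
write_qa_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(case_id = report$case_id, metrics = report$metrics,
           tests = report$tests, flagged = report$flagged,
           action_level = report$action_level),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(qa_report_row(report), path, row.names = FALSE)
  }
  invisible(path)
}

# one wide row per case for the cohort CSV
qa_report_row <- function(report) {
  m <- report$metrics
  vals <- stats::setNames(
    as.list(c(m$meae, m$mae)),
    c(paste0("meae_", tolower(m$space), "_", tolower(m$reference)),
      paste0("mae_", tolower(m$space), "_", tolower(m$reference))))
  cbind(data.frame(case_id = report$case_id, stringsAsFactors = FALSE),
        as.data.frame(vals),
        data.frame(flagged = report$flagged))
}
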