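#' Paired voxel values from two volumes
#'
#' Collects the values of two co-gridded volumes at voxels that are valid
#' in both — the substrate for both the calibration curves and the binned
#' error statistics.
#'
#' @param a,b volumes on the same grid (a is conventionally the sCT, or
#'   the CBCT when building a population curve).
#' @return list of class \code{paired_voxels}: \code{a}, \code{b}
#'   (numeric vectors), \code{n}, \code{value_space} (of \code{a}).
#' @export
volume_pairs <- function(a, b) {
  stopifnot(is_volume(a), is_volume(b))
  if (!same_grid(a, b)) stopf("grid mismatch between paired volumes")
  valid <- a$valid %||% array(TRUE, dim(a$data))
  if (!is.null(b$valid)) valid <- valid & b$valid
  paired_voxels(a$data[valid], b$data[valid], value_space = a$value_space)
}

#' Construct paired values directly
#'
#' @param a,b equal-length numeric vectors.
#' @param value_space value space of \code{a} (\code{"HU"}, \code{"RED"},
#'   \code{"DES"}).
#' @return a \code{paired_voxels} object.
#' @export
paired_voxels <- function(a, b, value_space = "HU") {
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  structure(list(a = as.numeric(a), b = as.numeric(b), n = length(a),
                 value_space = value_space),
            class = "paired_voxels")
}

new_curve <- function(points, kind, density_space, bin_width_HU = NA,
                      min_bin_count = NA, provenance = NULL, sort = TRUE) {
  if (sort) points <- points[order(points$hu), , drop = FALSE]
  rownames(points) <- NULL
  if (nrow(points) < 2L) stopf("calibration curve needs >= 2 points")
  if (anyDuplicated(points$hu) || any(diff(points$hu) <= 0)) {
    stopf("curve HU values must be strictly increasing")
  }
  if (any(points$density < 0)) stopf("densities must be >= 0")
  structure(list(points = points, kind = kind, density_space = density_space,
                 bin_width_HU = bin_width_HU, min_bin_count = min_bin_count,
                 provenance = provenance),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> kind=%s, space=%s, %d points, HU [%g, %g]\n",
              x$kind, x$density_space, nrow(x$points), min(x$points$hu),
              max(x$points$hu)))
  invisible(x)
}

#' Treatment-planning-system calibration curve
#'
#' Piecewise-linear HU-to-density lookup through explicit control points,
#' as used for diagnostic-quality CT and sCT. The default control points
#' are the phantom tissue classes (see [default_tissue_classes()]), since
#' they define the ground-truth HU/density relation of the phantom world.
#'
#' @param control_points data.frame with columns \code{hu} and
#'   \code{density}; NULL uses the defaults for \code{density_space}.
#' @param density_space \code{"RED"} or \code{"DES"}.
#' @return a \code{calibration_curve} of kind \code{"TPS"}.
#' @export
tps_curve <- function(control_points = NULL,
                      density_space = c("RED", "DES")) {
  density_space <- match.arg(density_space)
  if (is.null(control_points)) {
    cls <- default_tissue_classes()
    control_points <- data.frame(
      hu = cls$hu,
      density = if (density_space == "RED") cls$red else cls$des)
  }
  # control points must be supplied in strictly increasing HU order
  new_curve(control_points, "TPS", density_space, sort = FALSE)
}

#' Population-based CBCT calibration curve
#'
#' The central calibration idea: rather than a scan of a plastic insert
#' phantom, use paired, corrected, co-registered CT-CBCT voxels from a
#' reference population. CBCT HU values are grouped into half-open
#' \code{bin_width_HU}-wide bins (anchored at -1024 HU); within each
#' retained bin, the mean CBCT HU and the mean CT-derived density form one
#' curve point. Bins supported by fewer than \code{min_bin_count} pairs
#' are discarded.
#'
#' @param pairs a \code{paired_voxels} object with \code{a} = CBCT HU and
#'   \code{b} = the known density of the corresponding CT voxels.
#' @param density_space \code{"RED"} or \code{"DES"}.
#' @param bin_width_HU bin width in HU.
#' @param min_bin_count minimum pairs per retained bin.
#' @param case_ids identifiers of the cases the pairs came from (audit).
#' @return a \code{calibration_curve} of kind \code{"population"}.
#' @export
population_curve <- function(pairs, density_space = c("RED", "DES"),
                             bin_width_HU = 100, min_bin_count = 100,
                             case_ids = NULL) {
  density_space <- match.arg(density_space)
  stopifnot(inherits(pairs, "paired_voxels"))
  anchor <- -1024
  bin <- floor((pairs$a - anchor) / bin_width_HU)
  counts <- table(bin)
  keep <- names(counts)[counts >= min_bin_count]
  if (length(keep) < 2L) stopf("population curve underdetermined: < 2 bins with >= %d pairs",
                               min_bin_count)
  sel <- bin %in% as.numeric(keep)
  bsel <- factor(bin[sel], levels = sort(as.numeric(keep)))
  hu_mean <- tapply(pairs$a[sel], bsel, mean)
  de_mean <- tapply(pairs$b[sel], bsel, mean)
  new_curve(data.frame(hu = as.numeric(hu_mean),
                       density = as.numeric(de_mean)),
            "population", density_space, bin_width_HU = bin_width_HU,
            min_bin_count = min_bin_count, provenance = case_ids)
}

#' Insert-phantom CBCT calibration curve
#'
#' Conventional CBCT calibration: mean HU over each known-density insert
#' ROI of a calibration phantom scan gives one curve point.
#'
#' @param cbct the phantom CBCT scan (HU volume).
#' @param rois list of ROIs, each a list with \code{voxels} (linear
#'   indices, >= 10) and a density entry named after \code{density_space}
#'   in lower case (\code{red} / \code{des}) or \code{density}.
#' @param density_space \code{"RED"} or \code{"DES"}.
#' @return a \code{calibration_curve} of kind \code{"phantom"}.
#' @export
phantom_insert_curve <- function(cbct, rois, density_space = c("RED", "DES")) {
  density_space <- match.arg(density_space)
  stopifnot(is_volume(cbct))
  if (length(rois) < 2L) stopf("need >= 2 inserts for a calibration curve")
  pts <- lapply(rois, function(r) {
    if (length(r$voxels) < 10L) stopf("insert ROI has < 10 voxels")
    dens <- r[[tolower(density_space)]] %||% r$density
    data.frame(hu = mean(cbct$data[r$voxels]), density = dens)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[order(pts$hu), , drop = FALSE]
  if (any(diff(pts$hu) <= 0)) {
    stopf("inserts indistinguishable: non-monotone mean HU")
  }
  new_curve(pts, "phantom", density_space)
}

#' Evaluate a calibration curve
#'
#' Piecewise-linear interpolation between curve points; above the top
#' point the last segment is extrapolated linearly (the rightmost points
#' of clinical curves are extrapolations), below the bottom point the
#' lowest density is used, and negative extrapolated densities are
#' clamped to zero.
#'
#' @param curve a \code{calibration_curve}.
#' @param hu numeric HU values.
#' @return densities, same shape as \code{hu}.
#' @export
evaluate_curve <- function(curve, hu) {
  stopifnot(inherits(curve, "calibration_curve"))
  p <- curve$points
  out <- stats::approx(p$hu, p$density, xout = hu, rule = 2)$y
  n <- nrow(p)
  slope <- (p$density[n] - p$density[n - 1]) / (p$hu[n] - p$hu[n - 1])
  above <- hu > p$hu[n]
  out[above] <- p$density[n] + slope * (hu[above] - p$hu[n])
  pmax(out, 0)
}

#' Convert an HU volume to densities through a calibration curve
#'
#' @param vol HU volume.
#' @param curve a \code{calibration_curve}.
#' @return volume in the curve's density space, validity mask preserved.
#' @export
apply_curve <- function(vol, curve) {
  stopifnot(is_volume(vol), inherits(curve, "calibration_curve"))
  if (vol$value_space != "HU") {
    stopf("apply_curve expects an HU volume, got %s", vol$value_space)
  }
  dens <- evaluate_curve(curve, as.vector(vol$data))
  volume(array(dens, dim(vol$data)), vol$spacing, vol$origin,
         curve$density_space, valid = vol$valid)
}

#' Read / write calibration curves
#'
#' CSV files carry the points (\code{hu,density} header); JSON files carry
#' points plus kind, density space and provenance.
#'
#' @param curve a \code{calibration_curve}.
#' @param path output file; format chosen by extension (.csv or .json).
#' @return \code{path} invisibly (write) or a curve (read).
#' @export
write_curve <- function(curve, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(kind = curve$kind, density_space = curve$density_space,
           bin_width_HU = curve$bin_width_HU,
           min_bin_count = curve$min_bin_count,
           provenance = curve$provenance, points = curve$points),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(curve$points, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_curve
#' @param kind,density_space metadata for CSV reads (JSON carries its own).
#' @export
read_curve <- function(path, kind = "TPS", density_space = "RED") {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_curve(as.data.frame(j$points), j$kind, j$density_space,
              bin_width_HU = j$bin_width_HU %||% NA,
              min_bin_count = j$min_bin_count %||% NA,
              provenance = j$provenance)
  } else {
    new_curve(utils::read.csv(path), kind, density_space)
  }
}
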