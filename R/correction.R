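#' Crop a volume to the sCT body outline
#'
#' Voxels outside the supplied body mask are excluded from all downstream
#' statistics. Exclusion is recorded in the volume's validity mask rather
#' than by overwriting intensities, so binning can skip cropped voxels
#' unambiguously.
#'
#' @param vol volume to crop (CT, CBCT or sCT).
#' @param sct_mask [body_mask()] of the sCT, on the same grid.
#' @return the cropped volume, with attributes \code{n_cropped} (number of
#'   previously valid voxels removed by this crop).
#' @export
crop_to_body <- function(vol, sct_mask) {
  stopifnot(is_volume(vol), inherits(sct_mask, "body_mask"))
  if (!identical(dim(vol$data), dim(sct_mask$mask)) ||
      any(abs(vol$spacing - sct_mask$spacing) > 1e-6) ||
      any(abs(vol$origin - sct_mask$origin) > 1e-6)) {
    stopf("grid mismatch between volume and body mask")
  }
  if (!any(sct_mask$mask)) stopf("empty body mask")
  old_valid <- vol$valid %||% array(TRUE, dim(vol$data))
  new_valid <- old_valid & sct_mask$mask
  out <- volume(vol$data, vol$spacing, vol$origin, vol$value_space,
                valid = new_valid)
  attr(out, "n_cropped") <- sum(old_valid) - sum(new_valid)
  out
}

#' Water-fill transient air discrepancies
#'
#' The correction step for anatomy that differs between scan sessions but
#' is irrelevant for sCT quality: wherever the reference scan (CT or CBCT)
#' shows air (< \code{air_threshold}) while the sCT shows soft tissue
#' (> \code{soft_threshold}), the reference voxel is replaced by water
#' (0 HU). The rule is one-directional: sCT voxels are never modified,
#' and reference voxels at or above the air threshold are never touched.
#' Both inequalities are strict.
#'
#' @param ref reference volume (CT or CBCT), HU, already cropped.
#' @param sct the sCT volume on the same grid, HU, already cropped.
#' @param air_threshold HU below which the reference counts as air.
#' @param soft_threshold HU above which the sCT counts as soft tissue.
#' @return list of class \code{correction_result}: \code{corrected}
#'   (volume), \code{n_filled}, \code{n_cropped} (voxels currently outside
#'   the validity mask), \code{fill_mask} (logical array).
#' @export
water_fill <- function(ref, sct, air_threshold = -500, soft_threshold = -200) {
  stopifnot(is_volume(ref), is_volume(sct))
  if (ref$value_space != "HU" || sct$value_space != "HU") {
    stopf("water_fill requires HU volumes")
  }
  if (!same_grid(ref, sct)) stopf("grid mismatch between ref and sct")
  valid <- ref$valid %||% array(TRUE, dim(ref$data))
  if (!is.null(sct$valid)) valid <- valid & sct$valid
  fill_mask <- valid & ref$data < air_threshold & sct$data > soft_threshold
  data <- ref$data
  data[fill_mask] <- 0  # water
  corrected <- volume(data, ref$spacing, ref$origin, "HU", valid = valid)
  structure(list(corrected = corrected,
                 n_filled = sum(fill_mask),
                 n_cropped = sum(!valid),
                 fill_mask = fill_mask),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %d voxels water-filled, %d cropped\n",
              x$n_filled, x$n_cropped))
  invisible(x)
}

#' Crop and correct a CT or CBCT against an sCT
#'
#' Convenience wrapper running the full correction chain: extract the sCT
#' body outline, crop both volumes to it, then water-fill transient air.
#'
#' @param ref reference volume (CT or CBCT).
#' @param sct the sCT.
#' @param sct_mask optional precomputed sCT [body_mask()].
#' @inheritParams water_fill
#' @return a \code{correction_result}; \code{$sct} holds the cropped sCT.
#' @export
correct_pair <- function(ref, sct, sct_mask = NULL,
                         air_threshold = -500, soft_threshold = -200) {
  if (is.null(sct_mask)) sct_mask <- body_mask(sct)
  ref_c <- crop_to_body(ref, sct_mask)
  sct_c <- crop_to_body(sct, sct_mask)
  res <- water_fill(ref_c, sct_c, air_threshold, soft_threshold)
  res$sct <- sct_c
  res
}
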