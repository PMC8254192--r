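#' 3D scalar volume
#'
#' The basic image container used throughout the package: a 3D array of
#' scalar values on a regular grid, with voxel spacing and world origin in
#' millimetres. The internal axis order is (LR, AP, CC): the first array
#' dimension runs left-right, the second anterior-posterior, the third
#' cranio-caudal. Voxel indices are 0-based in all coordinate arithmetic;
#' the world position of voxel (i, j, k) is \code{origin + c(i, j, k) * spacing}.
#'
#' @param data 3D numeric array.
#' @param spacing voxel size per axis in mm, strictly positive.
#' @param origin world position of voxel (0, 0, 0) in mm.
#' @param value_space one of \code{"HU"} (Hounsfield units, within
#'   [-1024, 4000]), \code{"RED"} (relative electron density, >= 0),
#'   \code{"DES"} (relative mass density, >= 0) or \code{"RAW"} (arbitrary
#'   intensities, e.g. MRI).
#' @param valid optional logical array of the same shape flagging voxels
#'   that participate in downstream statistics; \code{NULL} means all.
#' @return An object of class \code{sct_volume}.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   value_space = c("HU", "RED", "DES", "RAW"),
                   valid = NULL) {
  value_space <- match.arg(value_space)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("expected 3D volume")
  }
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    stopf("volume contains non-finite voxels")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("spacing must be three strictly positive values (mm)")
  }
  if (length(origin) != 3L) stopf("origin must have three components (mm)")
  rng <- range(data)
  if (value_space == "HU" && (rng[1] < -1024 - 1e-6 || rng[2] > 4000 + 1e-6)) {
    stopf("HU values outside [-1024, 4000]; clamp_hu() first if intended")
  }
  if (value_space %in% c("RED", "DES") && rng[1] < -1e-9) {
    stopf("%s values must be non-negative", value_space)
  }
  if (!is.null(valid)) {
    if (!identical(dim(valid), dim(data))) stopf("valid mask shape mismatch")
    valid <- array(as.logical(valid), dim(data))
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         value_space = value_space, valid = valid),
    class = "sct_volume")
}

#' @export
print.sct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sct_volume> %d x %d x %d voxels, %s\n", d[1], d[2], d[3],
              x$value_space))
  cat(sprintf("  spacing: %s mm, origin: %s mm\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range: [%.1f, %.1f]", min(x$data), max(x$data)))
  if (!is.null(x$valid)) cat(sprintf(", valid voxels: %d", sum(x$valid)))
  cat("\n")
  invisible(x)
}

is_volume <- function(x) inherits(x, "sct_volume")

#' Clamp intensities to the supported Hounsfield range
#'
#' @param data numeric array or vector of HU values.
#' @param lo,hi clamp bounds; the defaults cover air through the upper end
#'   of the bone registration window.
#' @return Clamped values.
#' @export
clamp_hu <- function(data, lo = -1024, hi = 4000) {
  pmin(pmax(data, lo), hi)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# World coordinates (mm) of every voxel along one axis.
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

#' Read a 3D volume from a NIfTI file
#'
#' Reads a NIfTI-1 image and normalizes it to the package's internal
#' axis convention (LR, AP, CC with ascending world coordinates). The
#' stored orientation may be any permutation/flip of those axes; oblique
#' acquisitions are rejected. The value space is taken from an optional
#' JSON sidecar (same path with extension \code{.json}, field
#' \code{value_space}) unless given explicitly.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @param value_space value space of the voxel data; default from sidecar,
#'   falling back to \code{"HU"}.
#' @return An \code{sct_volume}.
#' @export
read_volume <- function(path, value_space = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L) stopf("expected 3D volume, got %dD", length(d))
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3]
  off <- xf[1:3, 4]
  data <- array(as.numeric(img), d)
  if (anyNA(data) || any(!is.finite(data))) {
    stopf("volume contains non-finite voxels: %s", path)
  }
  # normalize orientation: each voxel axis must align with one world axis
  perm <- integer(3)
  flip <- logical(3)
  spacing <- numeric(3)
  for (j in 1:3) {
    cn <- sqrt(sum(A[, j]^2))
    i <- which.max(abs(A[, j]))
    if (abs(A[i, j]) < 0.999 * cn) {
      stopf("oblique orientation not supported: %s", path)
    }
    perm[j] <- i
    flip[j] <- A[i, j] < 0
    spacing[i] <- cn
  }
  if (anyDuplicated(perm)) stopf("degenerate orientation matrix: %s", path)
  origin <- numeric(3)
  for (j in 1:3) {
    i <- perm[j]
    origin[i] <- if (flip[j]) off[i] + A[i, j] * (d[j] - 1) else off[i]
  }
  for (j in 1:3) {
    if (flip[j]) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[j]] <- rev(idx[[j]])
      data <- data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
  }
  ord <- order(perm)
  data <- aperm(data, ord)
  if (is.null(value_space)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (sidecar != path && file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      value_space <- meta$value_space
    }
  }
  volume(data, spacing = spacing, origin = origin,
         value_space = value_space %||% "HU")
}

#' Write a volume to a NIfTI file
#'
#' Volumes are written RAS-aligned with the package's axis convention.
#' Logical (mask) data is stored as uint8. A JSON sidecar recording the
#' value space is written when \code{sidecar = TRUE}.
#'
#' @param vol an \code{sct_volume} or a logical array plus grid via `like`.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param sidecar write a \code{.json} sidecar with the value space.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = FALSE) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing  # before the xforms: scales live here
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  if (sidecar) {
    jsonlite::write_json(list(value_space = vol$value_space),
                         sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a body mask as uint8 NIfTI
#'
#' @param mask a \code{body_mask} object (see [body_mask()]).
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)),
                         datatype = "uint8")
  RNifti::pixdim(img) <- mask$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(mask$spacing)
  aff[1:3, 4] <- mask$origin
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto the grid of another
#'
#' Maps the reference grid into the moving volume's world frame and
#' interpolates. Voxels falling outside the moving volume's extent are
#' filled with -1024 HU (air) for HU volumes, 0 for densities, so that
#' body-outline mismatch shows up as air for the correction stage.
#'
#' @param moving volume to be resampled.
#' @param reference volume whose grid the output adopts.
#' @param method \code{"trilinear"} or \code{"nearest"}.
#' @return An \code{sct_volume} on the reference grid.
#' @export
resample_to_grid <- function(moving, reference,
                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_volume(moving), is_volume(reference))
  dm <- dim(moving$data)
  # world extents must overlap
  mv_lo <- moving$origin
  mv_hi <- moving$origin + (dm - 1) * moving$spacing
  dr <- dim(reference$data)
  rf_lo <- reference$origin
  rf_hi <- reference$origin + (dr - 1) * reference$spacing
  if (any(mv_hi < rf_lo) || any(mv_lo > rf_hi)) {
    stopf("disjoint world extents: volumes do not overlap")
  }
  fill <- if (moving$value_space == "HU") -1024 else 0
  cx <- axis_coords(reference, 1)
  cy <- axis_coords(reference, 2)
  cz <- axis_coords(reference, 3)
  ix <- (rep(cx, times = dr[2] * dr[3]) - moving$origin[1]) / moving$spacing[1]
  iy <- (rep(rep(cy, each = dr[1]), times = dr[3]) - moving$origin[2]) /
    moving$spacing[2]
  iz <- (rep(cz, each = dr[1] * dr[2]) - moving$origin[3]) / moving$spacing[3]
  vals <- if (method == "trilinear") {
    tri_interp(moving$data, ix, iy, iz, fill = fill)
  } else {
    nn_interp(moving$data, ix, iy, iz, fill = fill)
  }
  if (moving$value_space == "HU") vals <- clamp_hu(vals)
  volume(array(vals, dr), spacing = reference$spacing,
         origin = reference$origin, value_space = moving$value_space)
}

#' Extract the body outline mask of an HU volume
#'
#' Thresholds at -300 HU (between the air and soft-tissue correction
#' cut-offs), keeps the largest 6-connected component and fills fully
#' enclosed holes, so internal air pockets count as inside the body.
#'
#' @param vol HU volume.
#' @param threshold body threshold in HU.
#' @return An object of class \code{body_mask} with fields \code{mask}
#'   (logical array), \code{spacing}, \code{origin}, \code{source_volume_id}.
#' @export
body_mask <- function(vol, threshold = -300) {
  stopifnot(is_volume(vol))
  if (vol$value_space != "HU") stopf("body_mask requires an HU volume")
  fg <- vol$data > threshold
  if (!any(fg)) stopf("no body found: empty foreground at %g HU", threshold)
  comp <- largest_component(fg)
  comp <- fill_holes(comp)
  structure(
    list(mask = comp, spacing = vol$spacing, origin = vol$origin,
         source_volume_id = attr(vol, "id") %||% NA_character_),
    class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %s voxels inside of %s\n", sum(x$mask),
              paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}
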