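#' Default tissue classes for the pelvic phantom
#'
#' Tissue classes with mean Hounsfield units, HU noise standard deviation,
#' and relative electron (RED) and mass (DES) densities. The HU/density
#' pairs follow the standard shape of a CT calibration curve: near-linear
#' through air, fat and water, with a slope change above soft tissue where
#' the bone segment begins. Bone is split into four sub-classes so the
#' phantom populates the whole 300-1200 HU range of the calibration bins.
#'
#' @return data.frame with columns \code{label}, \code{name}, \code{hu},
#'   \code{hu_sd}, \code{red}, \code{des}.
#' @export
default_tissue_classes <- function() {
  data.frame(
    label = 0:7,
    name = c("air", "fat", "water", "muscle",
             "bone300", "bone600", "bone900", "cortical"),
    hu = c(-1000, -100, 0, 60, 300, 600, 900, 1200),
    hu_sd = c(20, 15, 12, 12, 30, 35, 40, 50),
    red = c(0.001, 0.95, 1.00, 1.05, 1.20, 1.35, 1.52, 1.70),
    des = c(0.001, 0.95, 1.00, 1.06, 1.20, 1.43, 1.66, 1.90),
    stringsAsFactors = FALSE)
}

#' CBCT intensity distortion parameters
#'
#' Parametric stand-in for the scatter-driven miscalibration of CBCT
#' Hounsfield units: a global additive shift, a multiplicative compression
#' of the HU scale about \code{center_HU} (scatter flattens contrast), a
#' radial low-frequency cupping field, and additive Gaussian noise.
#'
#' @param global_shift_HU additive offset in HU.
#' @param compression slope factor in (0, 1.5] applied to
#'   \code{hu - center_HU}.
#' @param cupping_amplitude_HU peak-to-centre amplitude of the quadratic
#'   radial field, in HU.
#' @param noise_sd_HU Gaussian noise standard deviation, >= 0.
#' @param center_HU centre of the compression.
#' @param center_xy,rmax_mm in-plane geometry of the cupping field (world
#'   mm); filled in from the grid by [generate_case()] when left NULL.
#' @return list of class \code{cbct_distortion_params}.
#' @export
cbct_distortion_params <- function(global_shift_HU = 30, compression = 0.75,
                                   cupping_amplitude_HU = 40,
                                   noise_sd_HU = 25, center_HU = 0,
                                   center_xy = NULL, rmax_mm = NULL) {
  if (compression <= 0 || compression > 1.5) {
    stopf("compression must lie in (0, 1.5]")
  }
  if (noise_sd_HU < 0) stopf("noise_sd_HU must be >= 0")
  structure(list(global_shift_HU = global_shift_HU, compression = compression,
                 cupping_amplitude_HU = cupping_amplitude_HU,
                 noise_sd_HU = noise_sd_HU, center_HU = center_HU,
                 center_xy = center_xy, rmax_mm = rmax_mm),
            class = "cbct_distortion_params")
}

#' sCT prediction-error parameters
#'
#' Controls how the phantom degrades the true CT into a synthetic CT:
#' a constant HU bias on predicted bone, a fraction of bone voxels
#' mispredicted as soft tissue (the dominant failure mode of MRI-based
#' synthesis, where bone and air are hard to tell apart), and a Gaussian
#' blur emulating the smoothness of patch-averaged predictions.
#'
#' @param bone_hu_bias HU added to correctly detected bone voxels.
#' @param bone_miss_fraction fraction in [0, 1] of bone voxels replaced by
#'   muscle-equivalent HU.
#' @param blur_sigma_mm isotropic Gaussian blur of the prediction, mm.
#' @return list of class \code{sct_error_params}.
#' @export
sct_error_params <- function(bone_hu_bias = 0, bone_miss_fraction = 0,
                             blur_sigma_mm = 1.5) {
  if (bone_miss_fraction < 0 || bone_miss_fraction > 1) {
    stopf("bone_miss_fraction must lie in [0, 1]")
  }
  if (blur_sigma_mm < 0) stopf("blur_sigma_mm must be >= 0")
  structure(list(bone_hu_bias = bone_hu_bias,
                 bone_miss_fraction = bone_miss_fraction,
                 blur_sigma_mm = blur_sigma_mm),
            class = "sct_error_params")
}

#' Phantom configuration
#'
#' @param shape voxel counts per axis (LR, AP, CC).
#' @param spacing voxel size in mm.
#' @param seed integer RNG seed; a case is bit-reproducible given its seed.
#' @param tissue_classes tissue table, see [default_tissue_classes()].
#' @param n_air_pockets_common air pockets present in every modality.
#' @param n_air_pockets_transient air pockets present in the CT or the
#'   CBCT (split between them) but never in the sCT.
#' @param outline_jitter_mm maximum outward expansion of the CT/CBCT body
#'   outline relative to the sCT body (the sCT outline is the smallest).
#' @param noise_scale multiplier on the per-class HU noise and the MRI
#'   noise; 0 gives noise-free CT/MRI.
#' @param mri_noise_sd MRI noise standard deviation (arbitrary units).
#' @param cbct_distortion a [cbct_distortion_params()] object.
#' @param sct_error an [sct_error_params()] object.
#' @return list of class \code{phantom_config}.
#' @export
phantom_config <- function(shape = c(96, 96, 32), spacing = c(2, 2, 3),
                           seed = 1L,
                           tissue_classes = default_tissue_classes(),
                           n_air_pockets_common = 1L,
                           n_air_pockets_transient = 2L,
                           outline_jitter_mm = 4,
                           noise_scale = 1,
                           mri_noise_sd = 4,
                           cbct_distortion = cbct_distortion_params(),
                           sct_error = sct_error_params()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stopf("shape too small to contain the body: need >= 8 voxels per axis")
  }
  if (any(spacing <= 0)) stopf("spacing must be positive")
  if (n_air_pockets_common < 0 || n_air_pockets_transient < 0) {
    stopf("pocket counts must be >= 0")
  }
  if (any(tissue_classes$hu_sd < 0)) stopf("HU sd must be >= 0")
  needed <- c("air", "fat", "water", "muscle")
  if (!all(needed %in% tissue_classes$name)) {
    stopf("tissue_classes must include air, fat, water and muscle")
  }
  if (!any(grepl("bone|cortical", tissue_classes$name))) {
    stopf("tissue_classes must include at least one bone class")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 seed = as.integer(seed), tissue_classes = tissue_classes,
                 n_air_pockets_common = as.integer(n_air_pockets_common),
                 n_air_pockets_transient = as.integer(n_air_pockets_transient),
                 outline_jitter_mm = outline_jitter_mm,
                 noise_scale = noise_scale, mri_noise_sd = mri_noise_sd,
                 cbct_distortion = cbct_distortion, sct_error = sct_error),
            class = "phantom_config")
}

#' Apply the CBCT distortion model to HU values
#'
#' \code{shift + compression * (hu - center) + cupping(pos)} with a
#' quadratic in-plane cupping field
#' \code{amplitude * ((r / rmax)^2 - 1/2)} centred on the scan axis.
#' Monotone non-decreasing in \code{hu} at fixed position.
#'
#' @param hu numeric HU values.
#' @param pos optional N x 3 matrix of world coordinates (mm); required
#'   when the cupping amplitude is non-zero.
#' @param params a [cbct_distortion_params()] object.
#' @return distorted HU values (not clamped, no noise).
#' @export
apply_cbct_distortion <- function(hu, pos = NULL, params) {
  stopifnot(inherits(params, "cbct_distortion_params"))
  out <- params$global_shift_HU +
    params$compression * (hu - params$center_HU) + params$center_HU
  if (params$cupping_amplitude_HU != 0) {
    if (is.null(pos)) stopf("pos required when cupping amplitude is non-zero")
    ctr <- params$center_xy %||% c(0, 0)
    rmax <- params$rmax_mm %||% 100
    r2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
    out <- out + params$cupping_amplitude_HU * (r2 / rmax^2 - 0.5)
  }
  out
}

# --- geometry helpers (internal) --------------------------------------------

phantom_geometry <- function(shape, spacing, var = NULL) {
  fov <- shape * spacing
  ctr <- (shape - 1) * spacing / 2
  v <- var %||% c(ax = 1, by = 1, fh = 1, ring = 1)
  list(fov = fov, ctr = ctr,
       a = 0.42 * fov[1] * v[["ax"]], b = 0.36 * fov[2] * v[["by"]],
       fat_scale = 0.82,
       fh_r = 0.075 * fov[1] * v[["fh"]],          # femoral head radius
       ring_R = 0.18 * fov[2] * v[["ring"]], ring_rm = 0.035 * fov[1])
}

# per-case anatomical variation (patients differ); consumes exactly four
# uniform draws so callers can reproduce it from the config seed
draw_anatomy_variation <- function() {
  c(ax = stats::runif(1, 0.92, 1.08), by = stats::runif(1, 0.92, 1.08),
    fh = stats::runif(1, 0.88, 1.12), ring = stats::runif(1, 0.92, 1.08))
}

# world coordinate arrays for a grid
grid_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

# squared elliptical radius field (x, y only), full 3D array
ellipse_field <- function(co, shape, ctr, a, b) {
  ex <- ((co$x - ctr[1]) / a)^2
  ey <- ((co$y - ctr[2]) / b)^2
  array(rep(outer(ex, ey, `+`), times = shape[3]), shape)
}

sphere_mask <- function(co, shape, center, r) {
  dx2 <- (co$x - center[1])^2
  dy2 <- (co$y - center[2])^2
  dz2 <- (co$z - center[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(arr <= r^2, shape)
}

# pointwise anatomy labels at arbitrary world coordinates (mm); the body
# ellipse is scaled by `scale`. Vectorized over x/y/z of equal length.
phantom_labels_points <- function(x, y, z, g, cls, scale = 1) {
  lab_of <- function(nm) cls$label[match(nm, cls$name)]
  e <- ((x - g$ctr[1]) / (g$a * scale))^2 + ((y - g$ctr[2]) / (g$b * scale))^2
  labels <- rep(lab_of("air"), length(x))
  labels[e <= 1] <- lab_of("fat")
  inner <- e <= g$fat_scale^2
  labels[inner] <- lab_of("muscle")
  # bladder: anterior water ellipsoid
  bladder <- ((x - g$ctr[1]) / (0.22 * g$a))^2 +
    ((y - (g$ctr[2] - 0.35 * g$b)) / (0.20 * g$b))^2 +
    ((z - g$ctr[3]) / (0.45 * g$fov[3] / 2))^2 <= 1
  labels[bladder & inner] <- lab_of("water")
  # femoral heads: two spheres with concentric bone shells; deliberately
  # unequal (as left/right anatomy is) so rotations are geometrically pinned
  fh <- list(list(sx = -1, rs = 0.90, dz = 0),
             list(sx = 1, rs = 1.15, dz = 0.06 * g$fov[3]))
  for (f in fh) {
    cen <- c(g$ctr[1] + f$sx * 0.62 * g$a, g$ctr[2] + 0.05 * g$b,
             g$ctr[3] + f$dz)
    r2 <- (x - cen[1])^2 + (y - cen[2])^2 + (z - cen[3])^2
    r <- g$fh_r * f$rs
    for (sp in list(c(1.0, "bone300"), c(0.85, "bone600"),
                    c(0.65, "bone900"))) {
      labels[r2 <= (r * as.numeric(sp[1]))^2] <- lab_of(sp[2])
    }
    labels[r2 <= r^2 & r2 > (0.92 * r)^2] <- lab_of("cortical")
  }
  # pelvic ring: torus around the CC axis, posterior of centre
  yc <- g$ctr[2] + 0.30 * g$b
  rho <- sqrt((x - g$ctr[1])^2 + (y - yc)^2)
  tor <- (rho - g$ring_R)^2 + (z - g$ctr[3])^2
  labels[tor <= g$ring_rm^2 & inner] <- lab_of("cortical")
  labels[tor <= (0.6 * g$ring_rm)^2 & inner] <- lab_of("bone600")
  # vertebral column: posterior box segmented along CC into alternating
  # vertebral bodies and discs, anchoring the CC and pitch degrees of freedom
  vbox <- abs(x - g$ctr[1]) <= 0.09 * g$fov[1] / 2 &
    y >= g$ctr[2] + 0.32 * g$b & y <= g$ctr[2] + 0.55 * g$b
  seg <- (z %/% 15) %% 3   # 15 mm segments, 2-of-3 bone
  labels[vbox & seg < 2 & inner] <- lab_of("bone900")
  labels[vbox & seg == 0 & inner] <- lab_of("cortical")
  labels
}

# base anatomy labels on the grid, body ellipse scaled by `scale`
phantom_base_labels <- function(shape, spacing, scale = 1, g = NULL) {
  if (is.null(g)) g <- phantom_geometry(shape, spacing)
  co <- grid_coords(shape, spacing)
  cls <- default_tissue_classes()
  x <- rep(co$x, times = shape[2] * shape[3])
  y <- rep(rep(co$y, each = shape[1]), times = shape[3])
  z <- rep(co$z, each = shape[1] * shape[2])
  array(phantom_labels_points(x, y, z, g, cls, scale), shape)
}

# place n spherical air pockets in muscle; returns list(labels, idx)
place_pockets <- function(labels, shape, spacing, n, air_label, muscle_label) {
  idx_all <- integer(0)
  g <- phantom_geometry(shape, spacing)
  co <- grid_coords(shape, spacing)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 200L) {
    tries <- tries + 1L
    cen <- c(g$ctr[1] + stats::runif(1, -0.35, 0.35) * g$a,
             g$ctr[2] + stats::runif(1, -0.05, 0.20) * g$b,
             g$ctr[3] + stats::runif(1, -0.35, 0.35) * g$fov[3] / 2)
    r <- stats::runif(1, 4, 7)
    m <- sphere_mask(co, shape, cen, r)
    if (!any(m)) next
    if (all(labels[m] == muscle_label)) {
      labels[m] <- air_label
      idx_all <- c(idx_all, which(m))
      placed <- placed + 1L
    }
  }
  list(labels = labels, idx = sort(idx_all))
}

labels_to_hu <- function(labels, cls) {
  hu <- cls$hu[match(as.vector(labels), cls$label)]
  array(hu, dim(labels))
}

labels_to_density <- function(labels, cls, space) {
  col <- if (space == "RED") cls$red else cls$des
  array(col[match(as.vector(labels), cls$label)], dim(labels))
}

class_noise <- function(labels, cls, scale) {
  if (scale <= 0) return(array(0, dim(labels)))
  sd_map <- cls$hu_sd[match(as.vector(labels), cls$label)] * scale
  array(stats::rnorm(length(labels), 0, sd_map), dim(labels))
}

# --- case generation --------------------------------------------------------

#' Generate a paired CT / MRI / sCT / CBCT phantom case
#'
#' Builds a pelvic-like digital phantom — elliptical body with a fat rim,
#' muscle interior, an anterior water "bladder", two femoral-head spheres
#' and a pelvic-ring torus of layered bone — and derives the four
#' modalities from it:
#' \itemize{
#'   \item CT: class HU means plus per-class Gaussian noise;
#'   \item MRI: strictly monotone mapping of the class labels plus noise;
#'   \item sCT: the noise-free CT (without transient pockets) degraded per
#'     [sct_error_params()];
#'   \item CBCT: the noise-free CT of the CBCT's own anatomy passed through
#'     [apply_cbct_distortion()] plus noise.
#' }
#' Transient air pockets appear in the CT or the CBCT but never in the
#' sCT; the CT/CBCT body outlines are expanded by up to
#' \code{outline_jitter_mm} relative to the sCT body, which therefore has
#' the smallest outline. Everything is reproducible from the seed, and the
#' \code{truth} element records the label maps, per-modality body masks,
#' true density maps, pocket voxel indices and the exact distortion used.
#'
#' @param config a [phantom_config()].
#' @return list of class \code{phantom_case}: \code{ct}, \code{mri},
#'   \code{sct}, \code{cbct} ([volume()] objects on one grid) and
#'   \code{truth}.
#' @export
generate_case <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  spacing <- config$spacing
  cls <- config$tissue_classes
  lab_of <- function(nm) cls$label[match(nm, cls$name)]
  with_seed(config$seed, {
    # anatomy differs between cases; drawn first so other generators can
    # reproduce it from the same seed
    g <- phantom_geometry(shape, spacing, draw_anatomy_variation())
    # body outline scales: sCT = 1 (smallest), CT/CBCT expanded
    jit <- config$outline_jitter_mm
    scale_ct <- 1 + (if (jit > 0) stats::runif(1, 0.5, 1) * jit / g$a else 0)
    scale_cbct <- 1 + (if (jit > 0) stats::runif(1, 0.5, 1) * jit / g$a else 0)

    base <- phantom_base_labels(shape, spacing, scale = 1, g = g)
    # common pockets live in every modality
    pk <- place_pockets(base, shape, spacing, config$n_air_pockets_common,
                        lab_of("air"), lab_of("muscle"))
    base <- pk$labels
    common_idx <- pk$idx

    expand_region <- function(scale) {
      if (scale <= 1) return(array(FALSE, shape))
      co <- grid_coords(shape, spacing)
      e_out <- ellipse_field(co, shape, g$ctr, g$a * scale, g$b * scale) <= 1
      e_in <- ellipse_field(co, shape, g$ctr, g$a, g$b) <= 1
      e_out & !e_in
    }
    labels_ct <- base
    labels_ct[expand_region(scale_ct)] <- lab_of("fat")
    labels_cbct <- base
    labels_cbct[expand_region(scale_cbct)] <- lab_of("fat")

    n_tr <- config$n_air_pockets_transient
    n_ct <- as.integer(ceiling(n_tr / 2))
    pk_ct <- place_pockets(labels_ct, shape, spacing, n_ct,
                           lab_of("air"), lab_of("muscle"))
    labels_ct <- pk_ct$labels
    pk_cb <- place_pockets(labels_cbct, shape, spacing, n_tr - n_ct,
                           lab_of("air"), lab_of("muscle"))
    labels_cbct <- pk_cb$labels

    ct_clean <- labels_to_hu(labels_ct, cls)
    ct_data <- clamp_hu(ct_clean + class_noise(labels_ct, cls,
                                               config$noise_scale))

    # MRI: strictly monotone label mapping, so classes stay separable
    mri_map <- 30 + 25 * match(as.vector(base), cls$label)
    mri_data <- array(mri_map, shape)
    if (config$noise_scale > 0 && config$mri_noise_sd > 0) {
      mri_data <- mri_data + stats::rnorm(length(mri_data), 0,
                                          config$mri_noise_sd *
                                            config$noise_scale)
    }

    # sCT: degrade the noise-free CT of the sCT's own (pocket-free) anatomy
    se <- config$sct_error
    labels_sct <- base
    sct_clean <- labels_to_hu(labels_sct, cls)
    bone_labels <- cls$label[grepl("bone|cortical", cls$name)]
    bone_idx <- which(array(labels_sct %in% bone_labels, shape))
    if (se$bone_miss_fraction > 0 && length(bone_idx) > 0) {
      n_miss <- round(se$bone_miss_fraction * length(bone_idx))
      # isolated substream: varying the error level must leave the
      # acquisition noise of CT/MRI/CBCT untouched
      miss <- with_seed(config$seed + 7919L, sample(bone_idx, n_miss))
      sct_clean[miss] <- cls$hu[match("muscle", cls$name)]
      bone_idx <- setdiff(bone_idx, miss)
    }
    if (se$bone_hu_bias != 0) {
      sct_clean[bone_idx] <- sct_clean[bone_idx] + se$bone_hu_bias
    }
    if (se$blur_sigma_mm > 0) {
      sct_clean <- gauss_blur3(sct_clean, se$blur_sigma_mm / spacing)
    }
    sct_data <- clamp_hu(sct_clean)

    # CBCT: distortion of the noise-free CT of the CBCT anatomy, plus noise
    dp <- config$cbct_distortion
    if (is.null(dp$center_xy)) dp$center_xy <- g$ctr[1:2]
    if (is.null(dp$rmax_mm)) dp$rmax_mm <- max(g$a, g$b)
    co <- grid_coords(shape, spacing)
    pos <- cbind(rep(co$x, times = shape[2] * shape[3]),
                 rep(rep(co$y, each = shape[1]), times = shape[3]))
    cbct_clean <- labels_to_hu(labels_cbct, cls)
    cbct_data <- apply_cbct_distortion(as.vector(cbct_clean), pos, dp)
    if (dp$noise_sd_HU > 0) {
      cbct_data <- cbct_data + stats::rnorm(length(cbct_data), 0,
                                            dp$noise_sd_HU)
    }
    cbct_data <- clamp_hu(array(cbct_data, shape))

    body_of <- function(scale, labels) {
      co <- grid_coords(shape, spacing)
      ellipse_field(co, shape, g$ctr, g$a * scale, g$b * scale) <= 1
    }
    truth <- list(
      labels = labels_ct, labels_ct = labels_ct, labels_cbct = labels_cbct,
      labels_sct = labels_sct,
      body = list(sct = body_of(1), ct = body_of(scale_ct),
                  cbct = body_of(scale_cbct)),
      density = list(
        ct = list(RED = labels_to_density(labels_ct, cls, "RED"),
                  DES = labels_to_density(labels_ct, cls, "DES")),
        cbct = list(RED = labels_to_density(labels_cbct, cls, "RED"),
                    DES = labels_to_density(labels_cbct, cls, "DES"))),
      pockets = list(common = common_idx, ct = pk_ct$idx, cbct = pk_cb$idx),
      distortion = dp,
      cbct_source_clean = cbct_clean,
      outline_scales = c(sct = 1, ct = scale_ct, cbct = scale_cbct),
      seed = config$seed)

    mk <- function(data, space = "HU") {
      volume(data, spacing = spacing, origin = c(0, 0, 0),
             value_space = space)
    }
    structure(list(ct = mk(ct_data), mri = mk(mri_data, "RAW"),
                   sct = mk(sct_data), cbct = mk(cbct_data),
                   truth = truth, config = config),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, seed %d\n",
              paste(dim(x$ct$data), collapse = " x "), x$truth$seed))
  cat(sprintf("  pocket voxels: %d common, %d CT-only, %d CBCT-only\n",
              length(x$truth$pockets$common),
              length(x$truth$pockets$ct), length(x$truth$pockets$cbct)))
  invisible(x)
}

#' Analytically displaced phantom CT
#'
#' Samples the phantom anatomy rigidly moved by \code{tf} directly from
#' its analytic geometry — no resampling or interpolation is involved, so
#' the pair (reference CT, displaced CT) relates by exactly \code{tf},
#' like two acquisitions of one patient in different poses. Transient
#' pockets are omitted (they are session anatomy, not patient pose).
#'
#' @param config a [phantom_config()].
#' @param tf a [rigid_transform()] moving the anatomy; the identity gives
#'   the base (pocket-free) CT.
#' @param seed RNG seed for the acquisition noise; defaults to
#'   \code{config$seed + 1}.
#' @param supersample sub-voxel sampling factor per axis emulating the
#'   scanner's partial-volume averaging; 2 averages 8 sample points per
#'   voxel.
#' @return an HU [volume()].
#' @export
displaced_phantom_ct <- function(config = phantom_config(),
                                 tf = rigid_transform(),
                                 seed = NULL, supersample = 2L) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape
  spacing <- config$spacing
  # same anatomy as generate_case() for this seed
  g <- phantom_geometry(shape, spacing,
                        with_seed(config$seed, draw_anatomy_variation()))
  cls <- config$tissue_classes
  co <- grid_coords(shape, spacing)
  pts <- cbind(rep(co$x, times = shape[2] * shape[3]),
               rep(rep(co$y, each = shape[1]), times = shape[3]),
               rep(co$z, each = shape[1] * shape[2]))
  Ti <- tf_invert(tf)
  s <- max(1L, as.integer(supersample))
  subs <- (seq_len(s) - (s + 1) / 2) / s  # sub-voxel offsets, voxel units
  hu <- 0
  for (ox in subs) for (oy in subs) for (oz in subs) {
    p <- pts
    p[, 1] <- p[, 1] + ox * spacing[1]
    p[, 2] <- p[, 2] + oy * spacing[2]
    p[, 3] <- p[, 3] + oz * spacing[3]
    src <- tf_apply(Ti, p)
    lab <- phantom_labels_points(src[, 1], src[, 2], src[, 3], g, cls)
    hu <- hu + cls$hu[match(lab, cls$label)]
  }
  hu <- array(hu / s^3, shape)
  # dominant label at voxel centre, for the noise model
  src0 <- tf_apply(Ti, pts)
  labels <- array(phantom_labels_points(src0[, 1], src0[, 2], src0[, 3],
                                        g, cls), shape)
  with_seed(seed %||% (config$seed + 1L), {
    data <- clamp_hu(hu + class_noise(labels, cls, config$noise_scale))
    volume(data, spacing, c(0, 0, 0), "HU")
  })
}

#' Generate a density-insert calibration phantom
#'
#' Emulates the cylindrical plastic calibration phantom with known-density
#' inserts used for conventional CBCT calibration: a soft-tissue
#' equivalent cylinder containing small cylindrical inserts, imaged
#' without the patient-specific scatter distortion. Used to build the
#' "phantom" calibration curve that [population_curve()] is compared
#' against.
#'
#' @param inserts data.frame with columns \code{hu}, \code{red},
#'   \code{des}; defaults to the phantom tissue classes.
#' @param shape,spacing grid of the phantom scan.
#' @param noise_sd_HU additive noise on the scan.
#' @param seed RNG seed.
#' @return list with \code{scan} (an HU [volume()]) and \code{rois}
#'   (per insert: \code{voxels} linear indices, \code{red}, \code{des}).
#' @export
insert_phantom <- function(inserts = NULL, shape = c(64, 64, 12),
                           spacing = c(3, 3, 3), noise_sd_HU = 0,
                           seed = 1L) {
  if (is.null(inserts)) {
    cls <- default_tissue_classes()
    inserts <- data.frame(hu = cls$hu, red = cls$red, des = cls$des)
  }
  shape <- as.integer(shape)
  co <- grid_coords(shape, spacing)
  ctr <- (shape - 1) * spacing / 2
  fov <- shape * spacing
  R <- 0.45 * min(fov[1:2])
  rho2 <- outer((co$x - ctr[1])^2, (co$y - ctr[2])^2, `+`)
  body <- array(rep(rho2 <= R^2, shape[3]), shape)
  data <- array(-1000, shape)
  data[body] <- 40  # plastic scatter body, water-like
  n <- nrow(inserts)
  rois <- vector("list", n)
  r_ins <- 0.12 * R
  for (i in seq_len(n)) {
    ang <- 2 * pi * (i - 1) / n
    cen <- c(ctr[1] + 0.6 * R * cos(ang), ctr[2] + 0.6 * R * sin(ang))
    m2 <- outer((co$x - cen[1])^2, (co$y - cen[2])^2, `+`) <= r_ins^2
    m <- array(rep(m2, shape[3]), shape)
    data[m] <- inserts$hu[i]
    rois[[i]] <- list(voxels = which(m), red = inserts$red[i],
                      des = inserts$des[i], hu_nominal = inserts$hu[i])
  }
  with_seed(seed, {
    if (noise_sd_HU > 0) {
      data <- data + stats::rnorm(length(data), 0, noise_sd_HU)
    }
    data <- clamp_hu(data)
  })
  list(scan = volume(array(data, shape), spacing = spacing,
                     origin = c(0, 0, 0), value_space = "HU"),
       rois = rois)
}
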