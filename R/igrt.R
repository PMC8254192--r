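#' 6-DOF rigid transform
#'
#' Translations along the patient axes (AP: anterior-posterior, LR:
#' left-right, CC: cranio-caudal) in mm and intrinsic rotations pitch
#' (about LR), roll (about AP), yaw (about CC) in degrees, applied about
#' \code{center}. Internally the world axes are (x, y, z) = (LR, AP, CC)
#' and the rotation matrix is \code{Rx(pitch) Ry(roll) Rz(yaw)}.
#'
#' @param translations named or ordered numeric: AP, LR, CC in mm.
#' @param rotations named or ordered numeric: pitch, roll, yaw in degrees,
#'   each within (-180, 180].
#' @param center world rotation centre in mm (x, y, z).
#' @return list of class \code{rigid_transform}.
#' @export
rigid_transform <- function(translations = c(AP = 0, LR = 0, CC = 0),
                            rotations = c(pitch = 0, roll = 0, yaw = 0),
                            center = c(0, 0, 0)) {
  tr <- as.numeric(translations)
  ro <- as.numeric(rotations)
  if (length(tr) != 3L || length(ro) != 3L) stopf("need 3 + 3 parameters")
  if (any(ro <= -180 | ro > 180)) stopf("rotations must lie in (-180, 180]")
  structure(list(translations = stats::setNames(tr, c("AP", "LR", "CC")),
                 rotations = stats::setNames(ro, c("pitch", "roll", "yaw")),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> AP %.2f, LR %.2f, CC %.2f mm | pitch %.2f, roll %.2f, yaw %.2f deg\n",
    x$translations["AP"], x$translations["LR"], x$translations["CC"],
    x$rotations["pitch"], x$rotations["roll"], x$rotations["yaw"]))
  invisible(x)
}

rot_matrix <- function(rotations_deg) {
  r <- rotations_deg * pi / 180
  cp <- cos(r[1]); sp <- sin(r[1])   # pitch about x (LR)
  cr <- cos(r[2]); sr <- sin(r[2])   # roll about y (AP)
  cy <- cos(r[3]); sy <- sin(r[3])   # yaw about z (CC)
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  Ry <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# world translation vector (x, y, z) = (LR, AP, CC) from the AP/LR/CC fields
tf_tvec <- function(tf) {
  c(tf$translations["LR"], tf$translations["AP"], tf$translations["CC"])
}

#' Apply a rigid transform to world points
#'
#' @param tf a [rigid_transform()].
#' @param pts N x 3 matrix of world coordinates (x = LR, y = AP, z = CC).
#' @return transformed N x 3 matrix.
#' @export
tf_apply <- function(tf, pts) {
  R <- rot_matrix(tf$rotations)
  ctr <- tf$center
  tv <- tf_tvec(tf)
  sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + tv, `+`)
}

# recover pitch/roll/yaw (deg) from a rotation matrix composed as Rx Ry Rz
angles_from_matrix <- function(R) {
  roll <- asin(max(-1, min(1, R[1, 3])))
  yaw <- atan2(-R[1, 2], R[1, 1])
  pitch <- atan2(-R[2, 3], R[3, 3])
  c(pitch = pitch, roll = roll, yaw = yaw) * 180 / pi
}

#' Invert a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @return the inverse transform, with the same rotation centre.
#' @export
tf_invert <- function(tf) {
  R <- rot_matrix(tf$rotations)
  Ri <- t(R)
  tv <- tf_tvec(tf)
  ctr <- tf$center
  # forward: y = R (x - c) + c + t  =>  x = Ri (y - c - t) + c
  #        = Ri (y - c) + c + [Ri (-t) + (Ri - I) %*% ... ] -- solve directly:
  ti <- as.vector(Ri %*% (-tv))
  ang <- angles_from_matrix(Ri)
  rigid_transform(
    translations = c(AP = ti[2], LR = ti[1], CC = ti[3]),
    rotations = ang, center = ctr)
}

#' Compose two rigid transforms (first \code{a}, then \code{b})
#'
#' Both must share a rotation centre.
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composition as a \code{rigid_transform}.
#' @export
tf_compose <- function(a, b) {
  if (any(abs(a$center - b$center) > 1e-9)) {
    stopf("transforms must share a rotation centre")
  }
  Ra <- rot_matrix(a$rotations)
  Rb <- rot_matrix(b$rotations)
  R <- Rb %*% Ra
  ta <- tf_tvec(a); tb <- tf_tvec(b)
  t_new <- as.vector(Rb %*% ta) + tb
  ang <- angles_from_matrix(R)
  rigid_transform(
    translations = c(AP = t_new[2], LR = t_new[1], CC = t_new[3]),
    rotations = ang, center = a$center)
}

# voxel world coordinates of a set of linear indices
voxel_world <- function(vol, idx) {
  d <- dim(vol$data)
  i0 <- idx - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  cbind(vol$origin[1] + x * vol$spacing[1],
        vol$origin[2] + y * vol$spacing[2],
        vol$origin[3] + z * vol$spacing[3])
}

# foreground threshold for centre-of-mass / MI masking
fg_threshold <- function(vol) {
  if (vol$value_space == "HU") -300 else {
    r <- range(vol$data)
    r[1] + 0.1 * diff(r)
  }
}

histogram_mi <- function(x, y, nbins = 32) {
  bx <- cut(x, breaks = nbins, labels = FALSE)
  by <- cut(y, breaks = nbins, labels = FALSE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Resample a volume under a rigid transform
#'
#' Produces the image of \code{vol} moved by \code{tf} on the original
#' grid: the output voxel at world position w takes the input value at
#' \code{tf^-1(w)}. Useful for constructing displaced volumes with known
#' ground-truth transforms.
#'
#' @param vol input volume.
#' @param tf a [rigid_transform()].
#' @param method interpolation, \code{"trilinear"} or \code{"nearest"}.
#' @return transformed volume on the same grid.
#' @export
transform_volume <- function(vol, tf, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_volume(vol), inherits(tf, "rigid_transform"))
  d <- dim(vol$data)
  pts <- voxel_world(vol, seq_len(prod(d)))
  src <- tf_apply(tf_invert(tf), pts)
  ix <- (src[, 1] - vol$origin[1]) / vol$spacing[1]
  iy <- (src[, 2] - vol$origin[2]) / vol$spacing[2]
  iz <- (src[, 3] - vol$origin[3]) / vol$spacing[3]
  fill <- if (vol$value_space == "HU") -1024 else 0
  vals <- if (method == "trilinear") {
    tri_interp(vol$data, ix, iy, iz, fill = fill)
  } else {
    nn_interp(vol$data, ix, iy, iz, fill = fill)
  }
  if (vol$value_space == "HU") vals <- clamp_hu(vals)
  volume(array(vals, d), vol$spacing, vol$origin, vol$value_space)
}

#' Markerless 6-DOF rigid registration
#'
#' Registers \code{moving} (the planning CT, sCT or MRI) to \code{fixed}
#' (the CBCT). For HU-valued moving images the similarity is the mean
#' squared intensity difference evaluated only at moving voxels inside
#' the bone window (the clinical bone-match strategy for elective
#' lymph-node irradiation); for MRI no intensity constraint is applied
#' and a 32-bin histogram mutual information over body voxels is
#' maximized instead. Optimization is Nelder-Mead from a centre-of-mass
#' translation initialization, run at three point-subsampling resolutions;
#' the result is deterministic given the inputs.
#'
#' @param moving,fixed volumes; \code{moving} HU (CT/sCT) or RAW (MRI).
#' @param bone_window HU interval defining bone in the moving image.
#' @param max_points similarity evaluation points at the finest level.
#' @param similarity \code{"auto"} picks MSE for HU and MI for RAW input.
#' @param smooth_mm Gaussian pre-smoothing applied identically to both
#'   images before matching; equalizing the two images' effective point
#'   spread suppresses the resampling bias that otherwise displaces the
#'   similarity optimum by a fraction of a voxel.
#' @return a [rigid_transform()] mapping moving world coordinates onto
#'   fixed world coordinates, with the attained similarity in
#'   \code{attr(, "similarity")}.
#' @export
rigid_register <- function(moving, fixed, bone_window = c(100, 4000),
                           max_points = 6000,
                           similarity = c("auto", "mse", "mi"),
                           smooth_mm = 2) {
  stopifnot(is_volume(moving), is_volume(fixed))
  similarity <- match.arg(similarity)
  if (similarity == "auto") {
    similarity <- if (moving$value_space == "HU") "mse" else "mi"
  }
  if (smooth_mm > 0) {
    # blurred HU stays within the HU range (convex combination)
    moving <- volume(gauss_blur3(moving$data, smooth_mm / moving$spacing),
                     moving$spacing, moving$origin, moving$value_space)
    fixed <- volume(gauss_blur3(fixed$data, smooth_mm / fixed$spacing),
                    fixed$spacing, fixed$origin, fixed$value_space)
  }
  if (similarity == "mse") {
    sel <- which(moving$data >= bone_window[1] & moving$data <= bone_window[2])
    if (length(sel) < 500L) {
      stopf("empty bone mask: < 500 moving voxels in [%g, %g] HU",
            bone_window[1], bone_window[2])
    }
  } else {
    sel <- which(moving$data > fg_threshold(moving))
    if (length(sel) < 500L) stopf("too few foreground voxels for MI")
  }
  pts_all <- voxel_world(moving, sel)
  vals_all <- moving$data[sel]

  # centre-of-mass initialization
  mv_fg <- moving$data > fg_threshold(moving)
  fx_fg <- fixed$data > fg_threshold(fixed)
  com <- function(vol, fg) {
    w <- voxel_world(vol, which(fg))
    colMeans(w)
  }
  t0 <- com(fixed, fx_fg) - com(moving, mv_fg)
  d <- dim(fixed$data)
  center <- fixed$origin + (d - 1) * fixed$spacing / 2

  objective <- function(par, pts, vals) {
    tf <- rigid_transform(c(AP = par[2], LR = par[1], CC = par[3]),
                          c(pitch = par[4], roll = par[5], yaw = par[6]),
                          center = center)
    w <- tf_apply(tf, pts)
    ix <- (w[, 1] - fixed$origin[1]) / fixed$spacing[1]
    iy <- (w[, 2] - fixed$origin[2]) / fixed$spacing[2]
    iz <- (w[, 3] - fixed$origin[3]) / fixed$spacing[3]
    fv <- tri_interp(fixed$data, ix, iy, iz, fill = NA_real_)
    inb <- !is.na(fv)
    frac <- mean(inb)
    if (frac < 0.25) return(1e12)
    if (similarity == "mse") {
      mean((vals[inb] - fv[inb])^2) / frac
    } else {
      -histogram_mi(vals[inb], fv[inb]) / frac
    }
  }

  par <- c(t0[1], t0[2], t0[3], 0, 0, 0)
  # coarse-to-fine point subsampling; deterministic strides
  n <- nrow(pts_all)
  for (lev in c(4L, 2L, 1L, 1L)) {  # final pass restarts the simplex
    stride <- max(1L, floor(n / max(50L, max_points %/% lev)))
    take <- seq(1L, n, by = stride * lev)
    pts <- pts_all[take, , drop = FALSE]
    vals <- vals_all[take]
    opt <- stats::optim(
      par, objective, pts = pts, vals = vals, method = "Nelder-Mead",
      control = list(maxit = if (lev == 4L) 600 else 800,
                     reltol = 1e-10))
    par <- opt$par
  }
  tf <- rigid_transform(c(AP = par[2], LR = par[1], CC = par[3]),
                        c(pitch = par[4], roll = par[5], yaw = par[6]),
                        center = center)
  attr(tf, "similarity") <- opt$value
  tf
}

#' Match-difference table relative to the CT reference
#'
#' For each (case, CBCT fraction), the difference of each modality's
#' registration parameters from the CT-CBCT registration is computed per
#' degree of freedom; the CT difference is identically zero by
#' construction. Pooled per-DOF mean and standard deviation are reported
#' per modality.
#'
#' @param matches data.frame with columns \code{case}, \code{fraction},
#'   \code{modality} (must include \code{"CT"} per case/fraction) and the
#'   six DOF columns \code{AP, LR, CC, pitch, roll, yaw}.
#' @return list of class \code{delta_table}: \code{rows} (per
#'   case/fraction/modality deltas) and \code{summary} (per modality and
#'   DOF: mean, sd, n).
#' @export
compute_deltas <- function(matches) {
  dofs <- c("AP", "LR", "CC", "pitch", "roll", "yaw")
  stopifnot(all(c("case", "fraction", "modality", dofs) %in% names(matches)))
  key <- interaction(matches$case, matches$fraction, drop = TRUE)
  rows <- NULL
  for (k in levels(key)) {
    grp <- matches[key == k, , drop = FALSE]
    ct <- grp[grp$modality == "CT", , drop = FALSE]
    if (nrow(ct) != 1L) {
      stopf("missing (or duplicated) CT reference match for %s", k)
    }
    for (i in seq_len(nrow(grp))) {
      delta <- as.numeric(grp[i, dofs]) - as.numeric(ct[1, dofs])
      rows <- rbind(rows, cbind(
        data.frame(case = grp$case[i], fraction = grp$fraction[i],
                   modality = grp$modality[i], stringsAsFactors = FALSE),
        stats::setNames(as.data.frame(as.list(delta)), dofs)))
    }
  }
  summ <- NULL
  for (mod in setdiff(unique(rows$modality), "CT")) {
    sub <- rows[rows$modality == mod, , drop = FALSE]
    for (dof in dofs) {
      summ <- rbind(summ, data.frame(
        modality = mod, dof = dof, mean = mean(sub[[dof]]),
        sd = stats::sd(sub[[dof]]), n = nrow(sub),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(rows = rows, summary = summ), class = "delta_table")
}

#' One-sample Wilcoxon signed-rank test against a hypothesized centre
#'
#' Two-sided; exact when the non-zero differences are untied, midranks
#' with normal approximation otherwise. A sample identically equal to
#' \code{mu} carries no evidence against the null and reports p = 1.
#'
#' @param x numeric sample.
#' @param mu hypothesized centre.
#' @return the two-sided p-value.
#' @export
signed_rank_test <- function(x, mu = 0) {
  d <- x - mu
  if (all(d == 0)) return(1)
  exact <- !any(duplicated(abs(d[d != 0]))) && !any(d == 0)
  suppressWarnings(
    stats::wilcox.test(x, mu = mu, alternative = "two.sided",
                       exact = exact)$p.value)
}

#' Significance of match differences from zero
#'
#' Per modality and degree of freedom: Shapiro-Wilk normality p-value of
#' the delta sample and a two-sided one-sample Wilcoxon signed-rank test
#' against zero (exact for small untied samples). An all-zero sample has
#' no evidence against the null and reports p = 1.
#'
#' @param deltas a [compute_deltas()] result.
#' @param min_n minimum sample size per DOF.
#' @return data.frame with modality, dof, n, shapiro_p, p.
#' @export
delta_significance <- function(deltas, min_n = 5L) {
  stopifnot(inherits(deltas, "delta_table"))
  dofs <- c("AP", "LR", "CC", "pitch", "roll", "yaw")
  out <- NULL
  for (mod in setdiff(unique(deltas$rows$modality), "CT")) {
    sub <- deltas$rows[deltas$rows$modality == mod, , drop = FALSE]
    for (dof in dofs) {
      x <- sub[[dof]]
      if (length(x) < min_n) {
        stopf("need >= %d rows per DOF, got %d for %s/%s", min_n,
              length(x), mod, dof)
      }
      sp <- if (diff(range(x)) > 0) {
        tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
      } else NA_real_
      out <- rbind(out, data.frame(modality = mod, dof = dof, n = length(x),
                                   shapiro_p = sp, p = signed_rank_test(x),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Serialize a rigid transform to JSON
#'
#' @param tf a [rigid_transform()].
#' @param path output path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(
    list(translations_mm = as.list(tf$translations),
         rotations_deg = as.list(tf$rotations),
         center_mm = tf$center),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(unlist(j$translations_mm), unlist(j$rotations_deg),
                  j$center_mm)
}
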