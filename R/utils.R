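# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never disturb it.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Shift a 3D logical array by one voxel along `axis` (+1 or -1 step),
# padding with FALSE. Used by the flood-fill primitives.
shift_logical <- function(a, axis, step) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (step > 0) {
    idx_src[[axis]] <- seq_len(d[axis] - 1L)
    idx_dst[[axis]] <- seq(2L, d[axis])
  } else {
    idx_src[[axis]] <- seq(2L, d[axis])
    idx_dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-connected flood fill: grow `seeds` (logical array or indices) inside
# `mask` until stable.
flood_select <- function(mask, seeds) {
  idx <- if (is.logical(seeds)) which(seeds) else as.integer(seeds)
  array(cpp_flood(as.vector(mask), dim(mask), idx), dim(mask))
}

# Largest 6-connected component of a logical array.
largest_component <- function(mask) {
  lab <- cpp_label_components(as.vector(mask), dim(mask))
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  counts <- tabulate(lab)
  array(lab == which.max(counts), dim(mask))
}

# Fill interior holes: background connected to the array border stays
# background, everything else becomes foreground.
fill_holes <- function(mask) {
  bg <- !mask
  border <- array(FALSE, dim(mask))
  d <- dim(mask)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  outside <- flood_select(bg, which(border & bg))
  mask | (bg & !outside)
}

# Separable Gaussian blur of a 3D array; sigma in voxels per axis.
# Edge handling is replication. sigma <= 0 on an axis skips that axis.
gauss_blur3 <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    # index matrix with replicated edges
    idx <- outer(seq_len(n), seq(-half, half), `+`)
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    out <- matrix(0, nrow = dm[1], ncol = ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * m[idx[, j], , drop = FALSE]
    }
    dim(out) <- dm
    arr <- aperm(out, order(perm))
  }
  arr
}

# Trilinear interpolation of `arr` at fractional 0-based voxel coordinates.
# Points with any support outside the array get `fill`.
tri_interp <- function(arr, ix, iy, iz, fill = NA_real_) {
  d <- dim(arr)
  ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
    iz >= 0 & iz <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(ix))
  if (!any(ok)) return(out)
  x <- ix[ok]; y <- iy[ok]; z <- iz[ok]
  x0 <- pmin(floor(x), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(x))
  if (d[2] == 1) y0 <- rep(0, length(y))
  if (d[3] == 1) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(i, j, k) arr[1 + i + d[1] * (j + d[2] * k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
  out[ok] <- v
  out
}

# Nearest-neighbour interpolation, same conventions as tri_interp().
nn_interp <- function(arr, ix, iy, iz, fill = NA_real_) {
  d <- dim(arr)
  rx <- round(ix); ry <- round(iy); rz <- round(iz)
  ok <- rx >= 0 & rx <= d[1] - 1 & ry >= 0 & ry <= d[2] - 1 &
    rz >= 0 & rz <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(ix))
  out[ok] <- arr[1 + rx[ok] + d[1] * (ry[ok] + d[2] * rz[ok])]
  out
}
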