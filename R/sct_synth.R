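#' Multi-atlas of co-registered MRI/CT pairs
#'
#' @param entries list of entries, each a list with \code{case_id},
#'   \code{mri} and \code{ct} ([volume()] objects on one common grid).
#' @return list of class \code{sct_atlas}.
#' @export
sct_atlas <- function(entries) {
  if (length(entries) == 0L) stopf("empty atlas")
  ids <- vapply(entries, function(e) as.character(e$case_id), "")
  if (anyDuplicated(ids)) stopf("duplicate case_ids in atlas")
  ref <- entries[[1]]$mri
  for (e in entries) {
    stopifnot(is_volume(e$mri), is_volume(e$ct))
    if (!same_grid(e$mri, e$ct) || !same_grid(e$mri, ref)) {
      stopf("all atlas volumes must share one grid")
    }
  }
  structure(list(entries = entries, case_ids = ids), class = "sct_atlas")
}

#' Patch query parameters
#'
#' @param patch_size odd voxel extent per axis of the intensity patch.
#' @param k number of nearest atlas patches blended per voxel.
#' @param search_radius voxel offset bound around the spatially
#'   corresponding atlas location.
#' @return list of class \code{patch_query}.
#' @export
patch_query <- function(patch_size = c(5, 5, 3), k = 5, search_radius = 4) {
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3L || any(patch_size < 1L) ||
      any(patch_size %% 2L == 0L)) {
    stopf("patch_size must be three odd values >= 1")
  }
  if (k < 1L) stopf("k must be >= 1")
  if (search_radius < 0L) stopf("search_radius must be >= 0")
  structure(list(patch_size = patch_size, k = as.integer(k),
                 search_radius = as.integer(search_radius)),
            class = "patch_query")
}

#' L2-normalized patch distance
#'
#' Euclidean distance between two patch vectors after each is scaled to
#' unit L2 norm — invariant to global intensity scaling, with range
#' [0, 2]. If either patch is all-zero the unnormalized Euclidean
#' distance is used as a fallback.
#'
#' @param p,q equal-length numeric patch vectors.
#' @return scalar distance.
#' @export
patch_distance <- function(p, q) {
  if (length(p) != length(q)) stopf("patch vectors must have equal length")
  np <- sqrt(sum(p^2))
  nq <- sqrt(sum(q^2))
  if (np > 0 && nq > 0) {
    sqrt(max(0, sum((p / np - q / nq)^2)))
  } else {
    sqrt(sum((p - q)^2))
  }
}

#' Patch-based multi-atlas sCT synthesis
#'
#' For every target voxel the MRI patch around it is compared, with the
#' L2-normalized intensity distance, against atlas MRI patches at all
#' offsets within \code{search_radius} of the corresponding location in
#' every atlas entry. The \code{k} most similar patches' center CT values
#' are blended with Gaussian weights \eqn{\exp(-d^2/h^2)} (h = mean of
#' the k distances) into the synthetic CT value. Border patches are
#' edge-replicated; candidate offsets are visited center-first so exact
#' matches at the corresponding location win ties, making the synthesis
#' deterministic.
#'
#' @param mri query MRI volume on the atlas grid.
#' @param atlas an [sct_atlas()]; must not contain the query case.
#' @param query a [patch_query()].
#' @param query_id case id of the query; an error is raised if it is
#'   present in the atlas (leave-one-out discipline).
#' @param mask optional logical array restricting synthesis to a region
#'   (e.g. the body); voxels outside get \code{fill}.
#' @param fill HU value for unsynthesized voxels.
#' @return synthetic CT as an HU [volume()].
#' @export
synthesize_sct <- function(mri, atlas, query = patch_query(),
                           query_id = NULL, mask = NULL, fill = -1000) {
  stopifnot(is_volume(mri), inherits(atlas, "sct_atlas"),
            inherits(query, "patch_query"))
  if (!same_grid(mri, atlas$entries[[1]]$mri)) {
    stopf("query MRI must be on the atlas grid (resample first)")
  }
  if (!is.null(query_id) && as.character(query_id) %in% atlas$case_ids) {
    stopf("query case '%s' present in atlas: leave-one-out violated",
          query_id)
  }
  d <- dim(mri$data)
  target <- if (is.null(mask)) seq_len(prod(d)) else which(mask)
  if (length(target) == 0L) stopf("empty synthesis mask")
  half <- (query$patch_size - 1L) %/% 2L
  res <- cpp_patch_synth(
    as.vector(mri$data),
    lapply(atlas$entries, function(e) as.vector(e$mri$data)),
    lapply(atlas$entries, function(e) as.vector(e$ct$data)),
    as.integer(d), as.integer(half), query$k, query$search_radius,
    as.integer(target), fill)
  volume(array(res, d), mri$spacing, mri$origin, "HU")
}
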