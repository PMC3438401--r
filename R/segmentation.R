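#' Two-threshold segmentation thresholds
#'
#' @param t_bone Lower threshold: intensities in `[t_bone, t_cement)` become
#'   bone.
#' @param t_cement Upper threshold: intensities `>= t_cement` become cement.
#'   Intensity equal to a threshold is assigned to the upper class.
#' @return A `segmentation_thresholds` object.
#' @export
segmentation_thresholds <- function(t_bone, t_cement) {
  if (!is.finite(t_bone) || !is.finite(t_cement) || t_bone >= t_cement)
    stopf("thresholds must be finite with t_bone < t_cement")
  structure(list(t_bone = t_bone, t_cement = t_cement),
            class = "segmentation_thresholds")
}

#' Automatic two-threshold selection
#'
#' Automated surrogate for choosing thresholds by visual observation:
#' three-class multi-level Otsu thresholding, maximizing the between-class
#' variance of the intensity histogram over all threshold pairs. The result is
#' always overridable by an explicit [segmentation_thresholds()].
#'
#' @param volume A [grayscale_volume()] with three distinguishable modes
#'   (background, bone, cement).
#' @param n_bins Number of histogram bins (default 256).
#' @return A [segmentation_thresholds()] object.
#' @export
auto_thresholds <- function(volume, n_bins = 256L) {
  stopifnot(inherits(volume, "grayscale_volume"))
  v <- as.vector(volume$data)
  rng <- range(v)
  if (rng[1] == rng[2]) stopf("degenerate (constant) image: cannot threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- h / sum(h)
  # cumulative zeroth and first moments
  P <- cumsum(w)
  M <- cumsum(w * mids)
  mu_T <- M[n_bins]
  class_term <- function(p0, p1, m0, m1) {
    wk <- p1 - p0
    ifelse(wk > 0, (m1 - m0)^2 / wk, 0)
  }
  best <- -Inf
  best_ij <- c(NA_integer_, NA_integer_)
  for (i in 1:(n_bins - 2L)) {
    p1 <- P[i]; m1 <- M[i]
    if (p1 <= 0) next
    j <- (i + 1L):(n_bins - 1L)
    sigma <- class_term(0, p1, 0, m1) +
      class_term(p1, P[j], m1, M[j]) +
      class_term(P[j], 1, M[j], mu_T)
    k <- which.max(sigma)
    if (sigma[k] > best) {
      best <- sigma[k]
      best_ij <- c(i, j[k])
    }
  }
  if (!is.finite(best)) stopf("could not find two thresholds (degenerate histogram)")
  segmentation_thresholds(edges[best_ij[1] + 1L], edges[best_ij[2] + 1L])
}

#' Segment a grayscale volume into background / bone / cement
#'
#' Pure two-threshold classification: intensity below `t_bone` is background,
#' in `[t_bone, t_cement)` bone, at or above `t_cement` cement. Voxels of an
#' optional marker mask are re-coded as markers (code 3) afterwards.
#'
#' @param volume A [grayscale_volume()].
#' @param thresholds A [segmentation_thresholds()] object.
#' @param marker_mask Optional logical array (same dimensions) of marker
#'   voxels.
#' @return A [label_volume()].
#' @export
segment <- function(volume, thresholds, marker_mask = NULL) {
  stopifnot(inherits(volume, "grayscale_volume"),
            inherits(thresholds, "segmentation_thresholds"))
  a <- volume$data
  lab <- (a >= thresholds$t_bone) + (a >= thresholds$t_cement)
  storage.mode(lab) <- "integer"
  if (!is.null(marker_mask)) {
    stopifnot(identical(dim(marker_mask), dim(a)))
    lab[marker_mask] <- LBL[["marker"]]
  }
  out <- label_volume(lab, volume$voxel_size, volume$origin)
  attributes(out)["specimen"] <- attributes(volume)["specimen"]
  out
}

#' Remove small disconnected solid components
#'
#' Automated surrogate for manual slice-by-slice segmentation refinement:
#' solid components (bone or cement, 26-connectivity) smaller than
#' `min_component_voxels` are re-coded to background. Marker voxels are left
#' untouched. Removing more than 20% of the solid volume aborts with an error
#' (a symptom of badly chosen thresholds).
#'
#' @param label A [label_volume()].
#' @param min_component_voxels Minimum component size kept, voxels.
#' @return A list with elements `label` (the filtered [label_volume()]) and
#'   `report` (removed component sizes and totals).
#' @export
connectivity_filter <- function(label, min_component_voxels) {
  stopifnot(inherits(label, "label_volume"))
  solid <- solid_mask(label)
  total_solid <- sum(solid)
  cc <- .cc_label26(as.vector(solid), as.integer(dim(label$data)))
  ncomp <- attr(cc, "n_components")
  report <- list(removed_sizes = integer(), n_components = ncomp,
                 solid_voxels = total_solid, removed_voxels = 0L)
  if (ncomp > 0L) {
    sizes <- tabulate(cc[cc > 0L], nbins = ncomp)
    small <- which(sizes < min_component_voxels)
    if (length(small)) {
      removed <- sum(sizes[small])
      if (total_solid > 0L && removed > 0.2 * total_solid)
        stopf("connectivity filter would remove %.1f%% of the solid volume; check thresholds",
              100 * removed / total_solid)
      arr <- label$data
      arr[array(cc %in% small, dim = dim(arr))] <- LBL[["background"]]
      out <- label_volume(arr, label$voxel_size, label$origin)
      attributes(out)["specimen"] <- attributes(label)["specimen"]
      report$removed_sizes <- sort(sizes[small])
      report$removed_voxels <- removed
      return(list(label = out, report = report))
    }
  }
  list(label = label, report = report)
}
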