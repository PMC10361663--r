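# Spindle segmentation and pole-axis geometry from the reference channel.

#' Segment the spindle from a reference-channel frame
#'
#' Gaussian-smooths the image, applies an automatic global (Otsu)
#' threshold, keeps the largest connected component and fills its holes.
#' The result is checked for sanity: the mask must be non-empty and
#' brighter inside than outside, so an inverted-contrast input fails
#' loudly rather than returning an inverted mask.
#'
#' @param frame Numeric `Y x X` matrix (typically the tubulin-like
#'   reference channel).
#' @param smooth_sigma Gaussian smoothing sd in px before thresholding.
#' @return Logical `Y x X` mask.
#' @export
segment_spindle <- function(frame, smooth_sigma = 2) {
  if (sd(frame) == 0) stop_sf("segment_spindle: image is constant")
  sm <- EBImage::gblur(frame, sigma = smooth_sigma)
  rng <- range(sm)
  smn <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(smn))
  bin <- smn > th
  if (!any(bin)) stop_sf("segment_spindle: empty mask after thresholding")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  if (all(mask) || mean(frame[mask]) <= mean(frame[!mask]))
    stop_sf("segment_spindle: mask darker than background (inverted contrast?)")
  matrix(mask, nrow(frame), ncol(frame))
}

#' Locate the pole-to-pole axis and chromosome edges
#'
#' The poles are the extremal mask pixels along the mask's principal axis
#' (pole A is the one with the smaller image x). The chromosome edges —
#' the boundaries of the gap of reference (microtubule) staining — are the
#' half-depth crossings of the lowest-intensity trough of the pole-to-pole
#' reference profile around the spindle midpoint, in um from pole A;
#' user-supplied edges are echoed unchanged.
#'
#' @param mask Logical spindle mask.
#' @param ref_frame Reference-channel frame used for the gap profile
#'   (required unless `chrom_edges_um` is given).
#' @param pixel_size Pixel size (um/px).
#' @param chrom_edges_um Optional numeric length-2: user-supplied edges.
#' @param min_axis_ratio Minimum principal-axis elongation; rounder masks
#'   are rejected.
#' @return A `spindle_axis` list: `pole_a`, `pole_b` (px, `c(x, y)`),
#'   `chrom_edges_um`, `pixel_size`, `length_um`.
#' @export
find_axis <- function(mask, ref_frame = NULL, pixel_size = 1,
                      chrom_edges_um = NULL, min_axis_ratio = 1.2) {
  if (!any(mask)) stop_sf("find_axis: empty mask")
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  if (sqrt(eg$values[1] / max(eg$values[2], 1e-12)) < min_axis_ratio)
    stop_sf("find_axis: mask too round (axis ratio < %.2g)", min_axis_ratio)
  v <- eg$vectors[, 1]
  proj <- (pts[, 1] - ctr[1]) * v[1] + (pts[, 2] - ctr[2]) * v[2]
  pa <- pts[which.min(proj), ]
  pb <- pts[which.max(proj), ]
  if (pa[1] > pb[1] || (pa[1] == pb[1] && pa[2] > pb[2])) {
    tmp <- pa; pa <- pb; pb <- tmp
  }
  axis <- structure(list(pole_a = unname(pa), pole_b = unname(pb),
                         chrom_edges_um = NULL, pixel_size = pixel_size),
                    class = "spindle_axis")
  axis$length_um <- measure_spindle_length(axis)
  if (!is.null(chrom_edges_um)) {
    if (length(chrom_edges_um) != 2L)
      stop_sf("find_axis: `chrom_edges_um` must have length 2")
    axis$chrom_edges_um <- sort(as.numeric(chrom_edges_um))
  } else if (!is.null(ref_frame)) {
    axis$chrom_edges_um <- detect_chrom_edges(ref_frame, axis)
  }
  if (!is.null(axis$chrom_edges_um)) {
    e <- axis$chrom_edges_um
    if (e[1] <= 0 || e[2] >= axis$length_um)
      stop_sf("find_axis: chromosome edges must lie strictly between the poles")
  }
  axis
}

# Half-depth boundaries of the central trough of the reference profile.
detect_chrom_edges <- function(ref_frame, axis) {
  prof <- extract_profile(ref_frame, axis, width_um = 2)
  pos <- prof$position_um
  val <- prof$intensity
  L <- axis$length_um
  central <- pos > 0.25 * L & pos < 0.75 * L
  i_min <- which(central)[which.min(val[central])]
  shoulders <- (pos > 0.15 * L & pos < 0.35 * L) |
    (pos > 0.65 * L & pos < 0.85 * L)
  level <- (val[i_min] + median(val[shoulders])) / 2
  left <- i_min
  while (left > 1 && val[left] < level) left <- left - 1
  right <- i_min
  while (right < length(val) && val[right] < level) right <- right + 1
  if (left == i_min || right == i_min)
    stop_sf("find_axis: no reference-staining gap found around the midpoint")
  c(pos[left], pos[right])
}

#' Pole-to-pole spindle length
#'
#' Euclidean distance between the two poles times the pixel size.
#'
#' @param axis A `spindle_axis` from [find_axis()].
#' @return Length in um.
#' @export
measure_spindle_length <- function(axis) {
  sqrt(sum((axis$pole_a - axis$pole_b)^2)) * axis$pixel_size
}

#' @export
print.spindle_axis <- function(x, ...) {
  cat(sprintf("<spindle_axis> pole A (%g, %g) px, pole B (%g, %g) px, %.2f um\n",
              x$pole_a[1], x$pole_a[2], x$pole_b[1], x$pole_b[2],
              x$length_um))
  if (!is.null(x$chrom_edges_um))
    cat(sprintf("  chromosome edges at %.2f / %.2f um from pole A\n",
                x$chrom_edges_um[1], x$chrom_edges_um[2]))
  invisible(x)
}

#' Spindle-bound signal ratio
#'
#' Mean reporter intensity over the spindle mask divided by mean reference
#' intensity over the mask; both frames are expected registered and
#' background-subtracted.
#'
#' @param reporter,reference `Y x X` matrices.
#' @param mask Logical spindle mask.
#' @return Dimensionless ratio.
#' @export
spindle_bound_ratio <- function(reporter, reference, mask) {
  if (!any(mask)) stop_sf("spindle_bound_ratio: empty mask")
  mref <- mean(reference[mask])
  if (mref <= 0)
    stop_sf("spindle_bound_ratio: reference mean over mask is <= 0")
  mean(reporter[mask]) / mref
}
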