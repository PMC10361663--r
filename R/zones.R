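# Six-zone compartmentalization of the spindle mask:
# (bleached / unbleached half) x (pole / intermediate / chromosome zone).

ZONE_KEY <- tibble::tibble(
  zone_id = 1:6,
  half = rep(c("bleached", "unbleached"), each = 3),
  zone = rep(c("pole", "intermediate", "chromosome"), 2),
  roi = c("bleached_pole", "bleached_intermediate", "bleached_chromosome",
          "unbleached_pole", "unbleached_intermediate",
          "unbleached_chromosome"))

# axial position (um from pole A) of every pixel, as a Y x X matrix
axis_position_um <- function(dim_yx, axis) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  u <- (axis$pole_b - axis$pole_a)
  u <- u / sqrt(sum(u^2))
  xg <- matrix(1:nx, ny, nx, byrow = TRUE)
  yg <- matrix(1:ny, ny, nx)
  ((xg - axis$pole_a[1]) * u[1] + (yg - axis$pole_a[2]) * u[2]) *
    axis$pixel_size
}

#' Partition the spindle mask into six labeled zones
#'
#' The mask is split at the axis midpoint into two halves; the half
#' overlapping the bleach geometry is labeled "bleached". Each half is
#' divided into three equal-length bins along its pole-to-midpoint axis
#' segment, labeled pole, intermediate and chromosome from the pole
#' inward. Every mask pixel belongs to exactly one zone and the six zones
#' tile the mask exactly.
#'
#' @param mask Logical spindle mask.
#' @param axis A `spindle_axis` from [find_axis()].
#' @param bleach_range_um Numeric length-2: the axial interval (um from
#'   pole A) covered by the bleach geometry, e.g. from
#'   [event_axis_range()]. If the interval straddles the midpoint with
#'   more than 40% of its length on each side, the half assignment is
#'   ambiguous and an error is raised.
#' @return A `zone_set`: `labels` (integer `Y x X`, 0 outside the mask,
#'   1-6 per `key`), `key` (tibble zone_id/half/zone/roi), `axis`, and
#'   `bleached_side` (`"A"` if the pole-A half is bleached).
#' @export
compartmentalize <- function(mask, axis, bleach_range_um) {
  if (length(bleach_range_um) == 1L)
    bleach_range_um <- rep(bleach_range_um, 2)
  bleach_range_um <- sort(bleach_range_um)
  L <- axis$length_um
  mid <- L / 2
  span <- diff(bleach_range_um)
  frac_a <- if (span > 0) {
    (min(mid, bleach_range_um[2]) - min(mid, bleach_range_um[1])) / span
  } else as.numeric(bleach_range_um[1] < mid)
  if (frac_a > 0.4 && (1 - frac_a) > 0.4)
    stop_sf("compartmentalize: bleach geometry overlaps both halves by > 40%%; half assignment ambiguous")
  bleached_side <- if (frac_a >= 0.5) "A" else "B"

  s <- axis_position_um(dim(mask), axis)
  s <- pmin(pmax(s, 0), L)            # clamp corner projections into span
  half_a <- s < mid
  # distance from the owning pole, binned into three equal thirds
  d_pole <- ifelse(half_a, s, L - s)
  bin <- pmin(floor(d_pole / (mid / 3)), 2)   # 0 pole, 1 intermediate, 2 chromosome
  zone3 <- bin + 1
  labels <- matrix(0L, nrow(mask), ncol(mask))
  a_bleached <- bleached_side == "A"
  labels[mask] <- ifelse(half_a[mask] == a_bleached,
                         zone3[mask], zone3[mask] + 3L)
  structure(list(labels = labels, key = ZONE_KEY, axis = axis,
                 bleached_side = bleached_side),
            class = "zone_set")
}

#' Axial interval covered by a photo event
#'
#' Maps a simulator [photo_event()] (given in spindle-centred
#' coordinates) onto the axial coordinate of a detected axis (um from
#' pole A), assuming pole A is the left pole of the rendered field.
#'
#' @param event A [photo_event()].
#' @param axis A `spindle_axis`.
#' @return Numeric length-2 interval in um from pole A.
#' @export
event_axis_range <- function(event, axis) {
  L <- axis$length_um
  if (event$region == "half") {
    if (event$side == "left") c(0, L / 2) else c(L / 2, L)
  } else {
    ctr <- L / 2 + event$center_x_um
    pmin(pmax(c(ctr - event$width_um / 2, ctr + event$width_um / 2), 0), L)
  }
}

#' @export
print.zone_set <- function(x, ...) {
  n <- tabulate(x$labels[x$labels > 0], 6)
  cat("<zone_set> pixels per zone:\n")
  print(dplyr::mutate(x$key, n_px = n))
  invisible(x)
}
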