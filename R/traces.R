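# ROI intensity traces and pole-to-pole line profiles.

#' Extract per-frame mean-intensity traces for the standard ROI set
#'
#' For every frame, measures the mean reporter intensity over the whole
#' spindle, each half-spindle, each of the six zones, and the background.
#' No normalization is applied here.
#'
#' @param stack A registered [spindle_stack()].
#' @param zones A `zone_set` from [compartmentalize()].
#' @param background_roi Either `NULL` (per-frame fallback: the 1st
#'   percentile of the reporter frame) or a list with integer vectors `x`
#'   and `y` (`c(min, max)` px) describing a rectangle outside the cell.
#' @param channel Channel role to measure.
#' @return Tidy tibble: `roi`, `frame`, `time_s`, `mean_intensity`,
#'   `background`.
#' @export
extract_zone_traces <- function(stack, zones, background_roi = NULL,
                                channel = "reporter") {
  lab <- zones$labels
  rois <- list(whole_spindle = lab > 0,
               bleached_half = lab >= 1 & lab <= 3,
               unbleached_half = lab >= 4)
  for (i in 1:6) rois[[zones$key$roi[i]]] <- lab == i
  for (nm in names(rois)) if (!any(rois[[nm]]))
    stop_sf("extract_zone_traces: ROI '%s' is empty", nm)
  bg_mask <- NULL
  if (!is.null(background_roi)) {
    bg_mask <- matrix(FALSE, nrow(lab), ncol(lab))
    bg_mask[background_roi$y[1]:background_roi$y[2],
            background_roi$x[1]:background_roi$x[2]] <- TRUE
    if (!any(bg_mask)) stop_sf("extract_zone_traces: empty background ROI")
  }
  nt <- n_frames(stack)
  out <- vector("list", nt)
  for (f in seq_len(nt)) {
    img <- get_frame(stack, f, channel)
    bg <- if (is.null(bg_mask)) unname(quantile(img, 0.01)) else
      mean(img[bg_mask])
    out[[f]] <- tibble(roi = names(rois), frame = f,
                       time_s = stack$timestamps[f],
                       mean_intensity = unname(vapply(rois, function(m)
                         mean(img[m]), numeric(1))),
                       background = bg)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$roi, .data$frame)
}

#' Subtract the per-frame background from measured traces
#'
#' @param traces Tibble from [extract_zone_traces()].
#' @return Same tibble with `mean_intensity` background-subtracted and
#'   `background` zeroed.
#' @export
subtract_background <- function(traces) {
  dplyr::mutate(traces,
                mean_intensity = .data$mean_intensity - .data$background,
                background = 0)
}

# bilinear sample of img at (x, y) px; NA outside
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- rep(NA_real_, length(x))
  i00 <- y0[ok] + (x0[ok] - 1) * ny
  out[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00] +
    fx[ok] * (1 - fy[ok]) * img[i00 + ny] +
    (1 - fx[ok]) * fy[ok] * img[i00 + 1] +
    fx[ok] * fy[ok] * img[i00 + ny + 1]
  out
}

#' Pole-to-pole intensity profile averaged over a band of physical width
#'
#' Samples the image along the pole-to-pole axis at 1-px steps, averaging
#' across a band of the stated physical width (default 2 um) perpendicular
#' to the axis. If part of the band falls outside the image it is clipped
#' and the result is flagged (`attr(, "clipped")`).
#'
#' @param x A `Y x X` matrix or a [spindle_stack()].
#' @param axis A `spindle_axis` from [find_axis()].
#' @param width_um Band full width in um.
#' @param channel For stacks: channel role to profile.
#' @param frames For stacks: frame indices (default all).
#' @return Tibble `position_um`, `intensity` (plus `frame`, `time_s` for
#'   stacks); attributes `width_used_um` and `clipped`.
#' @export
extract_profile <- function(x, axis, width_um = 2, channel = "reporter",
                            frames = NULL) {
  if (inherits(x, "spindle_stack")) {
    frames <- frames %||% seq_len(n_frames(x))
    profs <- lapply(frames, function(f) {
      p <- extract_profile(get_frame(x, f, channel), axis, width_um)
      dplyr::mutate(p, frame = f, time_s = x$timestamps[f],
                    .before = 1L)
    })
    out <- dplyr::bind_rows(profs)
    attr(out, "width_used_um") <- width_um
    attr(out, "clipped") <- any(vapply(profs, attr, logical(1), "clipped"))
    return(out)
  }
  if (width_um <= 0) stop_sf("extract_profile: `width_um` must be positive")
  img <- x
  px <- axis$pixel_size
  u <- axis$pole_b - axis$pole_a
  len_px <- sqrt(sum(u^2))
  u <- u / len_px
  v <- c(-u[2], u[1])                     # unit normal
  n_steps <- as.integer(floor(len_px)) + 1L
  s_px <- seq(0, len_px, length.out = n_steps)
  half_w_px <- (width_um / px) / 2
  offs <- seq(-half_w_px, half_w_px, by = 1)
  cx <- axis$pole_a[1] + outer(s_px, rep(1, length(offs))) * u[1] +
    outer(rep(1, n_steps), offs) * v[1]
  cy <- axis$pole_a[2] + outer(s_px, rep(1, length(offs))) * u[2] +
    outer(rep(1, n_steps), offs) * v[2]
  vals <- matrix(bilinear_sample(img, as.numeric(cx), as.numeric(cy)),
                 n_steps, length(offs))
  clipped <- anyNA(vals)
  if (clipped)
    warning("extract_profile: band partially outside the image; clipped",
            call. = FALSE)
  out <- tibble(position_um = s_px * px,
                intensity = rowMeans(vals, na.rm = TRUE))
  attr(out, "width_used_um") <- width_um
  attr(out, "clipped") <- clipped
  out
}
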