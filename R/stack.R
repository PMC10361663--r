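# Two-channel time-lapse container and TIFF round-trip.

#' Construct a spindle image stack
#'
#' A `spindle_stack` holds a two-channel time-lapse as a 4-d array together
#' with its physical calibration. It is the common currency of the whole
#' pipeline: the simulator produces one, and registration, segmentation,
#' trace extraction and profile extraction all consume one.
#'
#' @param pixels Numeric array with dimensions `T x C x Y x X`
#'   (frame, channel, row, column). Intensities must be non-negative.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param timestamps Frame acquisition times in seconds, strictly
#'   increasing, one per frame.
#' @param channel_roles Named integer vector mapping roles to channel
#'   indices; must contain `reporter`, usually also `reference`.
#' @param config Optional simulation configuration echoed by the simulator.
#'
#' @return An object of class `spindle_stack`.
#' @export
spindle_stack <- function(pixels, pixel_size, timestamps,
                          channel_roles = c(reporter = 1L, reference = 2L),
                          config = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 4L)
    stop_sf("`pixels` must be a T x C x Y x X array")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stop_sf("`pixel_size` must be a positive scalar (um/px)")
  if (length(timestamps) != dim(pixels)[1L])
    stop_sf("`timestamps` length (%d) must equal the number of frames (%d)",
            length(timestamps), dim(pixels)[1L])
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop_sf("`timestamps` must be strictly increasing")
  if (any(pixels < 0)) stop_sf("intensities must be non-negative")
  if (!"reporter" %in% names(channel_roles))
    stop_sf("`channel_roles` must name a 'reporter' channel")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         timestamps = as.numeric(timestamps),
         channel_roles = channel_roles, config = config),
    class = "spindle_stack")
}

#' @export
print.spindle_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<spindle_stack> %d frames x %d channels, %d x %d px (%.3g um/px)\n",
    d[1], d[2], d[3], d[4], x$pixel_size))
  cat(sprintf("  time %.3g .. %.3g s; channels: %s\n",
              min(x$timestamps), max(x$timestamps),
              paste(names(x$channel_roles), x$channel_roles,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.spindle_stack <- function(x) dim(x$pixels)

n_frames <- function(stack) dim(stack$pixels)[1L]

#' Extract one image plane from a stack
#'
#' @param stack A [spindle_stack()].
#' @param frame Frame index (1-based).
#' @param channel Channel role name (`"reporter"`, `"reference"`) or index.
#' @return A numeric `Y x X` matrix.
#' @export
get_frame <- function(stack, frame, channel = "reporter") {
  ch <- if (is.character(channel)) {
    if (!channel %in% names(stack$channel_roles))
      stop_sf("stack has no '%s' channel", channel)
    stack$channel_roles[[channel]]
  } else as.integer(channel)
  if (frame < 1L || frame > n_frames(stack))
    stop_sf("frame %d out of range 1..%d", frame, n_frames(stack))
  stack$pixels[frame, ch, , ]
}

#' Write a stack to a multi-page TIFF with a YAML calibration sidecar
#'
#' Pages are stored frame-major (`T*C` pages, channels fastest) as 32-bit
#' float after division by a global scale factor; pixel size, timestamps,
#' channel roles and the scale factor go to `<path>.yaml`, so the
#' round-trip is lossless to single precision.
#'
#' @param stack A [spindle_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  scale <- max(stack$pixels, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    pages[[k]] <- stack$pixels[t, c, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size,
               timestamps_s = as.numeric(stack$timestamps),
               n_frames = d[1], n_channels = d[2],
               channel_roles = as.list(stack$channel_roles),
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.yaml` must exist alongside.
#' @return A [spindle_stack()].
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop_sf("calibration sidecar '%s' not found", sidecar)
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- meta$n_frames; nc <- meta$n_channels
  if (length(pages) != nt * nc)
    stop_sf("TIFF has %d pages, sidecar promises %d", length(pages), nt * nc)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  px <- array(0, c(nt, nc, ny, nx))
  k <- 1L
  for (t in seq_len(nt)) for (c in seq_len(nc)) {
    px[t, c, , ] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  spindle_stack(px, meta$pixel_size_um, unlist(meta$timestamps_s),
                unlist(meta$channel_roles))
}
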