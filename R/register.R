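# Rigid-body registration of time-lapse stacks (translation + rotation),
# estimated on the reference channel and applied to all channels.

# Rigid warp: the content of `img` is assumed displaced by (dx, dy) px and
# rotated by `theta_deg` (counter-clockwise about the image centre)
# relative to some template; the returned image samples
#   p_in = R(theta) (p_out - c) + c + (dx, dy)
# with bilinear interpolation, i.e. it undoes that motion. Pixels sampling
# outside the image are NA.
warp_rigid <- function(img, dx, dy, theta_deg) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- theta_deg * pi / 180
  co <- cos(th); si <- sin(th)
  xo <- matrix(1:nx, ny, nx, byrow = TRUE) - cx
  yo <- matrix(1:ny, ny, nx) - cy
  xs <- co * xo - si * yo + cx + dx
  ys <- si * xo + co * yo + cy + dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- matrix(NA_real_, ny, nx)
  i00 <- y0[ok] + (x0[ok] - 1) * ny
  out[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[i00] +
    fx[ok] * (1 - fy[ok]) * img[i00 + ny] +
    (1 - fx[ok]) * fy[ok] * img[i00 + 1] +
    fx[ok] * fy[ok] * img[i00 + ny + 1]
  out
}

# Integer content displacement of `img` relative to `ref` by the peak of
# the FFT cross-correlation.
phase_shift <- function(ref, img) {
  f <- fft(fft(ref) * Conj(fft(img)), inverse = TRUE)
  cc <- Re(f)
  ny <- nrow(cc); nx <- ncol(cc)
  k <- which.max(cc)
  iy <- (k - 1) %% ny
  ix <- (k - 1) %/% ny
  if (iy > ny / 2) iy <- iy - ny
  if (ix > nx / 2) ix <- ix - nx
  c(dx = -ix, dy = -iy)
}

neg_cor_rigid <- function(par, ref, img) {
  w <- warp_rigid(img, par[1], par[2], par[3])
  ok <- !is.na(w)
  if (sum(ok) < 50) return(1)
  r <- suppressWarnings(cor(w[ok], ref[ok]))
  if (!is.finite(r)) 1 else -r
}

estimate_rigid <- function(ref, img, theta_grid = seq(-8, 8, by = 2)) {
  init <- phase_shift(ref, img)
  cand <- lapply(theta_grid, function(th) {
    p <- c(init[["dx"]], init[["dy"]], th)
    list(par = p, value = neg_cor_rigid(p, ref, img))
  })
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  fit <- optim(best$par, neg_cor_rigid, ref = ref, img = img,
               method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-8))
  # polish translation/rotation at finer scale from the optimum
  fit2 <- optim(fit$par, neg_cor_rigid, ref = ref, img = img,
                method = "Nelder-Mead",
                control = list(maxit = 200, reltol = 1e-10))
  if (fit2$value < fit$value) fit <- fit2
  c(dx = fit$par[1], dy = fit$par[2], theta = fit$par[3],
    correlation = -fit$value)
}

#' Register a stack by rigid-body alignment to its first frame
#'
#' Each frame's rigid transform (translation + rotation) is estimated on
#' the reference channel by maximizing the intensity correlation with
#' frame 1 — FFT cross-correlation provides the translation start point, a
#' coarse rotation grid plus Nelder-Mead refinement the sub-pixel optimum —
#' and the same transform is applied to every channel. Border pixels that
#' sample outside the original frame are filled with the frame's minimum.
#'
#' @param stack A [spindle_stack()] with at least 2 frames.
#' @param ref_channel Channel role used to estimate the transforms.
#' @return A list: `stack`, the registered [spindle_stack()], and
#'   `transforms`, a tibble with one row per frame (`frame`, `dx_px`,
#'   `dy_px`, `theta_deg`, `correlation`) reporting the estimated content
#'   displacement relative to frame 1.
#' @export
register_stack <- function(stack, ref_channel = "reference") {
  nt <- n_frames(stack)
  if (nt < 2L) stop_sf("register_stack: need at least 2 frames")
  ref0 <- get_frame(stack, 1L, ref_channel)
  if (sd(ref0) == 0)
    stop_sf("register_stack: reference channel is constant; cannot register")
  d <- dim(stack$pixels)
  out <- stack$pixels
  rows <- vector("list", nt)
  rows[[1]] <- tibble(frame = 1L, dx_px = 0, dy_px = 0, theta_deg = 0,
                      correlation = 1)
  for (f in 2:nt) {
    est <- estimate_rigid(ref0, get_frame(stack, f, ref_channel))
    for (c in seq_len(d[2])) {
      img <- stack$pixels[f, c, , ]
      w <- warp_rigid(img, est[["dx"]], est[["dy"]], est[["theta"]])
      w[is.na(w)] <- min(img)
      out[f, c, , ] <- w
    }
    rows[[f]] <- tibble(frame = f, dx_px = est[["dx"]], dy_px = est[["dy"]],
                        theta_deg = est[["theta"]],
                        correlation = est[["correlation"]])
  }
  reg <- stack
  reg$pixels <- out
  list(stack = reg, transforms = dplyr::bind_rows(rows))
}
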