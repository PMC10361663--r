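# Photoactivation analysis: Gaussian profile fitting, pulse-centre
# tracking, quadratic kinematics, and equations-of-motion extrapolation to
# a reference-landmark velocity.

#' Fit a Gaussian to a pole-to-pole intensity profile
#'
#' Least-squares fit of `I(x) = offset + A exp(-(x - mu)^2 / (2 sigma^2))`.
#' The constant offset absorbs diffuse background; `offset = FALSE` fits
#' the bare Gaussian. A flat profile or optimizer failure returns
#' `converged = FALSE`.
#'
#' @param profile Tibble with `position_um` and `intensity` (one frame).
#' @param offset Include the constant offset term?
#' @return A `gaussian_fit`: `amplitude`, `center_um`, `sigma_um`,
#'   `offset`, `r_squared`, `converged`.
#' @export
fit_gaussian <- function(profile, offset = TRUE) {
  if (nrow(profile) < 7L)
    stop_sf("fit_gaussian: need >= 7 profile samples, got %d", nrow(profile))
  x <- profile$position_um
  y <- profile$intensity
  fail <- structure(list(amplitude = NA_real_, center_um = NA_real_,
                         sigma_um = NA_real_, offset = NA_real_,
                         r_squared = NA_real_, converged = FALSE),
                    class = "gaussian_fit")
  if (sd(y) == 0) return(fail)
  off0 <- if (offset) min(y) else 0
  w <- pmax(y - min(y), 0)
  if (sum(w) == 0) return(fail)
  mu0 <- sum(x * w) / sum(w)
  sig0 <- sqrt(max(sum(w * (x - mu0)^2) / sum(w), 1e-4))
  a0 <- max(max(y) - off0, 1e-6)
  span <- diff(range(x))
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ off + A * exp(-(x - mu)^2 / (2 * s^2)),
                        start = list(off = off0, A = a0, mu = mu0, s = sig0),
                        lower = c(off = -Inf, A = 0, mu = min(x), s = 1e-4),
                        upper = c(off = Inf, A = Inf, mu = max(x), s = span),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                        start = list(A = a0, mu = mu0, s = sig0),
                        lower = c(A = 0, mu = min(x), s = 1e-4),
                        upper = c(A = Inf, mu = max(x), s = span),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- as.list(coef(fit))
  resid <- y - predict(fit)
  sst <- sum((y - mean(y))^2)
  structure(list(amplitude = cf$A, center_um = cf$mu, sigma_um = cf$s,
                 offset = if (offset) cf$off else 0,
                 r_squared = 1 - sum(resid^2) / sst,
                 converged = cf$A > 1e-9 && cf$s < span * 0.99),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<gaussian_fit> mu = %.3f um, sigma = %.3f um, A = %.3g, R2 = %.3f\n",
                x$center_um, x$sigma_um, x$amplitude, x$r_squared))
  else cat("<gaussian_fit> not converged\n")
  invisible(x)
}

#' Track the pulse centre across post-activation frames
#'
#' Fits a Gaussian per frame and collects the converged centres; times are
#' reported relative to the first post-activation frame. Non-converged
#' frames are dropped and counted in `attr(, "n_dropped")`.
#'
#' @param profiles Long profile tibble from [extract_profile()] on a
#'   stack (`frame`, `time_s`, `position_um`, `intensity`).
#' @param activation_frame 1-based index of the first post-activation
#'   frame.
#' @param offset Passed to [fit_gaussian()].
#' @return Tibble `frame`, `time_s` (relative), `center_um`, `sigma_um`,
#'   `amplitude`, `r_squared`.
#' @export
track_centers <- function(profiles, activation_frame, offset = TRUE) {
  post <- dplyr::filter(profiles, .data$frame >= activation_frame)
  frames <- sort(unique(post$frame))
  if (length(frames) < 4L)
    stop_sf("track_centers: need >= 4 post-activation frames, got %d",
            length(frames))
  t_ref <- min(post$time_s)
  rows <- lapply(frames, function(f) {
    df <- dplyr::filter(post, .data$frame == f)
    g <- fit_gaussian(df, offset = offset)
    if (!g$converged) return(NULL)
    tibble(frame = f, time_s = df$time_s[1] - t_ref, center_um = g$center_um,
           sigma_um = g$sigma_um, amplitude = g$amplitude,
           r_squared = g$r_squared)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) < 4L)
    stop_sf("track_centers: only %d usable frames after dropping %d failed fits",
            nrow(out), dropped)
  attr(out, "n_dropped") <- dropped
  out
}

#' Fit constant-acceleration kinematics to a centre track
#'
#' Least-squares quadratic `mu(t) = c0 + c1 t + c2 t^2` on the centre
#' trajectory (fit in seconds and um); the initial velocity is `u0 = c1`
#' and the acceleration `a = 2 c2`, reported in um/min and um/min^2.
#'
#' @param track Tibble from [track_centers()] (needs `time_s`,
#'   `center_um`).
#' @return A `kinematics_fit`: `u0_um_min`, `a_um_min2`, `x_at_t0_um`,
#'   `r_squared`, `n`, the underlying `lm` fit, and `trend()`, a function
#'   of time (s) returning the fitted trendline.
#' @export
fit_kinematics <- function(track) {
  if (nrow(track) < 4L)
    stop_sf("fit_kinematics: need >= 4 points, got %d", nrow(track))
  if (anyDuplicated(track$time_s))
    stop_sf("fit_kinematics: duplicated time points; design is rank-deficient")
  tt <- track$time_s
  fit <- lm(center_um ~ tt + I(tt^2), data = track)
  cf <- unname(coef(fit))
  sst <- sum((track$center_um - mean(track$center_um))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(u0_um_min = cf[2] * 60, a_um_min2 = cf[3] * 2 * 3600,
                 x_at_t0_um = cf[1], r_squared = r2, n = nrow(track),
                 lm_fit = fit,
                 trend = function(t_s) cf[1] + cf[2] * t_s + cf[3] * t_s^2),
            class = "kinematics_fit")
}

#' @export
print.kinematics_fit <- function(x, ...) {
  cat(sprintf("<kinematics_fit> u0 = %.3f um/min, a = %.3f um/min^2, R2 = %.3f (n = %d)\n",
              x$u0_um_min, x$a_um_min2, x$r_squared, x$n))
  invisible(x)
}

#' Extrapolate the pulse velocity to a reference landmark
#'
#' With the landmark at `x = 0` and the pulse starting at distance
#' `x0 >= 0`, constant-acceleration motion `x(t) = x0 + u0 t + a t^2 / 2`
#' crosses the landmark at the real roots of that quadratic; the root of
#' smallest magnitude is taken (negative roots extrapolate backward in
#' time) and the landmark velocity is `uc = u0 + a t*`. Both roots are
#' retained for audit.
#'
#' @param u0 Initial velocity (um/min), positive away from the landmark.
#' @param a Acceleration (um/min^2).
#' @param x0 Distance of the pulse centre from the landmark (um, >= 0).
#' @param poleward_sign +1 if motion away from the landmark is poleward
#'   (chromosome-edge landmark), -1 if it is equatorward (pole landmark);
#'   used for the poleward-signed report `uc_poleward_um_min`.
#' @return A `kinematics_result`: `u0`, `a`, `x0`, `t_star_min`,
#'   `uc_um_min`, `uc_poleward_um_min`, `roots_min`, `poleward_sign`.
#' @export
velocity_at_reference <- function(u0, a, x0, poleward_sign = 1) {
  if (x0 < 0) stop_sf("velocity_at_reference: `x0` must be >= 0")
  if (a == 0) {
    if (u0 == 0)
      stop_sf("velocity_at_reference: u0 = 0 and a = 0; pulse never moves")
    roots <- -x0 / u0
  } else {
    disc <- u0^2 - 2 * a * x0
    if (disc < 0)
      stop_sf("velocity_at_reference: no real crossing of the reference point")
    roots <- sort((-u0 + c(-1, 1) * sqrt(disc)) / a)
  }
  t_star <- roots[which.min(abs(roots))]
  uc <- u0 + a * t_star
  structure(list(u0_um_min = u0, a_um_min2 = a, x0_um = x0,
                 t_star_min = t_star, uc_um_min = uc,
                 uc_poleward_um_min = poleward_sign * uc,
                 roots_min = roots, poleward_sign = poleward_sign),
            class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf("<kinematics_result> x0 = %.3f um, u0 = %.3f um/min, a = %.3f um/min^2\n",
              x$x0_um, x$u0_um_min, x$a_um_min2))
  cat(sprintf("  t* = %.4f min (roots %s), uc = %.4f um/min (poleward-signed %.4f)\n",
              x$t_star_min, paste(sprintf("%.4f", x$roots_min), collapse = ", "),
              x$uc_um_min, x$uc_poleward_um_min))
  invisible(x)
}

#' Distance from the activation stripe to a landmark
#'
#' Unsigned axial distance from the stripe centre to the chosen landmark:
#' the nearer chromosome edge, or the nearer pole.
#'
#' @param axis A `spindle_axis` with chromosome edges (for
#'   `landmark = "chrom_edge"`).
#' @param stripe_center_um Stripe centre, um from pole A along the axis.
#' @param landmark `"chrom_edge"` or `"pole"`.
#' @return Distance in um.
#' @export
measure_x0 <- function(axis, stripe_center_um,
                       landmark = c("chrom_edge", "pole")) {
  landmark <- match.arg(landmark)
  L <- axis$length_um
  if (stripe_center_um < 0 || stripe_center_um > L)
    stop_sf("measure_x0: stripe centre %.2f um outside the spindle span [0, %.2f]",
            stripe_center_um, L)
  if (landmark == "chrom_edge") {
    if (is.null(axis$chrom_edges_um))
      stop_sf("measure_x0: axis has no chromosome edges")
    min(abs(stripe_center_um - axis$chrom_edges_um))
  } else {
    min(stripe_center_um, L - stripe_center_um)
  }
}

#' Run the full photoactivation analysis on a stack
#'
#' Pipeline: rigid registration - mask and axis from the reference channel
#' (or, for activated-tubulin runs, from the summed post-activation
#' reporter signal) - per-frame pole-to-pole profiles of the reporter -
#' Gaussian centre tracking - quadratic kinematics - extrapolation of the
#' velocity to the landmark. The signed axis for the kinematics points
#' from the landmark toward the initial pulse position, so `x0 > 0`; the
#' headline `uc_poleward_um_min` is signed with poleward positive.
#'
#' @param stack A [spindle_stack()].
#' @param event The activation [photo_event()] (a stripe).
#' @param landmark `"chrom_edge"` or `"pole"`.
#' @param register Run rigid registration first?
#' @param mask_channel Channel role used for mask/axis (`"reference"`, or
#'   `"reporter"` when the activated signal itself is the mask).
#' @param chrom_edges_um Optional user-supplied chromosome edges.
#' @param profile_width_um Band width for [extract_profile()].
#' @return Tibble with one row: `x0_um`, `u0_um_min`, `a_um_min2`,
#'   `t_star_min`, `uc_um_min`, `uc_poleward_um_min`, `r2_quadratic`,
#'   `n_frames_used`; the centre track, kinematics fit and full
#'   `kinematics_result` are attached as attributes.
#' @export
pa_experiment <- function(stack, event, landmark = c("chrom_edge", "pole"),
                          register = TRUE, mask_channel = "reference",
                          chrom_edges_um = NULL, profile_width_um = 2) {
  landmark <- match.arg(landmark)
  if (event$region != "stripe")
    stop_sf("pa_experiment: activation event must be a stripe")
  if (register) stack <- register_stack(stack,
    ref_channel = if (mask_channel == "reporter") "reporter" else "reference")$stack
  mask_img <- if (mask_channel == "reporter") {
    post <- which(stack$timestamps >= stack$timestamps[event$frame_index])
    apply(stack$pixels[post, stack$channel_roles[["reporter"]], , ,
                       drop = FALSE], c(3, 4), mean)
  } else get_frame(stack, max(event$frame_index - 1L, 1L), mask_channel)
  mask <- segment_spindle(mask_img)
  axis <- find_axis(mask, mask_img, stack$pixel_size,
                    chrom_edges_um = chrom_edges_um)

  profiles <- extract_profile(stack, axis, width_um = profile_width_um,
                              channel = "reporter")
  track <- track_centers(profiles, event$frame_index)

  stripe_center <- track$center_um[1]
  x0 <- measure_x0(axis, stripe_center, landmark)
  l_pos <- if (landmark == "chrom_edge") {
    axis$chrom_edges_um[which.min(abs(stripe_center - axis$chrom_edges_um))]
  } else {
    if (stripe_center < axis$length_um / 2) 0 else axis$length_um
  }
  # signed axis: positive from the landmark toward the initial pulse
  e_sign <- if (stripe_center >= l_pos) 1 else -1
  signed <- dplyr::mutate(track,
                          center_um = e_sign * (.data$center_um - l_pos))
  kin <- fit_kinematics(signed)
  # moving away from a chromosome edge is poleward; away from a pole is not
  poleward_sign <- if (landmark == "chrom_edge") 1 else -1
  res <- velocity_at_reference(kin$u0_um_min, kin$a_um_min2, x0,
                               poleward_sign = poleward_sign)
  out <- tibble(x0_um = x0, u0_um_min = res$u0_um_min,
                a_um_min2 = res$a_um_min2, t_star_min = res$t_star_min,
                uc_um_min = res$uc_um_min,
                uc_poleward_um_min = res$uc_poleward_um_min,
                r2_quadratic = kin$r_squared, n_frames_used = kin$n)
  attr(out, "track") <- track
  attr(out, "kinematics_fit") <- kin
  attr(out, "kinematics_result") <- res
  attr(out, "axis") <- axis
  out
}
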