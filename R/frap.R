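# FRAP arithmetic: double normalization, full-scale normalization,
# one-phase association/decay fitting, and the end-to-end experiment.

#' Double-normalize ROI traces against a reference ROI
#'
#' Classic FRAP double normalization: for each ROI,
#' `value(t) = [ref(t_pre) / ref(t)] * [roi(t) / roi(t_pre)]`,
#' where `ref` is the reference ROI (by design the whole spindle), so
#' acquisition fade affecting ROI and reference equally cancels and the
#' pre-bleach value is exactly 1. Background must already be subtracted
#' (see [subtract_background()]).
#'
#' @param traces Tidy trace tibble (`roi`, `frame`, `time_s`,
#'   `mean_intensity`) as from [extract_zone_traces()].
#' @param ref_roi Name of the reference ROI.
#' @param t_pre 1-based frame index of the pre-bleach frame.
#' @return Tibble `roi`, `frame`, `time_s`, `value`, `normalization`
#'   (`"double"`), with `t_pre` carried as an attribute.
#' @export
double_normalize <- function(traces, ref_roi = "whole_spindle", t_pre = 1L) {
  need <- c("roi", "frame", "time_s", "mean_intensity")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop_sf("double_normalize: missing columns: %s", paste(miss, collapse = ", "))
  ref <- dplyr::filter(traces, .data$roi == ref_roi)
  if (!nrow(ref)) stop_sf("double_normalize: reference ROI '%s' not found", ref_roi)
  ref <- dplyr::arrange(ref, .data$frame)
  if (!t_pre %in% ref$frame)
    stop_sf("double_normalize: `t_pre` frame %d not in traces", t_pre)
  ref_pre <- ref$mean_intensity[ref$frame == t_pre]
  bad <- ref$frame[ref$mean_intensity <= 0]
  if (length(bad))
    stop_sf("double_normalize: reference ROI non-positive at frame %d", bad[1])
  out <- traces |>
    dplyr::left_join(dplyr::select(ref, "frame", ref_value = "mean_intensity"),
                     by = "frame") |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$frame)
      roi_pre <- df$mean_intensity[df$frame == t_pre]
      if (roi_pre <= 0)
        stop_sf("double_normalize: ROI '%s' non-positive at pre-bleach frame %d",
                key$roi, t_pre)
      dplyr::mutate(df, value = (ref_pre / .data$ref_value) *
                      (.data$mean_intensity / roi_pre))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("roi", "frame", "time_s", "value") |>
    dplyr::mutate(normalization = "double")
  attr(out, "t_pre") <- as.integer(t_pre)
  out
}

#' Full-scale normalize double-normalized bleached-ROI traces
#'
#' Rescales a double-normalized recovery so the first post-bleach frame
#' maps to 0 and the pre-bleach level maps to 1:
#' `value'(t) = [value(t) - value(t0)] / [1 - value(t0)]`.
#'
#' @param norm Tibble from [double_normalize()].
#' @param t0 1-based frame index of the first post-bleach frame.
#' @param rois ROIs to rescale (default: all present).
#' @return Same shape, `normalization = "double+fullscale"`, with `t0`
#'   carried as an attribute.
#' @export
full_scale_normalize <- function(norm, t0, rois = NULL) {
  rois <- rois %||% unique(norm$roi)
  out <- norm |>
    dplyr::filter(.data$roi %in% rois) |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      v0 <- df$value[df$frame == t0]
      if (!length(v0))
        stop_sf("full_scale_normalize: `t0` frame %d not in ROI '%s'",
                t0, key$roi)
      if (v0 >= 1)
        stop_sf("full_scale_normalize: ROI '%s' has no bleach depth (value(t0) = %.3f >= 1)",
                key$roi, v0)
      dplyr::mutate(df, value = (.data$value - v0) / (1 - v0))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(normalization = "double+fullscale")
  attr(out, "t_pre") <- attr(norm, "t_pre")
  attr(out, "t0") <- as.integer(t0)
  out
}

new_exp_fit <- function(kind, k = NA_real_, plateau = NA_real_,
                        amplitude = NA_real_, r_squared = NA_real_,
                        n_points = 0L, converged = FALSE, t0_s = NA_real_,
                        data = NULL) {
  structure(list(kind = kind, k = k,
                 halflife = if (is.finite(k) && k > 0) log(2) / k else NA_real_,
                 plateau = plateau, amplitude = amplitude,
                 r_squared = r_squared, n_points = n_points,
                 converged = converged, t0_s = t0_s, data = data),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> one-phase %s: ", x$kind))
  if (x$converged)
    cat(sprintf("k = %.4g /s, t1/2 = %.3g s, plateau = %.3g, R2 = %.3f (n = %d)\n",
                x$k, x$halflife, x$plateau, x$r_squared, x$n_points))
  else cat("not converged\n")
  invisible(x)
}

# shared scaffolding for the two one-phase fits
fit_one_phase <- function(data, kind, t0 = NULL) {
  need <- c("time_s", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_sf("fit_one_phase_%s: missing columns: %s", kind,
            paste(miss, collapse = ", "))
  t0 <- t0 %||% min(data$time_s)
  df <- dplyr::filter(dplyr::arrange(data, .data$time_s), .data$time_s >= t0)
  if (nrow(df) < 5L)
    stop_sf("fit_one_phase_%s: need >= 5 post-bleach points, got %d",
            kind, nrow(df))
  tt <- df$time_s - t0
  y <- df$value
  if (sd(y) == 0)
    return(new_exp_fit(kind, n_points = nrow(df), t0_s = t0, data = df))

  last3 <- mean(tail(y, 3))
  first <- y[1]
  # k0 from where the trace first crosses half of its terminal change
  change <- last3 - first
  half_target <- first + change / 2
  crossed <- if (change >= 0) which(y >= half_target) else which(y <= half_target)
  t_half <- if (length(crossed)) max(tt[min(crossed)], diff(range(tt)) / 50) else
    diff(range(tt)) / 2
  k0 <- min(max(log(2) / t_half, 1e-4), 5)

  fit <- tryCatch({
    if (kind == "association") {
      minpack.lm::nlsLM(y ~ plateau * (1 - exp(-k * tt)),
                        start = list(plateau = max(last3, 1e-3), k = k0),
                        lower = c(plateau = 0, k = 1e-5),
                        upper = c(plateau = Inf, k = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ plateau + amplitude * exp(-k * tt),
                        start = list(plateau = last3,
                                     amplitude = max(first - last3, 1e-3),
                                     k = k0),
                        lower = c(plateau = -Inf, amplitude = 0, k = 1e-5),
                        upper = c(plateau = Inf, amplitude = Inf, k = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit))
    return(new_exp_fit(kind, n_points = nrow(df), t0_s = t0, data = df))

  cf <- coef(fit)
  resid <- y - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  amp <- if (kind == "association") unname(cf["plateau"]) else
    unname(cf["amplitude"])
  conv <- is.finite(cf["k"]) && cf["k"] > 1.5e-5 && cf["k"] < 9.99 &&
    amp > 1e-6
  new_exp_fit(kind, k = unname(cf["k"]), plateau = unname(cf["plateau"]),
              amplitude = amp, r_squared = r2, n_points = nrow(df),
              converged = conv, t0_s = t0, data = df)
}

#' Fit a one-phase association (recovery) curve
#'
#' Least-squares fit of `y(t) = plateau * (1 - exp(-k (t - t0)))` to the
#' post-bleach points of a (full-scale) normalized recovery; the half-life
#' is `ln 2 / k`. Optimizer failure yields `converged = FALSE`, never an
#' exception.
#'
#' @param data Tibble with `time_s` and `value` for one ROI.
#' @param t0 Time (s) of the first post-bleach frame; default: the first
#'   time point in `data`.
#' @return An `exp_fit` object; see also [tidy.exp_fit()].
#' @export
fit_one_phase_association <- function(data, t0 = NULL) {
  fit_one_phase(data, "association", t0)
}

#' Fit a one-phase decay curve
#'
#' Least-squares fit of `y(t) = plateau + amplitude * exp(-k (t - t0))` to
#' the post-bleach points of a double-normalized (not full-scale) trace,
#' as used for the unbleached half-spindle.
#'
#' @inheritParams fit_one_phase_association
#' @return An `exp_fit` object.
#' @export
fit_one_phase_decay <- function(data, t0 = NULL) {
  fit_one_phase(data, "decay", t0)
}

#' Run the full FRAP analysis on a stack
#'
#' Pipeline: rigid registration - spindle segmentation on the pre-bleach
#' reference frame - axis and chromosome-edge detection - six-zone
#' compartmentalization (bleached side from the bleach geometry) - ROI
#' trace extraction - background subtraction - double normalization
#' against the whole spindle - full-scale normalization and one-phase
#' association fits for the bleached ROIs, one-phase decay fits (on the
#' double-normalized traces) for the unbleached ROIs.
#'
#' @param stack A [spindle_stack()].
#' @param bleach_event The bleach [photo_event()]; its `frame_index` is
#'   the first post-bleach frame (t0) and `frame_index - 1` the pre-bleach
#'   frame.
#' @param background_roi Passed to [extract_zone_traces()].
#' @param register Run rigid registration first?
#' @param chrom_edges_um Optional user-supplied chromosome edges.
#' @return Tibble with one row per ROI: `roi`, `kind`, `k_per_s`,
#'   `halflife_s`, `plateau`, `amplitude`, `r_squared`, `converged`,
#'   `n_points`, `flagged` (`r_squared < 0.8`); the normalized traces are
#'   attached as attribute `"normalized"`, the zone set as `"zones"`.
#' @export
frap_experiment <- function(stack, bleach_event, background_roi = NULL,
                            register = TRUE, chrom_edges_um = NULL) {
  t0 <- bleach_event$frame_index
  t_pre <- t0 - 1L
  if (t_pre < 1L) stop_sf("frap_experiment: no pre-bleach frame before t0 = %d", t0)
  if (register) stack <- register_stack(stack)$stack
  ref_img <- get_frame(stack, t_pre, "reference")
  mask <- segment_spindle(ref_img)
  axis <- find_axis(mask, ref_img, stack$pixel_size,
                    chrom_edges_um = chrom_edges_um)
  zones <- compartmentalize(mask, axis, event_axis_range(bleach_event, axis))
  traces <- subtract_background(
    extract_zone_traces(stack, zones, background_roi))
  norm <- double_normalize(traces, "whole_spindle", t_pre)

  bleached <- c("bleached_half", "bleached_pole", "bleached_intermediate",
                "bleached_chromosome")
  unbleached <- c("unbleached_half", "unbleached_pole",
                  "unbleached_intermediate", "unbleached_chromosome")
  t0_s <- stack$timestamps[t0]
  fs <- full_scale_normalize(norm, t0, rois = bleached)

  one_row <- function(roi, fit) tibble(
    roi = roi, kind = fit$kind, k_per_s = fit$k, halflife_s = fit$halflife,
    plateau = fit$plateau, amplitude = fit$amplitude,
    r_squared = fit$r_squared, converged = fit$converged,
    n_points = fit$n_points,
    flagged = !fit$converged | (is.finite(fit$r_squared) & fit$r_squared < 0.8))

  rows <- list()
  for (r in bleached) {
    df <- dplyr::filter(fs, .data$roi == r)
    rows[[r]] <- tryCatch(one_row(r, fit_one_phase_association(df, t0_s)),
                          error = function(e)
                            stop_sf("frap_experiment [%s]: %s", r,
                                    conditionMessage(e)))
  }
  for (r in unbleached) {
    df <- dplyr::filter(norm, .data$roi == r, .data$frame >= t0)
    rows[[r]] <- tryCatch(one_row(r, fit_one_phase_decay(df, t0_s)),
                          error = function(e)
                            stop_sf("frap_experiment [%s]: %s", r,
                                    conditionMessage(e)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "normalized") <- dplyr::bind_rows(
    fs, dplyr::filter(norm, .data$roi %in% c(unbleached, "whole_spindle")))
  attr(out, "zones") <- zones
  out
}
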