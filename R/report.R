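# Cohort reporting: per-condition summaries, pairwise comparisons, plots.

#' Summarize a measurement per condition
#'
#' @param data Tibble with a condition column and a numeric value column.
#' @param value,condition Column names (strings).
#' @return Tibble `condition`, `n`, `mean`, `sd`.
#' @export
summarize_conditions <- function(data, value, condition = "condition") {
  check_columns(data, c(value, condition), "summarize_conditions")
  data |>
    dplyr::group_by(condition = .data[[condition]]) |>
    dplyr::summarise(n = sum(is.finite(.data[[value]])),
                     mean = mean(.data[[value]], na.rm = TRUE),
                     sd = sd(.data[[value]], na.rm = TRUE),
                     .groups = "drop")
}

#' Pairwise Mann-Whitney comparisons between conditions
#'
#' Runs [mann_whitney()] on every unordered pair of conditions and adds
#' the star codes. With a single condition the result has zero rows.
#'
#' @inheritParams summarize_conditions
#' @return Tibble `group_a`, `group_b`, `n_a`, `n_b`, `u_statistic`,
#'   `p_value`, `stars`.
#' @export
compare_conditions <- function(data, value, condition = "condition") {
  check_columns(data, c(value, condition), "compare_conditions")
  levs <- unique(data[[condition]])
  if (length(levs) < 2L)
    return(tibble(group_a = character(), group_b = character(),
                  n_a = integer(), n_b = integer(),
                  u_statistic = numeric(), p_value = numeric(),
                  stars = character()))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- data[[value]][data[[condition]] == pr[1]]
    b <- data[[value]][data[[condition]] == pr[2]]
    mw <- mann_whitney(a, b)
    tibble(group_a = as.character(pr[1]), group_b = as.character(pr[2]),
           n_a = mw$n_a, n_b = mw$n_b, u_statistic = mw$u_statistic,
           p_value = mw$p_value, stars = star_code(mw$p_value))
  })
}

check_columns <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop_sf("%s: missing columns: %s", where, paste(miss, collapse = ", "))
  invisible(data)
}

#' Plot normalized recovery/decay curves with mean and spread bands
#'
#' @param norm Normalized trace tibble (`roi`, `time_s`, `value`),
#'   optionally with a `condition` column; the band is mean +/- sd across
#'   whatever replicates share a time point.
#' @param rois ROIs to show (default all).
#' @return A ggplot object.
#' @export
plot_recovery_curves <- function(norm, rois = NULL) {
  check_columns(norm, c("roi", "time_s", "value"), "plot_recovery_curves")
  if (!is.null(rois)) norm <- dplyr::filter(norm, .data$roi %in% rois)
  if (!"condition" %in% names(norm)) norm$condition <- "all"
  sm <- norm |>
    dplyr::group_by(.data$condition, .data$roi, .data$time_s) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(sd = ifelse(is.finite(.data$sd), .data$sd, 0))
  ggplot2::ggplot(sm, ggplot2::aes(.data$time_s, .data$mean,
                                   colour = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot a pulse-centre track with its quadratic trendline
#'
#' @param track Tibble from [track_centers()].
#' @param fit Optional `kinematics_fit` from [fit_kinematics()].
#' @return A ggplot object.
#' @export
plot_center_track <- function(track, fit = NULL) {
  check_columns(track, c("time_s", "center_um"), "plot_center_track")
  p <- ggplot2::ggplot(track, ggplot2::aes(.data$time_s, .data$center_um)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time post-activation (s)",
                  y = "Gaussian centre (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(min(track$time_s), max(track$time_s), length.out = 100)
    p <- p + ggplot2::geom_line(
      data = tibble(time_s = tt, center_um = fit$trend(tt)),
      colour = "firebrick")
  }
  p
}

#' Plot an averaged pole-to-pole profile with its confidence band
#'
#' @param avg Tibble from [average_profiles()].
#' @return A ggplot object.
#' @export
plot_averaged_profile <- function(avg) {
  check_columns(avg, c("position_frac", "mean", "ci_lo", "ci_hi"),
                "plot_averaged_profile")
  ggplot2::ggplot(avg, ggplot2::aes(.data$position_frac, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.25, fill = "darkgreen") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "pole-to-pole fraction", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Write the standard report from per-cell result tables
#'
#' Consumes tidy per-cell tables (e.g. concatenated [frap_experiment()] or
#' [pa_experiment()] rows with `condition` and `cell` columns), and writes
#' a per-condition summary CSV, a pairwise comparison CSV with star codes,
#' and (optionally) curve plots.
#'
#' @param results Tibble with `condition` plus the value column.
#' @param value Name of the measurement column to report.
#' @param out_dir Output directory (created if needed).
#' @param norm Optional normalized trace tibble for curve plots.
#' @param track Optional centre track for a centre-vs-time plot.
#' @return Invisibly, a list with the `summary` and `comparisons` tibbles
#'   and the paths written.
#' @export
report <- function(results, value, out_dir, norm = NULL, track = NULL) {
  check_columns(results, c("condition", value), "report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_conditions(results, value)
  comp <- compare_conditions(results, value)
  paths <- c(summary = file.path(out_dir, "summary.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"))
  readr::write_csv(summ, paths[["summary"]])
  readr::write_csv(comp, paths[["comparisons"]])
  if (!is.null(norm)) {
    p <- plot_recovery_curves(norm)
    ggplot2::ggsave(file.path(out_dir, "curves.png"), p,
                    width = 7, height = 5, dpi = 150)
    paths <- c(paths, curves = file.path(out_dir, "curves.png"))
  }
  if (!is.null(track)) {
    p <- plot_center_track(track)
    ggplot2::ggsave(file.path(out_dir, "center_track.png"), p,
                    width = 5, height = 4, dpi = 150)
    paths <- c(paths, center_track = file.path(out_dir, "center_track.png"))
  }
  invisible(list(summary = summ, comparisons = comp, paths = paths))
}
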