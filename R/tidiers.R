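# broom-style tidiers and autoplot methods for the fitted objects.

#' Tidy a one-phase exponential fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("k_per_s", "halflife_s", "plateau", "amplitude"),
         estimate = c(x$k, x$halflife, x$plateau, x$amplitude))
}

#' @rdname tidy.exp_fit
#' @return `glance()`: one-row fit summary.
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(kind = x$kind, k_per_s = x$k, halflife_s = x$halflife,
         plateau = x$plateau, amplitude = x$amplitude,
         r_squared = x$r_squared, n_points = x$n_points,
         converged = x$converged)
}

#' Plot a one-phase fit over its data
#'
#' @param object An `exp_fit` with attached data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_fit <- function(object, ...) {
  if (is.null(object$data)) stop_sf("autoplot.exp_fit: fit carries no data")
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
  if (object$converged) {
    tt <- seq(min(df$time_s), max(df$time_s), length.out = 200)
    rel <- tt - object$t0_s
    yy <- if (object$kind == "association")
      object$plateau * (1 - exp(-object$k * rel))
    else object$plateau + object$amplitude * exp(-object$k * rel)
    p <- p + ggplot2::geom_line(data = tibble(time_s = tt, value = yy),
                                colour = "steelblue")
  }
  p
}

#' Tidy a Gaussian profile fit
#'
#' @param x A `gaussian_fit`.
#' @param ... Unused.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("amplitude", "center_um", "sigma_um", "offset"),
         estimate = c(x$amplitude, x$center_um, x$sigma_um, x$offset))
}

#' @rdname tidy.gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, center_um = x$center_um,
         sigma_um = x$sigma_um, offset = x$offset,
         r_squared = x$r_squared, converged = x$converged)
}

#' Tidy a quadratic kinematics fit
#'
#' @param x A `kinematics_fit`.
#' @param ... Unused.
#' @export
tidy.kinematics_fit <- function(x, ...) {
  tibble(term = c("u0_um_min", "a_um_min2", "x_at_t0_um"),
         estimate = c(x$u0_um_min, x$a_um_min2, x$x_at_t0_um))
}

#' @rdname tidy.kinematics_fit
#' @export
glance.kinematics_fit <- function(x, ...) {
  tibble(u0_um_min = x$u0_um_min, a_um_min2 = x$a_um_min2,
         r_squared = x$r_squared, n = x$n)
}

#' Tidy a reference-point extrapolation result
#'
#' @param x A `kinematics_result`.
#' @param ... Unused.
#' @export
tidy.kinematics_result <- function(x, ...) {
  tibble(term = c("x0_um", "u0_um_min", "a_um_min2", "t_star_min",
                  "uc_um_min", "uc_poleward_um_min"),
         estimate = c(x$x0_um, x$u0_um_min, x$a_um_min2, x$t_star_min,
                      x$uc_um_min, x$uc_poleward_um_min))
}
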