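# Stochastic simulator: binding/unbinding transport on a virtual spindle,
# rendered as a two-channel time-lapse with commanded photo-events.

# poleward = away from the spindle centre (x = 0); equatorward = toward it.

um_min_to_um_s <- function(v) v / 60

k_on_at <- function(x, cfg) {
  k <- rep(cfg$k_on_base, length(x))
  band <- abs(x) < cfg$chromosome_band_halfwidth
  k[band] <- k[band] * cfg$k_on_chrom_boost
  k
}

k_off_at <- function(x, cfg) {
  if (length(cfg$k_off) == 1L) return(rep(cfg$k_off, length(x)))
  third <- cfg$spindle_length / 6
  zone <- ifelse(abs(x) < third, "chromosome",
                 ifelse(abs(x) < 2 * third, "intermediate", "pole"))
  unname(cfg$k_off[zone])
}

envelope_halfwidth <- function(x, cfg) {
  u <- pmax(0, 1 - (2 * x / cfg$spindle_length)^2)
  cfg$spindle_half_width * sqrt(u)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

init_population <- function(cfg) {
  n <- cfg$n_molecules
  x <- runif(n, -cfg$spindle_length / 2, cfg$spindle_length / 2)
  env <- envelope_halfwidth(x, cfg)
  y <- runif(n, -env, env)
  kon <- k_on_at(x, cfg)
  koff <- k_off_at(x, cfg)
  p_bound <- ifelse(kon + koff > 0, kon / (kon + koff), 0)
  bound <- runif(n) < p_bound
  motor <- integer(n)
  motor[bound] <- draw_motor_state(sum(bound), cfg)
  list(x = x, y = y, bound = bound, motor = motor,
       fluorescent = rep(cfg$initially_fluorescent, n))
}

draw_motor_state <- function(n, cfg) {
  r <- runif(n)
  ifelse(r < cfg$p_motor_poleward, 1L,
         ifelse(r < cfg$p_motor_poleward + cfg$p_motor_equatorward, 2L, 0L))
}

step_population <- function(pop, cfg) {
  dt <- cfg$dt_sim
  half <- cfg$spindle_length / 2
  u0 <- which(!pop$bound)
  b0 <- which(pop$bound)

  if (length(u0)) {
    sd_step <- sqrt(2 * cfg$diffusion_coeff_unbound * dt)
    # the modelled cytoplasm ends at the poles: unbound molecules reflect
    # there, so the binding lattice spans the whole unbound domain
    pop$x[u0] <- reflect_into(pop$x[u0] + rnorm(length(u0), 0, sd_step),
                              -half, half)
    pop$y[u0] <- reflect_into(pop$y[u0] + rnorm(length(u0), 0, sd_step),
                              -cfg$spindle_half_width, cfg$spindle_half_width)
    p_bind <- 1 - exp(-k_on_at(pop$x[u0], cfg) * dt)
    newly <- u0[runif(length(u0)) < p_bind]
    if (length(newly)) {
      pop$bound[newly] <- TRUE
      pop$motor[newly] <- draw_motor_state(length(newly), cfg)
      env <- envelope_halfwidth(pop$x[newly], cfg)
      pop$y[newly] <- pmin(pmax(pop$y[newly], -env), env)
    }
  }

  if (length(b0)) {
    m <- pop$motor[b0]
    x <- pop$x[b0]
    v <- numeric(length(b0))
    v[m == 0L] <- um_min_to_um_s(cfg$flux_velocity)
    v[m == 1L] <- um_min_to_um_s(cfg$motor_poleward_velocity)
    v[m == 2L] <- -um_min_to_um_s(cfg$motor_equatorward_velocity)
    x_new <- x + sign(x) * v * dt
    # equatorward motors park at the chromosome band edge and drop the motor
    bw <- cfg$chromosome_band_halfwidth
    parked <- m == 2L & abs(x_new) < bw & abs(x) >= bw
    x_new[parked] <- sign(x[parked]) * bw
    pop$motor[b0[parked]] <- 0L
    # crossing a pole clamps the molecule there and unbinds it
    at_pole <- abs(x_new) > half
    x_new[at_pole] <- sign(x_new[at_pole]) * half
    pop$x[b0] <- x_new
    if (any(at_pole)) {
      pop$bound[b0[at_pole]] <- FALSE
      pop$motor[b0[at_pole]] <- 0L
    }
    still <- b0[!at_pole]
    if (length(still)) {
      p_off <- 1 - exp(-k_off_at(pop$x[still], cfg) * dt)
      lost <- still[runif(length(still)) < p_off]
      pop$bound[lost] <- FALSE
      pop$motor[lost] <- 0L
    }
    env <- envelope_halfwidth(pop$x[b0], cfg)
    pop$y[b0] <- pmin(pmax(pop$y[b0], -env), env)
  }
  pop
}

#' Apply a photobleach or photoactivation event to a molecule population
#'
#' Molecules inside the event region flip their fluorescent flag with
#' probability `efficiency`: `activate` turns dark molecules bright,
#' `bleach` turns bright molecules dark. Molecules outside the region are
#' untouched.
#'
#' @param population A molecule population: data frame or list with
#'   numeric `x`, `y` (um, spindle-centred) and logical `fluorescent`.
#' @param event A [photo_event()].
#' @param config The [simulation_config()] providing the field geometry.
#' @return The population with updated `fluorescent`, same type as input.
#' @export
apply_photo_event <- function(population, event, config) {
  was_df <- is.data.frame(population)
  pop <- as.list(population)
  half <- config$spindle_length / 2 + config$image_margin_um
  in_region <- switch(
    event$region,
    stripe = {
      if (abs(event$center_x_um) - event$width_um / 2 > half)
        stop_sf("photo_event region lies entirely outside the field")
      abs(pop$x - event$center_x_um) <= event$width_um / 2
    },
    half = if (event$side == "left") pop$x < 0 else pop$x > 0)
  eligible <- if (event$kind == "activate") !pop$fluorescent else pop$fluorescent
  hit <- in_region & eligible
  flip <- hit & (runif(length(pop$x)) < event$efficiency)
  pop$fluorescent[flip] <- !pop$fluorescent[flip]
  if (was_df) as_tibble(pop) else pop
}

render_geometry <- function(cfg) {
  half_x <- cfg$spindle_length / 2 + cfg$image_margin_um
  half_y <- cfg$spindle_half_width + cfg$image_margin_um
  nx <- 2L * as.integer(ceiling(half_x / cfg$pixel_size)) + 1L
  ny <- 2L * as.integer(ceiling(half_y / cfg$pixel_size)) + 1L
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  x_um <- ((1:nx) - cx) * cfg$pixel_size
  y_um <- ((1:ny) - cy) * cfg$pixel_size
  xg <- matrix(x_um, ny, nx, byrow = TRUE)
  yg <- matrix(y_um, ny, nx)
  inside <- (xg / (cfg$spindle_length / 2))^2 +
    (yg / cfg$spindle_half_width)^2 <= 1
  # reference dip shaped so its half-depth points sit at the band edges
  s <- cfg$chromosome_band_halfwidth / sqrt(2 * log(2))
  gap <- 1 - cfg$chrom_gap_depth * exp(-xg^2 / (2 * s^2))
  ref <- cfg$reference_level * inside * gap
  k <- gaussian_kernel_2d(sd = 1, radius = 4L)
  list(nx = nx, ny = ny, cx = cx, cy = cy, ref = conv2d_same(ref, k),
       kernel = k)
}

gaussian_kernel_2d <- function(sd = 1, radius = 4L) {
  g <- exp(-((-radius):radius)^2 / (2 * sd^2))
  k <- outer(g, g)
  k / sum(k)
}

# 'same'-size convolution with zero padding at the borders
conv2d_same <- function(img, k) {
  r <- (nrow(k) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(0, ny + 2L * r, nx + 2L * r)
  pad[(r + 1):(r + ny), (r + 1):(r + nx)] <- img
  out <- matrix(0, ny, nx)
  for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
    if (k[i, j] == 0) next
    out <- out + k[i, j] * pad[i:(i + ny - 1L), j:(j + nx - 1L)]
  }
  out
}

#' Render one image-plane pair from a molecule population
#'
#' The reporter channel bins fluorescent molecules onto the pixel grid,
#' convolves with a Gaussian point-spread kernel (sd = 1 px), scales by
#' `photons_per_molecule` and adds the background; the reference channel
#' is the static spindle envelope with its chromosome gap. With
#' `noise = TRUE` each channel receives Poisson photon noise followed by
#' additive Gaussian read noise (clamped at zero).
#'
#' @inheritParams apply_photo_event
#' @param noise Apply the camera noise model?
#' @param geometry Precomputed internal render geometry (optional).
#' @return List with `reporter` and `reference` `Y x X` matrices.
#' @export
render_frame <- function(population, config, noise = TRUE, geometry = NULL) {
  pop <- as.list(population)
  if (any(!is.finite(pop$x)) || any(!is.finite(pop$y)))
    stop_sf("render_frame: molecule positions must be finite")
  g <- geometry %||% render_geometry(config)
  fl <- pop$fluorescent
  counts <- matrix(0, g$ny, g$nx)
  if (any(fl)) {
    col <- round(pop$x[fl] / config$pixel_size + g$cx)
    row <- round(pop$y[fl] / config$pixel_size + g$cy)
    ok <- col >= 1 & col <= g$nx & row >= 1 & row <= g$ny
    idx <- row[ok] + (col[ok] - 1) * g$ny
    counts[] <- tabulate(idx, nbins = g$ny * g$nx)
  }
  reporter <- conv2d_same(counts * config$photons_per_molecule, g$kernel) +
    config$background_level
  reference <- g$ref + config$background_level
  if (noise) {
    reporter <- add_camera_noise(reporter, config)
    reference <- add_camera_noise(reference, config)
  }
  list(reporter = reporter, reference = reference)
}

add_camera_noise <- function(img, cfg) {
  shot <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  pmax(shot + rnorm(length(img), 0, cfg$read_noise_sd), 0)
}

#' Simulate a spindle time-lapse with ground truth
#'
#' Runs the discrete-time stochastic transport model: per sub-step
#' `dt_sim`, unbound molecules diffuse (Gaussian steps of
#' sd `sqrt(2 D dt)`), bind with probability `1 - exp(-k_on(x) dt)`
#' (boosted inside the chromosome band), and bound molecules advect —
#' poleward at `flux_velocity` for the lattice-bound state, at their motor
#' velocity for motor states — then unbind with probability
#' `1 - exp(-k_off dt)`. Motor states are drawn per binding event; they
#' are dropped on unbinding, on parking at the chromosome band edge
#' (equatorward motors) or on reaching a pole (which also unbinds).
#' Commanded photo-events fire at the start of the frame they name.
#' Molecule number is conserved, and identical configurations with
#' identical seeds give bit-identical stacks.
#'
#' @param config A [simulation_config()].
#' @param keep_population Record the final molecule population in the
#'   ground truth (for kinetics audits)?
#' @return A list with `stack` (a [spindle_stack()]) and `truth`, a
#'   `ground_truth` list holding the expected recovery half-life
#'   `ln 2 / k_off` (uniform-`k_off` case), the configured flux and motor
#'   velocities, a per-frame bound/fluorescent census, and optionally the
#'   final population.
#' @export
simulate_spindle <- function(config, keep_population = FALSE) {
  validate_config(config)
  set.seed(config$rng_seed)
  g <- render_geometry(config)
  pop <- init_population(config)

  burn_steps <- as.integer(round(config$burn_in_s / config$dt_sim))
  for (i in seq_len(burn_steps)) pop <- step_population(pop, config)

  steps_per_frame <- as.integer(round(config$frame_interval / config$dt_sim))
  nt <- config$n_frames
  px <- array(0, c(nt, 2L, g$ny, g$nx))
  census <- vector("list", nt)
  for (f in seq_len(nt)) {
    for (ev in config$photo_events)
      if (ev$frame_index == f) pop <- apply_photo_event(pop, ev, config)
    pl <- render_frame(pop, config, noise = TRUE, geometry = g)
    px[f, 1L, , ] <- pl$reporter
    px[f, 2L, , ] <- pl$reference
    census[[f]] <- tibble(frame = f,
                          time_s = (f - 1) * config$frame_interval,
                          n_bound = sum(pop$bound),
                          n_total = length(pop$x),
                          n_fluorescent = sum(pop$fluorescent))
    if (f < nt)
      for (i in seq_len(steps_per_frame)) pop <- step_population(pop, config)
  }

  stack <- spindle_stack(px, config$pixel_size,
                         (seq_len(nt) - 1) * config$frame_interval,
                         c(reporter = 1L, reference = 2L), config = config)
  truth <- structure(list(
    expected_recovery_halflife =
      if (length(config$k_off) == 1L && config$k_off > 0)
        log(2) / config$k_off else NA_real_,
    true_flux_velocity = config$flux_velocity,
    true_motor_velocities = c(poleward = config$motor_poleward_velocity,
                              equatorward = config$motor_equatorward_velocity),
    per_frame = dplyr::bind_rows(census),
    final_population = if (keep_population) as_tibble(pop) else NULL,
    config = config), class = "ground_truth")
  list(stack = stack, truth = truth)
}
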