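# Fixtures built in code: small simulator configurations and tidy tables
# used across the test files.

# fast FRAP-type configuration (small molecule count for unit tests)
small_frap_config <- function(seed = 1L, n_molecules = 4000, k_off = 0.0277,
                              k_on_chrom_boost = 1, efficiency = 0.9,
                              n_frames = 25L, ...) {
  simulation_config(
    n_molecules = n_molecules, k_off = k_off,
    k_on_chrom_boost = k_on_chrom_boost, n_frames = n_frames,
    photo_events = list(photo_event("bleach", 3L, "half", side = "left",
                                    efficiency = efficiency)),
    rng_seed = seed, ...)
}

# photoactivation configuration: dark reporter, stable binding, stripe
# activation in the right half; transport set by the caller
small_pa_config <- function(seed = 1L, flux = 0.69, p_pol = 0, v_pol = 0,
                            p_eq = 0, v_eq = 0, center = 2.0,
                            n_molecules = 10000, n_frames = 46L, ...) {
  simulation_config(
    n_molecules = n_molecules, k_on_base = 5, k_off = 0,
    flux_velocity = flux,
    p_motor_poleward = p_pol, motor_poleward_velocity = v_pol,
    p_motor_equatorward = p_eq, motor_equatorward_velocity = v_eq,
    frame_interval = 2, n_frames = n_frames, burn_in_s = 5,
    initially_fluorescent = FALSE,
    photo_events = list(photo_event("activate", 2L, "stripe",
                                    center_x_um = center)),
    rng_seed = seed, ...)
}

run_pa <- function(cfg, landmark = "chrom_edge", register = FALSE) {
  sim <- simulate_spindle(cfg)
  pa_experiment(sim$stack, sim$stack$config$photo_events[[1]],
                landmark = landmark, register = register)
}

# tidy two-ROI trace table from plain vectors
trace_table <- function(roi_values, ref_values, dt = 5) {
  n <- length(roi_values)
  dplyr::bind_rows(
    tibble::tibble(roi = "roi", frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
                   mean_intensity = roi_values, background = 0),
    tibble::tibble(roi = "whole_spindle", frame = seq_len(n),
                   time_s = (seq_len(n) - 1) * dt,
                   mean_intensity = ref_values, background = 0))
}

# sampled Gaussian profile
gaussian_profile <- function(A = 5, mu = 4, sigma = 1, offset = 1,
                             span = 10, n = 101) {
  x <- seq(0, span, length.out = n)
  tibble::tibble(position_um = x,
                 intensity = offset + A * exp(-(x - mu)^2 / (2 * sigma^2)))
}

# independent oracle: exact two-tailed Mann-Whitney p by full enumeration
# of all C(n1+n2, n1) group assignments of the pooled midranks
mw_enumeration_p <- function(a, b) {
  n1 <- length(a)
  pooled <- rank(c(a, b))
  u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(pooled[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(b)) / 2
  # two-tailed: as or more extreme in distance from the null mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# independent oracle: dense grid search for the one-phase association fit
grid_search_association <- function(tt, y, k_grid = seq(0.001, 0.2, by = 1e-4)) {
  best <- c(k = NA_real_, plateau = NA_real_, sse = Inf)
  for (k in k_grid) {
    basis <- 1 - exp(-k * tt)
    plateau <- sum(basis * y) / sum(basis^2)
    sse <- sum((y - plateau * basis)^2)
    if (sse < best[["sse"]]) best <- c(k = k, plateau = plateau, sse = sse)
  }
  best
}

# independent oracle: brute-force time-scan root finder for the landmark
# crossing of x0 + u0 t + a t^2 / 2: a coarse scan brackets every sign
# change, then a dense 1e-4-step scan inside each bracket pins it down
scan_t_star <- function(u0, a, x0, t_max = 60, dt = 1e-4, dt_coarse = 0.01) {
  xfun <- function(tt) x0 + tt * (u0 + 0.5 * a * tt)
  tt <- seq(-t_max, t_max, by = dt_coarse)
  x <- xfun(tt)
  flips <- which(x[-1] * x[-length(x)] <= 0)
  if (!length(flips)) return(NA_real_)
  roots <- vapply(flips, function(i) {
    tf <- seq(tt[i] - dt_coarse, tt[i + 1] + dt_coarse, by = dt)
    xf <- xfun(tf)
    j <- which(xf[-1] * xf[-length(xf)] <= 0)[1]
    if (is.na(j)) return(tt[i])
    if (xf[j + 1] == xf[j]) tf[j] else
      tf[j] - xf[j] * dt / (xf[j + 1] - xf[j])
  }, numeric(1))
  roots[which.min(abs(roots))]
}
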