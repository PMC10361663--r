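# Simulator: conservation, determinism, photo-events, rendering, kinetics.

test_that("config validation names the offending field", {
  expect_error(simulation_config(pixel_size = -1), "pixel_size")
  expect_error(simulation_config(dt_sim = 0.3, frame_interval = 1), "dt_sim")
  expect_error(simulation_config(chromosome_band_halfwidth = 6,
                                 spindle_length = 10),
               "chromosome_band_halfwidth")
  expect_error(simulation_config(p_motor_poleward = 0.6,
                                 p_motor_equatorward = 0.6),
               "p_motor")
  expect_error(simulation_config(k_off = c(a = 1, b = 2, c = 3)), "k_off")
  # per-zone triple with proper names is accepted
  cfg <- simulation_config(k_off = c(pole = 0.01, intermediate = 0.02,
                                     chromosome = 0.04))
  expect_s3_class(cfg, "simulation_config")
})

test_that("molecule number is conserved and seeds control determinism", {
  cfg <- small_frap_config(seed = 3L, n_molecules = 1500, n_frames = 6L,
                           burn_in_s = 5)
  sim1 <- simulate_spindle(cfg)
  expect_true(all(sim1$truth$per_frame$n_total == 1500))
  # bound + unbound always partitions the population
  expect_true(all(sim1$truth$per_frame$n_bound >= 0 &
                    sim1$truth$per_frame$n_bound <= 1500))
  sim2 <- simulate_spindle(cfg)
  expect_identical(sim1$stack$pixels, sim2$stack$pixels)
  cfg2 <- small_frap_config(seed = 4L, n_molecules = 1500, n_frames = 6L,
                            burn_in_s = 5)
  sim3 <- simulate_spindle(cfg2)
  expect_false(identical(sim1$stack$pixels, sim3$stack$pixels))
})

test_that("with k_off = 0 and no events the reporter signal is constant", {
  cfg <- simulation_config(n_molecules = 2000, k_on_base = 5, k_off = 0,
                           n_frames = 5L, burn_in_s = 2,
                           background_level = 0, read_noise_sd = 0,
                           photons_per_molecule = 100, rng_seed = 9L)
  # noiseless totals: render without camera noise at each census point
  sim <- simulate_spindle(cfg)
  expect_true(all(sim$truth$per_frame$n_fluorescent == 2000))
  totals <- apply(sim$stack$pixels[, 1, , ], 1, sum)
  # Poisson shot noise only; relative spread of the total is tiny
  expect_lt(diff(range(totals)) / mean(totals), 0.02)
})

test_that("photo events flip fluorescence with the stated efficiency", {
  cfg <- simulation_config(n_molecules = 10000, rng_seed = 2L,
                           initially_fluorescent = FALSE)
  pop <- list(x = runif(10000, -4, 4), y = runif(10000, -1, 1),
              bound = rep(TRUE, 10000), motor = integer(10000),
              fluorescent = rep(FALSE, 10000))
  ev_all <- photo_event("activate", 1L, "stripe", center_x_um = 0,
                        width_um = 20, efficiency = 1)
  expect_equal(sum(apply_photo_event(pop, ev_all, cfg)$fluorescent), 10000)

  ev_none <- photo_event("activate", 1L, "stripe", center_x_um = 0,
                         width_um = 20, efficiency = 0)
  expect_equal(sum(apply_photo_event(pop, ev_none, cfg)$fluorescent), 0)

  set.seed(5)
  ev_half <- photo_event("activate", 1L, "stripe", center_x_um = 0,
                         width_um = 20, efficiency = 0.5)
  n_on <- sum(apply_photo_event(pop, ev_half, cfg)$fluorescent)
  # binomial: 5000 +/- 3 sd, sd = sqrt(10000 * 0.25) = 50
  expect_lt(abs(n_on - 5000), 150)

  # bleach with efficiency 1 over everything -> all dark
  pop_on <- pop; pop_on$fluorescent <- rep(TRUE, 10000)
  ev_bleach <- photo_event("bleach", 1L, "stripe", center_x_um = 0,
                           width_um = 20, efficiency = 1)
  expect_equal(sum(apply_photo_event(pop_on, ev_bleach, cfg)$fluorescent), 0)

  # region outside the field errors
  ev_out <- photo_event("activate", 1L, "stripe", center_x_um = 8,
                        width_um = 0.5)
  expect_error(apply_photo_event(pop, ev_out, cfg), "outside")

  # molecules outside a stripe are untouched
  ev_stripe <- photo_event("bleach", 1L, "stripe", center_x_um = 2,
                           width_um = 1, efficiency = 1)
  res <- apply_photo_event(pop_on, ev_stripe, cfg)
  outside <- abs(pop$x - 2) > 0.5
  expect_true(all(res$fluorescent[outside]))
  expect_true(all(!res$fluorescent[!outside]))
})

test_that("rendering places molecules correctly and preserves mean intensity", {
  cfg <- simulation_config(n_molecules = 1, background_level = 7,
                           read_noise_sd = 0, rng_seed = 1L)
  none <- list(x = numeric(0), y = numeric(0), bound = logical(0),
               motor = integer(0), fluorescent = logical(0))
  img <- render_frame(none, cfg, noise = FALSE)$reporter
  expect_true(all(img == 7))

  one <- list(x = 1.5, y = -0.5, bound = TRUE, motor = 0L,
              fluorescent = TRUE)
  img1 <- render_frame(one, cfg, noise = FALSE)$reporter
  g <- spindleflux:::render_geometry(cfg)
  peak <- which(img1 == max(img1), arr.ind = TRUE)
  expect_lt(abs((peak[1, 2] - g$cx) * cfg$pixel_size - 1.5), 0.11)
  expect_lt(abs((peak[1, 1] - g$cy) * cfg$pixel_size - (-0.5)), 0.11)

  # Monte-Carlo mean over noisy renders matches the noiseless render total
  set.seed(42)
  cfg2 <- simulation_config(n_molecules = 1000, rng_seed = 1L)
  popn <- list(x = runif(1000, -4, 4), y = runif(1000, -1, 1),
               bound = rep(TRUE, 1000), motor = integer(1000),
               fluorescent = rep(TRUE, 1000))
  clean <- sum(render_frame(popn, cfg2, noise = FALSE)$reporter)
  noisy <- mean(replicate(50, sum(render_frame(popn, cfg2)$reporter)))
  expect_lt(abs(noisy / clean - 1), 0.01)

  expect_error(render_frame(list(x = NaN, y = 0, bound = TRUE, motor = 0L,
                                 fluorescent = TRUE), cfg), "finite")
})

test_that("binding reaches the k_on/(k_on+k_off) equilibrium without transport", {
  kon <- 0.2; koff <- 0.1
  cfg <- simulation_config(n_molecules = 8000, k_on_base = kon, k_off = koff,
                           n_frames = 2L, burn_in_s = 60,
                           diffusion_coeff_unbound = 2, rng_seed = 8L)
  sim <- simulate_spindle(cfg, keep_population = TRUE)
  pop <- sim$truth$final_population
  p_eq <- kon / (kon + koff)
  n_bound <- sum(pop$bound)
  sd_bin <- sqrt(8000 * p_eq * (1 - p_eq))
  expect_lt(abs(n_bound - 8000 * p_eq), 3 * sd_bin + 0.005 * 8000)
})

test_that("ground truth mirrors the configured kinetics", {
  cfg <- small_frap_config(seed = 1L, n_molecules = 200, n_frames = 3L,
                           burn_in_s = 0, k_off = 0.0277)
  sim <- simulate_spindle(cfg)
  expect_equal(sim$truth$expected_recovery_halflife, log(2) / 0.0277)
  expect_equal(sim$truth$true_flux_velocity, 0)
  expect_equal(sim$stack$timestamps, (0:2) * 5)
})

test_that("stacks round-trip through TIFF + sidecar", {
  cfg <- small_frap_config(seed = 2L, n_molecules = 300, n_frames = 3L,
                           burn_in_s = 0)
  sim <- simulate_spindle(cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$timestamps, sim$stack$timestamps)
  # float storage: agreement to single precision
  expect_lt(max(abs(back$pixels - sim$stack$pixels)) /
              max(sim$stack$pixels), 1e-6)
})
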