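# Simulator configuration and photo-event descriptions.

#' Describe a commanded photobleach or photoactivation event
#'
#' Events act on the molecule population at the start of the frame they
#' name, so `frame_index` is the first post-event frame (the FRAP "t0").
#' Two region shapes cover the experimental designs: a half-spindle
#' selection (half-spindle FRAP) and a stripe perpendicular to the spindle
#' axis (photoactivation; the default stripe width is the 2 um used at the
#' microscope).
#'
#' @param kind `"bleach"` (fluorescent -> dark) or `"activate"`
#'   (dark -> fluorescent).
#' @param frame_index 1-based index of the first frame rendered after the
#'   event.
#' @param region `"half"` or `"stripe"`.
#' @param side For `region = "half"`: `"left"` (axis coordinate x < 0) or
#'   `"right"` (x > 0); x is measured along the spindle axis from the
#'   spindle centre.
#' @param center_x_um For `region = "stripe"`: stripe centre on the spindle
#'   axis, um from the spindle centre (negative = left half).
#' @param width_um Stripe full width in um (default 2).
#' @param efficiency Per-molecule conversion probability in \[0, 1\].
#'
#' @return A `photo_event` list.
#' @export
photo_event <- function(kind = c("bleach", "activate"), frame_index,
                        region = c("half", "stripe"),
                        side = c("left", "right"),
                        center_x_um = 0, width_um = 2, efficiency = 1) {
  kind <- match.arg(kind)
  region <- match.arg(region)
  side <- match.arg(side)
  if (!is_scalar_num(frame_index) || frame_index < 1)
    stop_sf("photo_event: `frame_index` must be a positive frame number")
  if (!is_scalar_num(efficiency) || efficiency < 0 || efficiency > 1)
    stop_sf("photo_event: `efficiency` must lie in [0, 1]")
  if (region == "stripe" && (!is_scalar_num(width_um) || width_um <= 0))
    stop_sf("photo_event: stripe `width_um` must be positive")
  structure(list(kind = kind, frame_index = as.integer(frame_index),
                 region = region, side = side,
                 center_x_um = center_x_um, width_um = width_um,
                 efficiency = efficiency),
            class = "photo_event")
}

#' Configure the stochastic spindle simulator
#'
#' Defines the virtual metaphase spindle: its geometry, the
#' binding/unbinding kinetics of the reporter, transport (poleward lattice
#' flux plus optional motor-driven states), the photo-events to command,
#' and the camera model. Defaults describe a HeLa-scale metaphase spindle
#' (10 um pole-to-pole) imaged at 0.1 um/px with a 5-s frame interval for
#' 120 s, the FRAP design used throughout; the chromosome band is the
#' central +/- 1 um where a Ran-GTP-like on-rate boost can be applied.
#'
#' All rates are per second, velocities in um/min (converted internally),
#' lengths in um.
#'
#' @param spindle_length Pole-to-pole distance (um).
#' @param spindle_half_width Transverse half-width at the equator (um); the
#'   spindle envelope tapers elliptically to the poles.
#' @param chromosome_band_halfwidth Half-width of the chromosome band
#'   around the spindle centre (um); must be < `spindle_length / 2`.
#' @param pixel_size Rendered pixel size (um/px).
#' @param frame_interval Time between rendered frames (s).
#' @param n_frames Number of rendered frames.
#' @param dt_sim Stochastic sub-step (s); must divide `frame_interval`.
#' @param n_molecules Number of reporter molecules.
#' @param k_on_base Binding rate outside the chromosome band (1/s).
#' @param k_on_chrom_boost Multiplier on `k_on_base` inside the band.
#' @param k_off Unbinding rate (1/s): a scalar, or a named triple
#'   `c(pole = , intermediate = , chromosome = )` applied by axial thirds
#'   of each half-spindle.
#' @param flux_velocity Poleward advection of bound, non-motor molecules
#'   (um/min), directed away from the spindle centre.
#' @param motor_poleward_velocity,motor_equatorward_velocity Speeds of the
#'   two motor-bound states (um/min).
#' @param p_motor_poleward,p_motor_equatorward Probability that a binding
#'   event enters the respective motor state; their sum must be <= 1.
#' @param diffusion_coeff_unbound Diffusion coefficient of the unbound
#'   state (um^2/s).
#' @param photo_events List of [photo_event()]s.
#' @param background_level Camera background offset (counts).
#' @param photons_per_molecule Expected integrated counts per fluorescent
#'   molecule per frame.
#' @param read_noise_sd Additive Gaussian read noise (counts).
#' @param reference_level Peak intensity of the static tubulin-like
#'   reference channel (counts).
#' @param chrom_gap_depth Fractional dip of the reference channel inside
#'   the chromosome band (the "gap of MT staining" used to locate the
#'   chromosome edges); 0 disables the gap.
#' @param initially_fluorescent `TRUE` for FRAP-type bright-by-default
#'   reporters, `FALSE` for dark photoactivatable reporters.
#' @param burn_in_s Equilibration time simulated before the first frame (s).
#' @param image_margin_um Dark margin around the spindle in the rendered
#'   field (um); the modelled cytoplasm itself ends at the poles, where
#'   unbound molecules reflect.
#' @param rng_seed Integer seed; identical configurations with identical
#'   seeds give bit-identical stacks.
#'
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(spindle_length = 10,
                              spindle_half_width = 2.5,
                              chromosome_band_halfwidth = 1,
                              pixel_size = 0.1,
                              frame_interval = 5,
                              n_frames = 25,
                              dt_sim = 0.1,
                              n_molecules = 20000,
                              k_on_base = 0.3,
                              k_on_chrom_boost = 1,
                              k_off = 0.0277,
                              flux_velocity = 0,
                              motor_poleward_velocity = 0,
                              motor_equatorward_velocity = 0,
                              p_motor_poleward = 0,
                              p_motor_equatorward = 0,
                              diffusion_coeff_unbound = 20,
                              photo_events = list(),
                              background_level = 10,
                              photons_per_molecule = 50,
                              read_noise_sd = 2,
                              reference_level = 400,
                              chrom_gap_depth = 0.6,
                              initially_fluorescent = TRUE,
                              burn_in_s = 30,
                              image_margin_um = 2,
                              rng_seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos_scalar <- c("spindle_length", "spindle_half_width",
                  "chromosome_band_halfwidth", "pixel_size",
                  "frame_interval", "dt_sim")
  for (f in pos_scalar)
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0)
      stop_sf("invalid config: `%s` must be a positive scalar", f)
  nonneg <- c("k_on_base", "k_on_chrom_boost", "flux_velocity",
              "motor_poleward_velocity", "motor_equatorward_velocity",
              "p_motor_poleward", "p_motor_equatorward",
              "diffusion_coeff_unbound", "background_level",
              "photons_per_molecule", "read_noise_sd", "reference_level",
              "burn_in_s", "image_margin_um")
  for (f in nonneg)
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] < 0)
      stop_sf("invalid config: `%s` must be a non-negative scalar", f)
  if (!is.numeric(cfg$k_off) || any(cfg$k_off < 0) ||
      !length(cfg$k_off) %in% c(1L, 3L))
    stop_sf("invalid config: `k_off` must be a non-negative scalar or triple")
  if (length(cfg$k_off) == 3L &&
      !setequal(names(cfg$k_off), c("pole", "intermediate", "chromosome")))
    stop_sf("invalid config: a `k_off` triple must be named pole/intermediate/chromosome")
  if (cfg$p_motor_poleward + cfg$p_motor_equatorward > 1)
    stop_sf("invalid config: `p_motor_poleward` + `p_motor_equatorward` must be <= 1")
  if (cfg$n_frames < 1 || cfg$n_molecules < 1)
    stop_sf("invalid config: `n_frames` and `n_molecules` must be >= 1")
  if (cfg$dt_sim > cfg$frame_interval + 1e-9)
    stop_sf("invalid config: `dt_sim` must not exceed `frame_interval`")
  steps <- cfg$frame_interval / cfg$dt_sim
  if (abs(steps - round(steps)) > 1e-9)
    stop_sf("invalid config: `dt_sim` must divide `frame_interval` evenly")
  if (cfg$chromosome_band_halfwidth >= cfg$spindle_length / 2)
    stop_sf("invalid config: `chromosome_band_halfwidth` must be < spindle_length/2")
  if (cfg$chrom_gap_depth < 0 || cfg$chrom_gap_depth >= 1)
    stop_sf("invalid config: `chrom_gap_depth` must lie in [0, 1)")
  for (ev in cfg$photo_events) {
    if (!inherits(ev, "photo_event"))
      stop_sf("invalid config: `photo_events` must be photo_event objects")
    if (ev$frame_index > cfg$n_frames)
      stop_sf("invalid config: photo_event `frame_index` %d exceeds n_frames %d",
              ev$frame_index, cfg$n_frames)
    if (ev$region == "stripe" &&
        abs(ev$center_x_um) > cfg$spindle_length / 2 + cfg$image_margin_um)
      stop_sf("invalid config: photo_event `center_x_um` outside the field")
  }
  invisible(cfg)
}

#' Read or write a simulator configuration as YAML
#'
#' Field names in the file mirror [simulation_config()] arguments exactly;
#' photo events are nested lists with the [photo_event()] fields.
#'
#' @param path YAML file path.
#' @return [read_config()]: a `simulation_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  evs <- lapply(raw$photo_events, function(e) do.call(photo_event, e))
  raw$photo_events <- NULL
  raw$k_off <- unlist(raw$k_off)
  args <- raw[names(raw) %in% names(formals(simulation_config))]
  do.call(simulation_config, c(args, list(photo_events = evs)))
}

#' @rdname read_config
#' @param config A `simulation_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$k_off <- as.list(out$k_off)
  out$photo_events <- lapply(out$photo_events, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}
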