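# Registration, segmentation, axis, zones, traces, profiles, ratios.

make_ref_stack <- function(n_frames = 2L, seed = 1L) {
  cfg <- simulation_config(n_molecules = 3000, n_frames = n_frames,
                           burn_in_s = 2, rng_seed = seed)
  simulate_spindle(cfg)$stack
}

test_that("rigid registration recovers known shifts and rotations", {
  stack <- make_ref_stack()
  ref <- get_frame(stack, 1L, "reference")
  ny <- nrow(ref); nx <- ncol(ref)

  # integer shift: content moved by dx = +3, dy = -2
  shifted <- matrix(min(ref), ny, nx)
  shifted[1:(ny - 2), 4:nx] <- ref[3:ny, 1:(nx - 3)]
  est <- spindleflux:::estimate_rigid(ref, shifted)
  expect_lt(abs(est[["dx"]] - 3), 0.5)
  expect_lt(abs(est[["dy"]] - (-2)), 0.5)
  expect_lt(abs(est[["theta"]]), 0.5)

  # 5 degree rotation about the image centre (independent construction)
  rot <- EBImage::imageData(EBImage::rotate(EBImage::Image(ref), 5,
                                            output.dim = c(ny, nx)))
  est_r <- spindleflux:::estimate_rigid(ref, matrix(rot, ny, nx))
  expect_lt(abs(abs(est_r[["theta"]]) - 5), 0.5)
  expect_lt(abs(est_r[["dx"]]), 1)

  # identical frames: identity transform
  est_0 <- spindleflux:::estimate_rigid(ref, ref)
  expect_lt(abs(est_0[["dx"]]), 0.1)
  expect_lt(abs(est_0[["dy"]]), 0.1)
  expect_lt(abs(est_0[["theta"]]), 0.1)

  flat <- stack
  flat$pixels[, 2, , ] <- 1
  expect_error(register_stack(flat), "constant")
})

test_that("register_stack applies one transform to both channels", {
  stack <- make_ref_stack(n_frames = 3L)
  # displace frame 2 of both channels by an integer shift
  shifted <- stack
  for (ch in 1:2) {
    img <- stack$pixels[2, ch, , ]
    out <- matrix(min(img), nrow(img), ncol(img))
    out[, 3:ncol(img)] <- img[, 1:(ncol(img) - 2)]
    shifted$pixels[2, ch, , ] <- out
  }
  reg <- register_stack(shifted)
  expect_lt(abs(reg$transforms$dx_px[2] - 2), 0.5)
  # registered frame 2 should again correlate highly with frame 1
  r <- cor(as.numeric(reg$stack$pixels[2, 1, , ]),
           as.numeric(shifted$pixels[1, 1, , ]))
  expect_gt(r, 0.8)
  expect_equal(reg$transforms$dx_px[1], 0)
})

test_that("segmentation recovers a bright ellipse and rejects bad inputs", {
  ny <- 80; nx <- 120
  yg <- matrix(1:ny, ny, nx); xg <- matrix(1:nx, ny, nx, byrow = TRUE)
  inside <- ((xg - 60) / 45)^2 + ((yg - 40) / 18)^2 <= 1
  set.seed(1)
  img <- 10 + 90 * inside + matrix(rnorm(ny * nx, 0, 3), ny, nx)
  mask <- segment_spindle(img)
  iou <- sum(mask & inside) / sum(mask | inside)
  expect_gt(iou, 0.9)

  # two components: only the larger is kept
  img2 <- img
  img2[5:8, 5:8] <- 120
  mask2 <- segment_spindle(img2)
  expect_false(any(mask2[5:8, 5:8]))
  expect_gt(sum(mask2 & inside) / sum(mask2 | inside), 0.9)

  # inverted contrast must fail loudly, never return an inverted mask
  expect_error(segment_spindle(max(img) - img), "inverted|empty")
  expect_error(segment_spindle(matrix(1, 10, 10)), "constant")
})

test_that("axis detection finds poles, length, and chromosome edges", {
  stack <- make_ref_stack()
  ref <- get_frame(stack, 1L, "reference")
  mask <- segment_spindle(ref)
  ax <- find_axis(mask, ref, stack$pixel_size)
  g <- spindleflux:::render_geometry(stack$config)
  # true poles at x = -5 and +5 um on the centre row
  expect_lt(abs(ax$pole_a[1] - (g$cx - 50)), 2)
  expect_lt(abs(ax$pole_b[1] - (g$cx + 50)), 2)
  expect_lt(abs(ax$pole_a[2] - g$cy), 2)
  expect_lt(abs(measure_spindle_length(ax) - 10) / 10, 0.05)
  # chromosome edges near the configured band edges (+/- 1 um about centre),
  # symmetric about the midpoint
  expect_lt(abs(ax$chrom_edges_um[1] - 4), 0.3)
  expect_lt(abs(ax$chrom_edges_um[2] - 6), 0.3)
  expect_lt(abs((ax$chrom_edges_um[1] + ax$chrom_edges_um[2]) / 2 -
                  measure_spindle_length(ax) / 2), 0.15)

  # user-supplied edges are echoed unchanged
  ax2 <- find_axis(mask, ref, stack$pixel_size, chrom_edges_um = c(4.2, 5.9))
  expect_equal(ax2$chrom_edges_um, c(4.2, 5.9))

  # round mask is rejected
  round_mask <- matrix(FALSE, 50, 50)
  round_mask[((row(round_mask) - 25)^2 + (col(round_mask) - 25)^2) < 100] <- TRUE
  expect_error(find_axis(round_mask), "round")
})

test_that("spindle length follows Euclidean distance and pixel size", {
  ax <- structure(list(pole_a = c(0, 0), pole_b = c(30, 40),
                       pixel_size = 0.1), class = "spindle_axis")
  expect_equal(measure_spindle_length(ax), 5.0)
  ax$pixel_size <- 0.2
  expect_equal(measure_spindle_length(ax), 10.0)
})

test_that("compartmentalization partitions the mask into six labeled zones", {
  # rectangular mask with a manually supplied axis along its long midline
  ny <- 60; nx <- 120
  mask <- matrix(FALSE, ny, nx)
  mask[16:45, 11:110] <- TRUE
  ax <- structure(list(pole_a = c(11, 30), pole_b = c(110, 30),
                       pixel_size = 0.1,
                       chrom_edges_um = c(4.4, 5.5)), class = "spindle_axis")
  ax$length_um <- measure_spindle_length(ax)
  zones <- compartmentalize(mask, ax, bleach_range_um = c(0, 4.0))
  lab <- zones$labels
  # partition law: union over zones = mask, zones disjoint by construction
  expect_equal(lab > 0, mask)
  counts <- tabulate(lab[lab > 0], 6)
  expect_true(all(counts > 0))
  # rectangle: six zones of equal pixel count within rounding
  expect_lt(diff(range(counts)) / mean(counts), 0.1)
  # bleach on the pole-A side labels that side bleached
  expect_equal(zones$bleached_side, "A")
  left_cols <- lab[, 11:59]
  expect_true(all(left_cols[left_cols > 0] <= 3))

  # ambiguous bleach geometry straddling the midpoint errors
  expect_error(compartmentalize(mask, ax, bleach_range_um = c(3.5, 6.4)),
               "ambiguous")
})

test_that("zone traces report ROI means with linear response", {
  stack <- make_ref_stack()
  ref <- get_frame(stack, 1L, "reference")
  mask <- segment_spindle(ref)
  ax <- find_axis(mask, ref, stack$pixel_size)
  zones <- compartmentalize(mask, ax, c(0, ax$length_um / 2))

  # uniform reporter -> constant traces equal to the value
  flat <- stack
  flat$pixels[, 1, , ] <- 4
  tr <- extract_zone_traces(flat, zones,
                            background_roi = list(x = c(1, 5), y = c(1, 5)))
  expect_true(all(tr$mean_intensity == 4))
  expect_true(all(tr$background == 4))

  # doubling the second frame doubles its trace (linearity)
  lin <- stack
  lin$pixels[2, 1, , ] <- 2 * lin$pixels[1, 1, , ]
  tr2 <- extract_zone_traces(lin, zones)
  ws <- dplyr::filter(tr2, roi == "whole_spindle")
  expect_equal(ws$mean_intensity[2] / ws$mean_intensity[1], 2, tolerance = 1e-12)

  # checkerboard 0/10 -> mean 5
  chk <- stack
  board <- matrix(0, dim(stack$pixels)[3], dim(stack$pixels)[4])
  board[(row(board) + col(board)) %% 2 == 0] <- 10
  chk$pixels[1, 1, , ] <- board
  tr3 <- extract_zone_traces(chk, zones)
  ws3 <- dplyr::filter(tr3, roi == "whole_spindle", frame == 1)
  expect_lt(abs(ws3$mean_intensity - 5), 0.2)
})

test_that("line profiles average across the stated physical width", {
  ny <- 80; nx <- 120
  ax <- structure(list(pole_a = c(11, 40), pole_b = c(110, 40),
                       pixel_size = 0.1), class = "spindle_axis")
  ax$length_um <- measure_spindle_length(ax)

  flat <- matrix(3, ny, nx)
  p <- extract_profile(flat, ax, width_um = 2)
  expect_true(all(abs(p$intensity - 3) < 1e-12))
  expect_equal(attr(p, "width_used_um"), 2)
  # widening the band on a uniform image changes nothing
  p4 <- extract_profile(flat, ax, width_um = 4)
  expect_true(all(abs(p4$intensity - 3) < 1e-12))

  # bright line perpendicular to the axis at 40% of the span
  img <- matrix(0, ny, nx)
  img[, 11 + round(0.4 * 99)] <- 50
  p2 <- extract_profile(img, ax, width_um = 2)
  peak_frac <- p2$position_um[which.max(p2$intensity)] / max(p2$position_um)
  expect_lt(abs(peak_frac - 0.4), 0.02)

  # linearity: scaling pixels scales the profile
  p3 <- extract_profile(2.5 * img, ax, width_um = 2)
  expect_equal(p3$intensity, 2.5 * p2$intensity, tolerance = 1e-12)

  # band partially outside the image is clipped with a warning
  ax_edge <- structure(list(pole_a = c(11, 3), pole_b = c(110, 3),
                            pixel_size = 0.1), class = "spindle_axis")
  ax_edge$length_um <- measure_spindle_length(ax_edge)
  expect_warning(pe <- extract_profile(flat, ax_edge, width_um = 4),
                 "clipped")
  expect_true(attr(pe, "clipped"))
})

test_that("spindle-bound ratio divides masked means", {
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  rep_img <- matrix(10, 2, 2)
  ref_img <- matrix(4, 2, 2)
  expect_equal(spindle_bound_ratio(rep_img, ref_img, mask), 2.5)
  expect_equal(spindle_bound_ratio(ref_img, ref_img, mask), 1.0)
  expect_equal(spindle_bound_ratio(2 * ref_img, ref_img, mask), 2.0)
  expect_error(spindle_bound_ratio(rep_img, ref_img - 4, mask), "<= 0")
})
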