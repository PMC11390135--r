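test_that("Eq. (1) oracle: quarter-stepped cosine fringes demodulate exactly", {
  set.seed(8)
  phi <- matrix(runif(64 * 64, -pi, pi), 64)
  B <- matrix(runif(64 * 64, 0.5, 2), 64)
  A <- 2
  U <- lapply(1:3, function(k) A + B * cos(phi + (k - 2) * pi / 2))
  E <- stps_field(U[[1]], U[[2]], U[[3]], 1e-6)
  expected <- (sqrt(2) / 4) * B * exp(1i * (phi - pi / 4))
  expect_lt(max(Mod(E$values - 1 - expected)), 1e-10)
  ## no fringes: differences cancel any DC regardless of its level
  U0 <- lapply(1:3, function(k) matrix(7.3, 16, 16))
  E0 <- stps_field(U0[[1]], U0[[2]], U0[[3]], 1e-6)
  expect_equal(E0$values, matrix(1 + 0i, 16, 16))
  expect_error(stps_field(matrix(1, 2, 2), matrix(1, 3, 3), matrix(1, 2, 2),
                          1e-6), "shape")
})

test_that("triplet selection applies the one-diameter rule with guards", {
  op <- fx_optics()
  mk_track <- function(v_um_s, frames = 1:100) {
    d <- data.frame(frame = frames, t_s = (frames - 1) * op$frame_interval,
                    x_um = 40,
                    y_um = 30 + v_um_s * (frames - 1) * op$frame_interval,
                    radius_um = 5, area = 100)
    structure(list(cell_id = 1, detections = d, slope_um_s = 0,
                   intercept_um = 40, v_um_s = v_um_s,
                   z_estimates = data.frame()), class = "cell_track")
  }
  ## printed-rule arithmetic: R = 5 um, v = 500 um/s, dt = 0.998 ms -> k = 20
  tr <- mk_track(500)
  tri <- select_triplet(tr, op, anchor_frame = 50, quadrature_window = 0)
  expect_equal(tri$k, 20L)
  expect_equal(tri$frames, c(30L, 50L, 70L))
  ## consecutive displacement ~ one diameter
  expect_equal(tri$centers[3, 2] - tri$centers[2, 2], 10, tolerance = 0.02)
  ## quadrature snapping stays within the window and improves the step
  tri_q <- select_triplet(tr, op, anchor_frame = 50)
  expect_lte(abs(tri_q$k - 20L), 5L)
  expect_lte(abs(abs(tri_q$phase_step) - pi / 2),
             abs(abs(tri$phase_step) - pi / 2) + 1e-12)
  expect_error(select_triplet(mk_track(0), op, 50), "static")
  expect_error(select_triplet(tr, op, anchor_frame = 1), "span")
  ## too-fast crossing: k = 0
  fast <- mk_track(50000)
  expect_error(select_triplet(fast, op, 50), "under one frame")
})

test_that("ROI extraction registers to sub-pixel shifts and guards edges", {
  set.seed(2)
  pitch <- 0.1465e-6
  scene <- matrix(runif(400 * 400), 400)
  ## two integer-offset crops of the same static scene cross-correlate at -delta
  c1 <- c(199, 199) * pitch * 1e6            # 1-based pixel 200 as (x, y) um
  roi1 <- extract_roi(scene, c1, 64, pitch)
  delta <- c(5, -3)
  c2 <- c1 + delta * pitch * 1e6
  roi2 <- extract_roi(scene, c2, 64, pitch)
  xc <- Re(stats::fft(Conj(stats::fft(roi1 - mean(roi1))) *
                        stats::fft(roi2 - mean(roi2)), inverse = TRUE))
  pk <- arrayInd(which.max(xc), dim(xc)) - 1
  pk <- ifelse(pk > 32, pk - 64, pk)
  expect_equal(as.integer(pk), -delta)
  ## integer-pixel center reproduces a plain crop
  expect_equal(roi1, scene[168:231, 168:231], tolerance = 1e-12)
  ## a smooth scene shifts with sub-pixel accuracy
  xs <- seq_len(400)
  smooth <- outer(sin(xs / 23), cos(xs / 31)) + 2
  r_half <- extract_roi(smooth, c1 + c(0.5, 0) * pitch * 1e6, 64, pitch)
  interp <- (smooth[168:231, 168:231] + smooth[169:232, 168:231]) / 2
  expect_lt(max(abs(r_half - interp)), 0.01)
  expect_equal(dim(r_half), c(64, 64))
  expect_error(extract_roi(scene, c(2, 2), 64, pitch), "clipped")
})

test_that("STPS retrieves the axial position of a simulated flowing cell", {
  vid <- fx_single()
  op <- fx_optics()
  res <- fx_single_track()
  expect_equal(length(res$tracks), 1)
  tr <- res$tracks[[1]]
  expect_gte(nrow(tr$z_estimates), 1)
  good <- tr$z_estimates[!tr$z_estimates$low_confidence, ]
  expect_gte(nrow(good), 1)
  expect_lt(abs(good$z_um[1] - vid$cell$z * 1e6), 1.5)
})

test_that("an in-focus cell refocuses to z near zero", {
  op <- fx_optics()
  v <- stps_matched_velocity(6e-6, 20, op)
  cl <- cell_spec(300 * op$object_pitch, 200 * op$object_pitch, 0,
                  6e-6, 2.5, v)
  cfg <- sim_config(op, list(cl), n_frames = 50, noise_level = 0, seed = 3)
  vid <- render_video(cfg)
  frames <- c(5, 25, 45)
  ctr <- t(vapply(frames, function(f)
    holoflow:::.sim_cell_center_px(cl, op, f), numeric(2))) *
    op$object_pitch * 1e6
  rois <- lapply(1:3, function(i)
    extract_roi(vid$stack$frames[[frames[i]]], ctr[i, ], 256,
                op$object_pitch))
  res <- suppressWarnings(
    stps_axial_position(rois[[1]], rois[[2]], rois[[3]], op,
                        phase_step = pi / 2))
  expect_false(res$low_confidence)
  expect_lt(abs(res$z), 0.5e-6)
})

test_that("cell-free ROIs give a low-confidence flag", {
  op <- fx_optics()
  cfg <- sim_config(op, list(), n_frames = 3, noise_level = 0.005, seed = 4)
  vid <- render_video(cfg)
  ctr <- c(300, 400) * op$object_pitch * 1e6
  rois <- lapply(1:3, function(i)
    extract_roi(vid$stack$frames[[i]], ctr, 256, op$object_pitch))
  res <- suppressWarnings(
    stps_axial_position(rois[[1]], rois[[2]], rois[[3]], op,
                        phase_step = pi / 2))
  expect_true(res$low_confidence)
  expect_true(is.na(res$z))
})

test_that("off-quadrature carrier steps trigger a warning", {
  op <- fx_optics()
  carrier <- 2 * pi * outer(op$carrier_freq[1] * (0:63),
                            op$carrier_freq[2] * (0:63), `+`)
  U <- lapply(1:3, function(k) 2 + cos(carrier + (k - 2) * pi / 2))
  expect_warning(
    stps_axial_position(U[[1]], U[[2]], U[[3]], op,
                        z_range = c(-2e-6, 2e-6), coarse_step = 1e-6,
                        phase_step = 0.4),
    "deviates")
})
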