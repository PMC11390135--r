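test_that("a cell-free normalized frame yields no detections", {
  op <- default_optics(sensor_rows = 400L, sensor_cols = 512L)
  cfg <- sim_config(op, list(), n_frames = 6, noise_level = 0.005, seed = 2)
  vid <- render_video(cfg)
  ds <- downsample_stack(vid$stack)
  norm <- remove_background(ds, ssm_background(ds))
  d <- locate_cells_frame(norm$frames[[6]], norm$pitch)
  expect_equal(nrow(d), 0)
})

test_that("detections recover simulated positions to sub-pixel accuracy", {
  vid <- fx_flow()
  res <- fx_proposed()
  mt <- match_truth(res$tracks, vid$truth)
  ## <= 2 down-sampled pixels (0.586 um); in practice far below
  expect_lt(mean(abs(mt$dx)), 0.586)
  expect_lt(mean(abs(mt$dy)), 0.586)
  expect_lt(mean(abs(mt$dx)), 0.1)
  ## two well-separated cells -> two detections ordered by x
  f <- res$detections[res$detections$frame == 50, ]
  expect_equal(nrow(f), 2)
  expect_true(all(diff(f$x_um) > 0))
})

test_that("every persistent cell yields exactly one track", {
  vid <- fx_flow()
  res <- fx_proposed()
  expect_equal(length(res$tracks), length(vid$cfg$cells))
  mt <- match_truth(res$tracks, vid$truth)
  expect_equal(sort(mt$matches$cell_id), seq_along(vid$cfg$cells))
})

test_that("the STTL matrix has full-resolution rows and per-frame support", {
  op <- fx_optics()
  ## static cell: one horizontal line across all frames
  det <- data.frame(frame = 1:40, x_um = 30, y_um = 50, radius_um = 5,
                    area = 100)
  sttl <- build_sttl(det, op, n_frames = 40)
  expect_equal(dim(sttl$values), c(600, 40))
  expect_equal(sum(sttl$values), 40)
  rows <- which(rowSums(sttl$values) > 0)
  expect_equal(length(rows), 1)
  ## presence only in frames [10, 50)
  det2 <- data.frame(frame = 10:49, x_um = 30 + 0.1 * (0:39), y_um = 1,
                     radius_um = 5, area = 100)
  sttl2 <- build_sttl(det2, op, n_frames = 60)
  expect_equal(which(colSums(sttl2$values) > 0), 10:49)
})

test_that("a drifting cell's STTL slope matches its drift velocity", {
  op <- fx_optics()
  v <- stps_matched_velocity(6e-6, 20, op)
  cl <- cell_spec(200 * op$object_pitch, 150 * op$object_pitch, 5e-6,
                  6e-6, 2, v, vx = 20e-6)
  cfg <- sim_config(op, list(cl), n_frames = 80, noise_level = 0.005,
                    seed = 9)
  vid <- render_video(cfg)
  ds <- downsample_stack(vid$stack)
  norm <- remove_background(ds, ssm_background(ds))
  dets <- detect_stack(norm)
  sttl <- build_sttl(dets, op, n_frames = 80)
  marks <- which(sttl$values > 0, arr.ind = TRUE)
  fit <- stats::lm.fit(cbind(1, (marks[, 2] - 1) * sttl$t_scale),
                       (marks[, 1] - 1) * sttl$x_scale)
  expect_equal(unname(fit$coefficients[2]), 20, tolerance = 0.05)
})

test_that("linking separates parallel cells and bridges single-frame gaps", {
  dt <- 1e-3
  mk <- function(frames, x, y) data.frame(frame = frames, x_um = x,
                                          y_um = y, radius_um = 5,
                                          area = 100)
  two <- rbind(mk(1:30, 20, 10 + 0.5 * (0:29)),
               mk(1:30, 60, 12 + 0.5 * (0:29)))
  tr <- link_tracks(two, dt, max_jump = 3)
  expect_equal(length(tr), 2)
  expect_true(all(vapply(tr, function(t) nrow(t$detections), numeric(1)) ==
                    30))
  expect_equal(sort(vapply(tr, function(t) median(t$detections$x_um),
                           numeric(1))), c(20, 60))
  ## one missing frame is bridged into a single track
  gap <- mk(c(1:10, 12:25), 20, 10 + 0.5 * c(0:9, 11:24))
  trg <- link_tracks(gap, dt, max_jump = 3, bridge = 1)
  expect_equal(length(trg), 1)
  ## with bridging off the track splits
  trs <- link_tracks(gap, dt, max_jump = 3, bridge = 0)
  expect_equal(length(trs), 2)
  ## short tracks are discarded
  expect_equal(length(link_tracks(mk(1:3, 5, 5), dt, min_length = 5)), 0)
})

test_that("track line fit and velocity behave on exact and noisy inputs", {
  dt <- 1e-3
  mk_track <- function(x, y, frames = seq_along(x)) {
    d <- data.frame(frame = frames, x_um = x, y_um = y, radius_um = 5,
                    area = 100)
    d$t_s <- (d$frame - 1) * dt
    structure(list(cell_id = 1,
                   detections = d[, c("frame", "t_s", "x_um", "y_um",
                                      "radius_um", "area")],
                   slope_um_s = NA, intercept_um = NA, v_um_s = NA,
                   z_estimates = data.frame()),
              class = "cell_track")
  }
  t1 <- mk_track(10 + 3 * (0:19) * dt * 1e3, 5 + 0.5 * (0:19))
  fit <- fit_track_line(t1)
  expect_equal(unname(fit["slope"]), 3000, tolerance = 1e-9)
  expect_equal(unname(fit["intercept"]), 10, tolerance = 1e-9)
  t2 <- mk_track(rep(4, 10), 1:10)
  expect_equal(unname(fit_track_line(t2)["slope"]), 0)
  ## exact constant motion: v = distance / duration identically
  t3 <- mk_track(rep(1, 11), 0.3 * (0:10))
  expect_equal(estimate_velocity(t3), 0.3 / dt, tolerance = 1e-9)
  expect_equal(estimate_velocity(mk_track(c(1, 1), c(2, 2))), 0)
  expect_error(estimate_velocity(mk_track(1, 2, frames = 1)),
               "zero-duration")
  ## noisy synthetic track: slope within 3 sigma of the sampling law
  set.seed(4)
  n <- 50; drift <- 12
  x <- 20 + drift * (0:(n - 1)) * dt + rnorm(n, 0, 0.3)
  tn <- mk_track(x, 1:n)
  se <- 0.3 / (dt * sqrt(sum(((0:(n - 1)) - mean(0:(n - 1)))^2)))
  expect_lt(abs(unname(fit_track_line(tn)["slope"]) - drift), 3 * se)
})

test_that("velocity estimates match simulated flow within 2 percent", {
  vid <- fx_flow()
  res <- fx_proposed()
  mt <- match_truth(res$tracks, vid$truth)
  expect_lt(max(abs(mt$matches$v_err_rel)), 0.02)
})

test_that("monitoring period and throughput follow the printed formulas", {
  expect_equal(monitoring_period(1, 0.998e-3), 0.998e-3)
  expect_equal(monitoring_period(200, 0.5e-3), 2 * monitoring_period(100, 0.5e-3))
  op <- default_optics()     # full 1200 x 1920 sensor
  expect_equal(cell_throughput(0, op, 11618), 0)
  expect_equal(cell_throughput(262, op, 11618),
               2 * cell_throughput(131, op, 11618))
  ## independent arithmetic of the cylinder-volume formula
  delta <- 5.86e-6 / 40
  vol <- pi * (1200 * delta / 2)^2 * (1920 * delta)
  expect_equal(cell_throughput(131, op, 11618),
               131 / (vol * 11618 * 0.998e-3), tolerance = 1e-12)
})

test_that("per-interval throughput bins cells by first appearance", {
  op <- fx_optics()
  mk <- function(id, f0) {
    d <- data.frame(frame = f0:(f0 + 9), t_s = (f0:(f0 + 9) - 1) * 1e-3,
                    x_um = 1, y_um = 1, radius_um = 5, area = 10)
    structure(list(cell_id = id, detections = d, slope_um_s = 0,
                   intercept_um = 0, v_um_s = 0,
                   z_estimates = data.frame()), class = "cell_track")
  }
  tracks <- list(mk(1, 1), mk(2, 3), mk(3, 55), mk(4, 90))
  tb <- throughput_by_interval(tracks, op, n_frames = 100, intervals = 10)
  expect_equal(tb$n_cells, c(2, 0, 0, 0, 0, 1, 0, 0, 1, 0))
  expect_equal(sum(tb$n_cells), 4)
  one <- cell_throughput(1, op, 100) * 10   # one cell in a tenth of the time
  expect_equal(tb$throughput[6], one, tolerance = 1e-12)
})
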