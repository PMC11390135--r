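test_that("half-size binning cancels a period-2 carrier and preserves means", {
  big <- matrix(0, 1200, 1920)
  expect_equal(dim(downsample_half(big)), c(600, 960))
  expect_equal(downsample_half(matrix(3.7, 10, 8)),
               matrix(3.7, 5, 4))
  fringe <- matrix(cos(pi * (0:99)), 100, 60)   # period-2 rows
  ds <- downsample_half(fringe)
  expect_equal(max(abs(ds - mean(ds))), 0, tolerance = 1e-12)
  expect_equal(mean(ds), 0, tolerance = 1e-12)
  expect_error(downsample_half(matrix(1, 1, 5)), "2 x 2")
  expect_message(downsample_half(matrix(1, 5, 4)), "trim")
})

test_that("ncc is the zero-mean correlation with hand-checked value", {
  a <- matrix(c(1, 2, 3, 4), 2)
  b <- matrix(c(1, 2, 3, 5), 2)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a), -1)
  expect_equal(ncc(a, b), 0.9827, tolerance = 1e-3)
  expect_error(ncc(a, matrix(1, 3, 3)), "shape")
  expect_error(ncc(a, matrix(2, 2, 2)), "variance")
})

test_that("SSM equals the temporal mean (transform-pair linearity oracle)", {
  vid <- fx_flow()
  ds <- downsample_stack(vid$stack)
  sub <- ds[1:40]
  bg <- ssm_background(sub)
  oracle <- Reduce(`+`, sub$frames) / 40
  expect_equal(bg$background, oracle, tolerance = 1e-10)
  ## identical frames: background equals the frame
  same <- hologram_stack(list(oracle, oracle, oracle), 1e-3, 1e-6)
  expect_equal(ssm_background(same)$background, oracle, tolerance = 1e-10)
  expect_error(ssm_background(sub, 1), "at least 2")
  expect_error(ssm_background(sub, 99), "exceeds")
})

test_that("both background methods recover the true background (NCC >= 0.98)", {
  vid <- fx_flow()
  tb <- downsample_half(true_background(vid$cfg))
  ds <- downsample_stack(vid$stack)
  expect_gte(ncc(ssm_background(ds)$background, tb), 0.98)
  expect_gte(ncc(sbmm_background(ds)$background, tb), 0.98)
})

test_that("SBMM on a cell-free video returns the static scene exactly", {
  op <- default_optics(sensor_rows = 120L, sensor_cols = 160L)
  cfg <- sim_config(op, list(), n_frames = 6, noise_level = 0)
  frame <- downsample_half(render_frame(cfg, 1))
  stack <- hologram_stack(rep(list(frame), 6), op$frame_interval,
                          2 * op$object_pitch)
  bg <- sbmm_background(stack, block_grid = c(4L, 4L))
  expect_equal(ncc(bg$background, frame), 1, tolerance = 1e-12)
  expect_true(all(lengths(bg$params$static_pairs) == 5))
})

test_that("a crossing cell suppresses static pairs only in its blocks", {
  vid <- fx_single()
  ds <- downsample_stack(vid$stack)
  sub <- ds[1:30]
  grid <- c(5L, 6L)
  bg <- suppressWarnings(sbmm_background(sub, block_grid = grid))
  ## cell row ~ 300 full-res -> down-sampled 150 of 300: block row 3;
  ## during frames 1..30 the cell spans columns ~ y0..y0+v*dt in ds px
  gt <- vid$truth[vid$truth$frame <= 30, ]
  row_blk <- ceiling((gt$x_um[1] * 1e-6 / ds$pitch) / (300 / grid[1]))
  col_px <- gt$y_um * 1e-6 / ds$pitch
  col_blks <- unique(ceiling(col_px / (480 / grid[2])))
  occupied <- (row_blk - 1) * grid[2] + col_blks
  far_block <- (grid[1] - 1) * grid[2] + grid[2]   # opposite corner
  n_pairs <- 29
  expect_lt(min(lengths(bg$params$static_pairs[occupied])), n_pairs)
  expect_equal(length(bg$params$static_pairs[[far_block]]), n_pairs)
})

test_that("background division normalizes static content to one", {
  vid <- fx_flow()
  ds <- downsample_stack(vid$stack)
  bg <- ssm_background(ds)
  ## stack equal to the background in every frame -> all-ones stack
  same <- hologram_stack(list(bg$background, bg$background),
                         ds$frame_interval, ds$pitch)
  ones <- remove_background(same, bg)
  expect_equal(ones$frames[[1]], matrix(1, 300, 480), tolerance = 1e-12)
  ## cell-free area of a real normalized frame has mean ~ 1
  norm <- remove_background(ds, bg)
  f <- norm$frames[[3]]
  truth3 <- vid$truth[vid$truth$frame == 3, ]
  rows_px <- truth3$x_um * 1e-6 / ds$pitch
  mask <- rep(TRUE, 300)
  for (r in rows_px) mask[abs(seq_len(300) - r) < 60] <- FALSE
  expect_equal(mean(f[mask, ]) , 1, tolerance = 0.01)
  ## epsilon flooring keeps output finite for zero backgrounds
  zbg <- holoflow:::.background_model(matrix(0, 2, 2), "SSM", list())
  z <- remove_background(hologram_stack(list(matrix(1, 2, 2)), 1e-3, 1e-6),
                         zbg)
  expect_true(all(is.finite(z$frames[[1]])))
  expect_error(remove_background(ds, zbg), "shape")
})

test_that("SBMM is at least as accurate as SSM on busier videos", {
  ## statistical tendency over 5 seeds on a denser scenario
  op <- default_optics(sensor_rows = 600L, sensor_cols = 960L)
  d_ssm <- d_sbmm <- numeric()
  for (seed in 101:105) {
    cfg <- sim_scenario_flow(op, n_cells = 3, n_frames = 50, seed = seed)
    vid <- render_video(cfg)
    tb <- downsample_half(true_background(cfg))
    ds <- downsample_stack(vid$stack)
    d_ssm <- c(d_ssm, ncc(ssm_background(ds)$background, tb))
    d_sbmm <- c(d_sbmm, suppressWarnings(
      ncc(sbmm_background(ds)$background, tb)))
    rm(vid, ds); gc(FALSE)
  }
  expect_gt(mean(d_sbmm), mean(d_ssm))
  expect_gte(min(d_ssm), 0.98)
  expect_gte(min(d_sbmm), 0.98)
})
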