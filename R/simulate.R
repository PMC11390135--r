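#' Specification of one simulated flowing cell
#'
#' A thin phase object translating at constant velocity along the flow axis
#' of the channel, at fixed transverse position and fixed defocus.
#'
#' @param x0 Transverse position (meters, maps to sensor rows).
#' @param y_entry Flow-axis position at frame 1 (meters, maps to columns).
#' @param z Axial defocus of the cell plane relative to the focal plane
#'   (meters; fixed per cell).
#' @param radius Cell radius in meters.
#' @param peak_phase Peak optical phase delay at the cell center (radians).
#' @param velocity Flow velocity along +y (meters/second, >= 0).
#' @param vx Optional transverse drift velocity along +x (meters/second,
#'   default 0).  Drifting cells produce sloped spatiotemporal tracking
#'   lines; the axial-retrieval scenario keeps \code{vx = 0} so the carrier
#'   phase step of a triplet is governed by the flow displacement alone.
#' @return An object of class \code{cell_spec}.
#' @export
cell_spec <- function(x0, y_entry, z, radius, peak_phase, velocity, vx = 0) {
  stopifnot(radius > 0, velocity >= 0, is.finite(peak_phase))
  structure(list(x0 = x0, y_entry = y_entry, z = z, radius = radius,
                 peak_phase = peak_phase, velocity = velocity, vx = vx),
            class = "cell_spec")
}

#' Simulation configuration for a synthetic hologram video
#'
#' @param optics An [optical_config()].
#' @param cells List of [cell_spec()] objects.
#' @param n_frames Number of frames to render (>= 1).
#' @param noise_level Relative scale of the multiplicative Gaussian
#'   approximation to shot noise (0 disables noise).
#' @param seed Integer seed making the rendered stack reproducible.
#' @param vignette_depth Depth of the static radial illumination falloff in
#'   \\[0, 1); together with the residual carrier fringes it constitutes the
#'   quasi-static background that the elimination methods must recover.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(optics, cells, n_frames, noise_level = 0.005,
                       seed = 1L, vignette_depth = 0.15) {
  stopifnot(inherits(optics, "optical_config"), n_frames >= 1,
            noise_level >= 0, vignette_depth >= 0, vignette_depth < 1)
  if (!all(vapply(cells, inherits, logical(1), "cell_spec")))
    stop("'cells' must be a list of cell_spec objects")
  fov_x <- optics$sensor_rows * optics$object_pitch
  for (cl in cells)
    if (cl$x0 < 0 || cl$x0 > fov_x)
      stop("cell x0 outside the field of view")
  structure(list(optics = optics, cells = cells,
                 n_frames = as.integer(n_frames),
                 noise_level = noise_level, seed = as.integer(seed),
                 vignette_depth = vignette_depth),
            class = "sim_config")
}

#' Flow velocity matched to a quarter-period carrier step
#'
#' The spatiotemporal phase-shifting triplet uses the three frames over which
#' a cell moves by its own diameter; the carrier phase then steps by
#' \eqn{2\pi f_{c,y} \delta_y} between consecutive region-of-interest
#' extractions (\eqn{\delta_y} the displacement in pixels).  This helper
#' snaps the velocity so that the displacement over \code{k} frames is the
#' multiple-of-4-plus-1 pixel count nearest to one cell diameter, realizing a
#' +pi/2 step for a 0.25 cycles/px flow-axis carrier.
#'
#' @param radius Cell radius in meters.
#' @param k Half-width of the triplet in frames (the cell covers one diameter
#'   in \code{k} frames).
#' @param optics An [optical_config()] (uses the object pitch, frame interval
#'   and flow-axis carrier frequency).
#' @return Velocity in meters/second.
#' @export
stps_matched_velocity <- function(radius, k, optics) {
  stopifnot(radius > 0, k >= 1)
  pitch <- optics$object_pitch
  fcy <- optics$carrier_freq[2]
  if (abs(fcy) < 1e-9) stop("flow-axis carrier frequency is zero")
  d_px <- 2 * radius / pitch              # diameter in pixels
  per <- 1 / (4 * abs(fcy))               # px per quarter carrier period
  ## nearest displacement with fractional carrier phase = +1/4 cycle
  n4 <- round((d_px - per) / (4 * per))
  d_snap <- (4 * n4 + 1) * per
  d_snap * pitch / (k * optics$frame_interval)
}

#' Complex transmittance of a model cell
#'
#' A phase-only disk with a smooth parabolic phase cap:
#' \eqn{t = \exp(i \phi_{max} \max(0, 1 - r^2/R^2))}.  The modulus is 1
#' everywhere and the mean phase over the disk is \eqn{\phi_{max}/2}.
#'
#' @param cell A [cell_spec()].
#' @param nrow,ncol Raster shape in pixels.
#' @param pitch Pixel pitch in meters (must equal the object pitch).
#' @param center Cell-center position in 1-based pixel units,
#'   length-2 (row, col); may be fractional.
#' @return Complex matrix of unit modulus.
#' @export
cell_transmittance <- function(cell, nrow, ncol, pitch,
                               center = c((nrow + 1) / 2, (ncol + 1) / 2)) {
  if (cell$radius < pitch)
    stop("cell radius below one pixel cannot be rendered")
  r2 <- outer(((seq_len(nrow) - center[1]) * pitch)^2,
              ((seq_len(ncol) - center[2]) * pitch)^2, `+`)
  phi <- cell$peak_phase * pmax(1 - r2 / cell$radius^2, 0)
  exp(1i * phi)
}

## ---- internal rendering machinery -------------------------------------

## patch size (px) large enough to hold the defocused diffraction pattern
.sim_patch_size <- function(cell, optics) {
  pitch <- optics$object_pitch
  spread <- cell$radius + abs(cell$z) * tan(asin(optics$na))
  p <- 2^ceiling(log2(2 * spread / pitch + 64))
  as.integer(min(max(p, 128), 1024))
}

## Precompute, per video: reference wave, vignette, and per-cell defocused
## patch spectra (so each cell-frame needs a single inverse FFT).
.sim_setup <- function(config) {
  op <- config$optics
  nx <- op$sensor_rows; ny <- op$sensor_cols
  m <- 0:(nx - 1); n <- 0:(ny - 1)
  refer <- op$reference_amplitude *
    exp(2i * pi * outer(op$carrier_freq[1] * m, op$carrier_freq[2] * n, `+`))
  rho2 <- outer((m / (nx - 1) - 0.5)^2, (n / (ny - 1) - 0.5)^2, `+`) / 0.5
  vignette <- 1 - config$vignette_depth * rho2
  cells <- lapply(config$cells, function(cl) {
    p <- .sim_patch_size(cl, op)
    tm1 <- cell_transmittance(cl, p, p, op$object_pitch,
                              center = c(p / 2 + 1, p / 2 + 1)) - 1
    ## scattered wave at the camera plane, relative to an illumination plane
    ## wave referenced to unit phase AT the camera: the illumination reaches
    ## the cell plane with phase exp(2 pi i z / lambda), so the cell's
    ## scattered term carries that factor in front of the propagated
    ## transmittance deviation.  Without it the defocused field would not be
    ## the exact propagation of the in-focus cell and refocusing criteria
    ## would not recover z.
    psi0 <- exp(2i * pi * cl$z / op$wavelength) *
      angular_spectrum_propagate(complex_field(tm1, op$object_pitch),
                                 -cl$z, op$wavelength)$values
    ## circular pupil of the objective: the imaging system passes object
    ## frequencies up to NA / lambda only
    fpx <- fft_freq(p) / op$object_pitch
    pupil <- outer(fpx^2, fpx^2, `+`) <= (op$na / op$wavelength)^2
    list(spec = fft2(psi0) * pupil, p = p,
         fx = fft_freq(p), fy = fft_freq(p), cell = cl)
  })
  list(refer = refer, vignette = vignette, cells = cells,
       nx = nx, ny = ny)
}

## 0-based pixel position of a cell center at a given frame (1-based)
.sim_cell_center_px <- function(cell, optics, frame) {
  t <- (frame - 1) * optics$frame_interval
  c((cell$x0 + cell$vx * t) / optics$object_pitch,
    (cell$y_entry + cell$velocity * t) / optics$object_pitch)
}

#' Render one off-axis hologram frame
#'
#' Builds the object wave as 1 plus the superposition of each cell's
#' transmittance deviation propagated from its defocus plane to the focal
#' plane (first-order superposition, valid for sparse flows), adds the tilted
#' plane reference wave, and records the intensity
#' \eqn{I = V \, |U + R|^2} under the static illumination vignette \eqn{V},
#' optionally perturbed by multiplicative noise.
#'
#' @param config A [sim_config()].
#' @param frame_index Frame to render, 1-based, <= \code{n_frames}.
#' @param setup Internal precomputation (from rendering a whole video);
#'   leave \code{NULL} to compute on the fly.
#' @param noise Apply the configured noise (uses the current RNG state).
#' @return Numeric intensity matrix (sensor_rows x sensor_cols), >= 0.
#' @export
render_frame <- function(config, frame_index, setup = NULL, noise = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            frame_index >= 1, frame_index <= config$n_frames)
  if (is.null(setup)) setup <- .sim_setup(config)
  op <- config$optics
  U <- matrix(1 + 0i, setup$nx, setup$ny)
  for (ci in setup$cells) {
    ctr <- .sim_cell_center_px(ci$cell, op, frame_index)
    p <- ci$p
    ri <- round(ctr[1]); cc <- round(ctr[2])
    i0 <- ri - p / 2      # 0-based row offset of patch top-left
    j0 <- cc - p / 2
    if (i0 + p < 1 || i0 >= setup$nx || j0 + p < 1 || j0 >= setup$ny) next
    shift <- exp(-2i * pi * outer(ci$fx * (ctr[1] - ri),
                                  ci$fy * (ctr[2] - cc), `+`))
    psi <- ifft2(ci$spec * shift)
    pr <- max(1, 1 - i0):min(p, setup$nx - i0)
    pc <- max(1, 1 - j0):min(p, setup$ny - j0)
    U[i0 + pr, j0 + pc] <- U[i0 + pr, j0 + pc] + psi[pr, pc]
  }
  I <- setup$vignette * Mod(U + setup$refer)^2
  if (noise && config$noise_level > 0)
    I <- pmax(I * (1 + config$noise_level * stats::rnorm(length(I))), 0)
  I
}

#' Static background of a simulated recording
#'
#' The noise-free frame with all flowing cells removed: the carrier fringe
#' pattern under the illumination vignette.  Serves as ground truth for the
#' background-elimination accuracy checks.
#'
#' @param config A [sim_config()].
#' @return Numeric intensity matrix.
#' @export
true_background <- function(config) {
  cfg0 <- config
  cfg0$cells <- list()
  render_frame(cfg0, 1L, noise = FALSE)
}

#' Render a synthetic hologram video with ground truth
#'
#' Renders \code{n_frames} off-axis holograms of the configured flowing
#' cells and tabulates the exact per-frame 3D ground truth of every cell
#' whose center lies inside the field of view.  Deterministic under the
#' configured seed (bit-identical stacks).
#'
#' @param config A [sim_config()].
#' @return List with \code{stack} (a [hologram_stack()]) and \code{truth}, a
#'   data.frame with columns \code{cell_id}, \code{frame}, \code{t_s},
#'   \code{x_um}, \code{y_um}, \code{z_um}, \code{radius_um}, \code{v_um_s}.
#' @export
render_video <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  op <- config$optics
  setup <- .sim_setup(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames))
    frames[[f]] <- render_frame(config, f, setup = setup, noise = TRUE)
  truth <- .sim_truth(config)
  list(stack = hologram_stack(frames, op$frame_interval, op$object_pitch),
       truth = truth)
}

.sim_truth <- function(config) {
  op <- config$optics
  rows <- list()
  for (j in seq_along(config$cells)) {
    cl <- config$cells[[j]]
    for (f in seq_len(config$n_frames)) {
      ctr <- .sim_cell_center_px(cl, op, f)
      if (ctr[1] < 0 || ctr[1] > op$sensor_rows - 1 ||
          ctr[2] < 0 || ctr[2] > op$sensor_cols - 1) next
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = j, frame = f, t_s = (f - 1) * op$frame_interval,
        x_um = ctr[1] * op$object_pitch * 1e6,
        y_um = ctr[2] * op$object_pitch * 1e6,
        z_um = cl$z * 1e6, radius_um = cl$radius * 1e6,
        v_um_s = cl$velocity * 1e6)
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = integer(), frame = integer(),
                      t_s = numeric(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), radius_um = numeric(),
                      v_um_s = numeric()))
  do.call(rbind, rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulated flow scenario with axially matched velocities
#'
#' Draws a sparse population of flowing cells in the style of the recording
#' the package emulates: radii 5-8 um, peak phase 1-3 rad, defocus uniform in
#' \\[-10, +10\\] um, flow velocities in the 300-700 um/s band snapped by
#' [stps_matched_velocity()] so each cell realizes ~pi/2 carrier steps across
#' its one-diameter triplet displacement.  Cells are spread across the
#' transverse axis with a minimum spacing so their diffraction patterns stay
#' separable, and staggered along the flow axis.
#'
#' @param optics An [optical_config()]; the default works on a 600 x 960 px
#'   sensor so a full video fits comfortably in memory.
#' @param n_cells Number of cells.
#' @param n_frames Frames to render.
#' @param seed Integer seed (cell draw and noise).
#' @param noise_level Relative noise scale.
#' @param drift_sd Standard deviation of transverse drift velocities in m/s
#'   (default 0: purely axial flow, required by the axial-retrieval study).
#' @return A [sim_config()].
#' @export
sim_scenario_flow <- function(optics = default_optics(sensor_rows = 600L,
                                                      sensor_cols = 960L),
                              n_cells = 3, n_frames = 120, seed = 1L,
                              noise_level = 0.005, drift_sd = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pitch <- optics$object_pitch
  fov_x <- optics$sensor_rows * pitch
  fov_y <- optics$sensor_cols * pitch
  margin <- 160 * pitch        # keep padded 256-px ROIs inside the frame
  lo <- margin; hi <- fov_x - margin
  if (hi <= lo) stop("sensor too small for the default scenario")
  ## evenly spaced transverse slots with ~1 um jitter
  slots <- if (n_cells == 1) (lo + hi) / 2 else seq(lo, hi, length.out = n_cells)
  x0 <- slots + stats::runif(n_cells, -1e-6, 1e-6)
  cells <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    radius <- stats::runif(1, 5e-6, 8e-6)
    v_want <- stats::runif(1, 300e-6, 700e-6)
    k <- max(1L, as.integer(round(2 * radius / (v_want * optics$frame_interval))))
    v <- stps_matched_velocity(radius, k, optics)
    vx <- if (drift_sd > 0) stats::rnorm(1, 0, drift_sd) else 0
    span <- v * (n_frames - 1) * optics$frame_interval
    y_max <- max(margin + pitch, fov_y - margin - span)
    y0 <- stats::runif(1, margin, max(margin + pitch, min(y_max, fov_y / 3)))
    cells[[j]] <- cell_spec(x0 = x0[j], y_entry = y0,
                            z = stats::runif(1, -10e-6, 10e-6),
                            radius = radius,
                            peak_phase = stats::runif(1, 1, 3),
                            velocity = v, vx = vx)
  }
  sim_config(optics, cells, n_frames, noise_level = noise_level, seed = seed)
}
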