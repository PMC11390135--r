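#' Optical configuration of an off-axis holographic recording
#'
#' Bundles the parameters of the interferometric recording geometry: source
#' wavelength, objective magnification and numerical aperture, camera pixel
#' pitch and sensor shape, frame interval, and the spatial carrier frequency
#' of the off-axis fringes.  The object-space pixel pitch is derived as
#' \code{camera_pitch / magnification}.
#'
#' @param wavelength Source wavelength in meters.
#' @param magnification Lateral magnification of the imaging system
#'   (dimensionless, > 0).
#' @param na Numerical aperture of the objective, in (0, 1).
#' @param camera_pitch Camera pixel size in meters.
#' @param sensor_rows,sensor_cols Sensor shape in pixels.  Rows map to the
#'   transverse (x, across-channel) axis, columns to the flow (y) axis.
#' @param frame_interval Time between frames in seconds.
#' @param carrier_freq Length-2 numeric, carrier frequency of the off-axis
#'   fringes in cycles per camera pixel along (rows, cols).  An off-axis
#'   system places this near the Nyquist limit (fringe period about 2 px).
#' @param reference_amplitude Amplitude of the reference wave relative to the
#'   unit-amplitude illumination.
#'
#' @return An object of class \code{optical_config}; a list with the fields
#'   above plus \code{object_pitch} (meters per pixel in object space).
#' @examples
#' cfg <- optical_config(532e-9, 40, 0.65, 5.86e-6, 1200, 1920, 0.998e-3)
#' cfg$object_pitch * 1e6   # 0.1465 um
#' @export
optical_config <- function(wavelength, magnification, na, camera_pitch,
                           sensor_rows, sensor_cols, frame_interval,
                           carrier_freq = c(0.47, 0.25),
                           reference_amplitude = 1) {
  stopifnot(wavelength > 0, magnification > 0, na > 0, na < 1,
            camera_pitch > 0, sensor_rows >= 2, sensor_cols >= 2,
            frame_interval > 0, length(carrier_freq) == 2,
            reference_amplitude > 0)
  if (any(abs(carrier_freq) > 0.5))
    stop("carrier frequency beyond 0.5 cycles/pixel is aliased")
  cfg <- list(
    wavelength = wavelength, magnification = magnification, na = na,
    camera_pitch = camera_pitch,
    sensor_rows = as.integer(sensor_rows),
    sensor_cols = as.integer(sensor_cols),
    frame_interval = frame_interval,
    carrier_freq = as.numeric(carrier_freq),
    reference_amplitude = reference_amplitude,
    object_pitch = camera_pitch / magnification)
  class(cfg) <- "optical_config"
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Off-axis holographic recording configuration\n")
  cat(sprintf("  wavelength     : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  magnification  : %gx, NA %.2f\n", x$magnification, x$na))
  cat(sprintf("  camera         : %d x %d px, pitch %.2f um (object %.4f um)\n",
              x$sensor_rows, x$sensor_cols, x$camera_pitch * 1e6,
              x$object_pitch * 1e6))
  cat(sprintf("  frame interval : %.4g ms\n", x$frame_interval * 1e3))
  cat(sprintf("  carrier        : (%.3f, %.3f) cycles/px, ref amplitude %g\n",
              x$carrier_freq[1], x$carrier_freq[2], x$reference_amplitude))
  invisible(x)
}

#' Recording configuration used throughout the examples
#'
#' The 532 nm, NA 0.65, 40x configuration with a 5.86 um, 1200 x 1920 px
#' camera running at a 0.998 ms frame interval that the package's simulated
#' scenarios emulate.  Pass \code{sensor_rows}/\code{sensor_cols} to work at
#' a reduced sensor size.
#'
#' @param ... Overrides forwarded to [optical_config()].
#' @return An \code{optical_config}.
#' @export
default_optics <- function(...) {
  args <- list(wavelength = 532e-9, magnification = 40, na = 0.65,
               camera_pitch = 5.86e-6, sensor_rows = 1200L,
               sensor_cols = 1920L, frame_interval = 0.998e-3,
               carrier_freq = c(0.47, 0.25), reference_amplitude = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(optical_config, args)
}

#' Complex-valued optical field
#'
#' A 2D complex raster with its object-space pixel pitch: the unit on which
#' numerical propagation and spatiotemporal phase shifting operate.
#'
#' @param values Complex (or numeric) matrix, at least 2 x 2, finite.
#' @param pitch Pixel pitch in meters (> 0).
#' @return An object of class \code{complex_field}.
#' @export
complex_field <- function(values, pitch) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("degenerate raster: need at least 2 x 2")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  if (!is.numeric(pitch) || length(pitch) != 1 || pitch <= 0)
    stop("pitch must be a positive scalar")
  storage.mode(values) <- "complex"
  structure(list(values = values, pitch = pitch), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d px, pitch %.4g um\n",
              nrow(x$values), ncol(x$values), x$pitch * 1e6))
  invisible(x)
}

## ---- FFT helpers (internal) -------------------------------------------

## Zero frequency at index 1 (half-open FFT convention); cycles per sample.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ((k + n %/% 2) %% n - n %/% 2) / n
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## circularly shift a matrix so that element [i0, j0] lands at [1, 1]
circshift_to_origin <- function(m, i0, j0) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 + (i0 - 1)) %% nr) + 1
  ci <- ((seq_len(nc) - 1 + (j0 - 1)) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

## wrap angles to (-pi, pi]
wrap_phase_scalar <- function(x) -((-x + pi) %% (2 * pi) - pi)

#' Angular-spectrum propagation of a complex field
#'
#' Propagates a monochromatic scalar field over a signed distance \code{z} by
#' multiplying its 2D spectrum with the exact transfer function
#' \eqn{H(f_x,f_y) = \exp(i 2 \pi z \sqrt{\lambda^{-2} - f_x^2 - f_y^2})}.
#' Evanescent components (\eqn{f_x^2+f_y^2 \ge \lambda^{-2}}) are set to zero
#' rather than amplified, for numerical stability.  Propagation forms a group:
#' \code{propagate(z1)} then \code{propagate(z2)} equals
#' \code{propagate(z1 + z2)} up to round-off.
#'
#' @param field A [complex_field()].
#' @param z Signed propagation distance in meters.
#' @param wavelength Wavelength in meters.
#' @return A \code{complex_field} of the same shape and pitch.
#' @export
angular_spectrum_propagate <- function(field, z, wavelength) {
  stopifnot(inherits(field, "complex_field"), is.finite(z), wavelength > 0)
  if (z == 0) return(field)
  v <- field$values
  fx <- fft_freq(nrow(v)) / field$pitch
  fy <- fft_freq(ncol(v)) / field$pitch
  arg <- 1 / wavelength^2 - outer(fx^2, rep(1, length(fy))) -
    outer(rep(1, length(fx)), fy^2)
  H <- matrix(0 + 0i, nrow(v), ncol(v))
  prop <- arg > 0
  H[prop] <- exp(2i * pi * z * sqrt(arg[prop]))
  complex_field(ifft2(fft2(v) * H), field$pitch)
}

#' Tamura coefficient of an amplitude image
#'
#' The image-contrast statistic \eqn{TC = \sqrt{\sigma / \mu}}, with
#' \eqn{\sigma} the (population) standard deviation and \eqn{\mu} the mean of
#' the raster.  For a pure-phase object the amplitude contrast, and hence the
#' TC, is minimal at the in-focus plane, which makes the TC a refocusing
#' criterion.  Invariant under multiplication by a positive constant.
#'
#' @param amplitude Non-negative numeric matrix with at least one strictly
#'   positive element.
#' @return Non-negative scalar.
#' @export
tamura_coefficient <- function(amplitude) {
  if (!is.numeric(amplitude)) stop("'amplitude' must be numeric")
  if (any(amplitude < 0)) stop("'amplitude' must be non-negative")
  mu <- mean(amplitude)
  if (mu <= 0) stop("degenerate input: all-zero amplitude raster")
  sigma <- sqrt(mean((amplitude - mu)^2))
  sqrt(sigma / mu)
}

#' Coarse-to-fine autofocus by Tamura-coefficient minimization
#'
#' Scans the refocusing distance on a coarse grid over \code{[z_min, z_max]},
#' then refines on a fine grid around the coarse minimum.  At each candidate
#' z the field is propagated by the angular spectrum method and the TC of its
#' amplitude is evaluated; the reported \code{z_star} minimizes the TC.
#'
#' @param field A [complex_field()] containing the out-of-focus object.
#' @param z_min,z_max Search range in meters (\code{z_min < z_max}).
#' @param coarse_step,fine_step Grid steps in meters (defaults 1 um / 0.1 um).
#' @param wavelength Wavelength in meters.
#' @param flat_tol Relative TC range below which the curve is declared flat
#'   (no usable minimum), e.g. for a uniform plane wave.
#' @return List with \code{z_star} (meters), \code{tc_curve} (data.frame with
#'   columns \code{z}, \code{tc}, coarse and fine samples combined), and
#'   \code{flat} (logical flag; \code{z_star} is \code{NA} when flat).
#' @export
autofocus_tc <- function(field, z_min, z_max, coarse_step = 1e-6,
                         fine_step = 0.1e-6, wavelength,
                         flat_tol = 1e-3) {
  stopifnot(inherits(field, "complex_field"),
            coarse_step > 0, fine_step > 0)
  if (!(z_min < z_max)) stop("empty search range: need z_min < z_max")
  zs <- seq(z_min, z_max, by = coarse_step)
  tc <- vapply(zs, function(z) {
    tamura_coefficient(Mod(angular_spectrum_propagate(field, z,
                                                      wavelength)$values))
  }, numeric(1))
  rng <- (max(tc) - min(tc)) / max(mean(tc), .Machine$double.eps)
  if (rng < flat_tol) {
    warning("flat TC curve: no usable focus minimum")
    return(list(z_star = NA_real_,
                tc_curve = data.frame(z = zs, tc = tc), flat = TRUE))
  }
  z0 <- zs[which.min(tc)]
  zf <- seq(max(z_min, z0 - coarse_step), min(z_max, z0 + coarse_step),
            by = fine_step)
  tcf <- vapply(zf, function(z) {
    tamura_coefficient(Mod(angular_spectrum_propagate(field, z,
                                                      wavelength)$values))
  }, numeric(1))
  curve <- rbind(data.frame(z = zs, tc = tc), data.frame(z = zf, tc = tcf))
  curve <- curve[order(curve$z), ]
  curve <- curve[!duplicated(curve$z), ]
  list(z_star = zf[which.min(tcf)], tc_curve = curve, flat = FALSE)
}
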