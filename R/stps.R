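#' Select the one-diameter frame triplet of a track
#'
#' Spatiotemporal phase shifting uses the three frames over which the cell
#' translates by exactly one diameter per step, so that its contours in the
#' three frames are tangent to each other.  The half-spacing is
#' \code{k = round(2 R / (v dt))} frames; the triplet is
#' \code{(anchor - k, anchor, anchor + k)} and the retrieved axial position
#' is later assigned to the middle frame.  ROI centers come from the
#' per-frame detections, falling back to the fitted transverse line plus
#' the constant-flow reconstruction \code{y(t) = y_first + v (t - t_first)}.
#'
#' @param track A \code{cell_track} with a velocity estimate.
#' @param config An [optical_config()].
#' @param anchor_frame Middle frame of the triplet (defaults to the frame
#'   nearest the temporal middle of the track).
#' @param roi_size ROI side in full-resolution pixels.
#' @param quadrature_window Half-width of the search window around the
#'   one-diameter spacing within which the spacing is snapped to the
#'   carrier-quadrature optimum (0 keeps the plain one-diameter rule).
#'   The measured equivalent radius of a defocused cell overestimates its
#'   true radius, so the plain rule often realizes a phase step far from
#'   pi/2; a small adjustment of the spacing restores quadrature without
#'   giving up the tangency scale.
#' @return An object of class \code{frame_triplet}: frames, 3 x 2 matrix of
#'   ROI centers (um), \code{k}, \code{radius_um}, \code{roi_size} and the
#'   carrier \code{phase_step} expected between consecutive ROIs (radians,
#'   wrapped), given the configured carrier.
#' @export
select_triplet <- function(track, config, anchor_frame = NULL,
                           roi_size = 256L, quadrature_window = 5L) {
  d <- track$detections
  if (is.null(anchor_frame))
    anchor_frame <- d$frame[which.min(abs(d$frame - stats::median(d$frame)))]
  v <- track$v_um_s * 1e-6
  if (!is.finite(v) || v <= 0)
    stop("no displacement: a static cell admits no spatiotemporal phase shift")
  radius <- stats::median(d$radius_um) * 1e-6
  k0 <- as.integer(round(2 * radius / (v * config$frame_interval)))
  if (k0 < 1)
    stop("cell crosses its own diameter in under one frame interval; ",
         "no triplet exists at this frame rate")
  ## The one-diameter rule fixes the scale of the spacing; within a small
  ## window around it, pick the spacing whose carrier phase step is closest
  ## to quarter-period quadrature (+/- pi/2), which maximizes the rejection
  ## of the conjugate term in the three-step combination.
  if (quadrature_window > 0) {
    kc <- max(1L, k0 - as.integer(quadrature_window)):
      (k0 + as.integer(quadrature_window))
    step_of <- function(k) wrap_phase_scalar(
      2 * pi * config$carrier_freq[2] * v * k * config$frame_interval /
        config$object_pitch)
    dev <- abs(abs(vapply(kc, step_of, numeric(1))) - pi / 2)
    k <- kc[which.min(dev)]
  } else k <- k0
  frames <- c(anchor_frame - k, anchor_frame, anchor_frame + k)
  if (frames[1] < min(d$frame) || frames[3] > max(d$frame))
    stop("triplet extends outside the track span")
  centers <- t(vapply(frames, function(f) {
    hit <- which(d$frame == f)
    if (length(hit) == 1) {
      c(d$x_um[hit], d$y_um[hit])
    } else {
      t_s <- (f - 1) * config$frame_interval
      y0 <- d$y_um[which.min(d$t_s)]
      c(track$intercept_um + track$slope_um_s * t_s,
        y0 + track$v_um_s * (t_s - min(d$t_s)))
    }
  }, numeric(2)))
  disp_px <- (centers[3, ] - centers[2, ]) * 1e-6 / config$object_pitch
  step <- wrap_phase_scalar(2 * pi * sum(config$carrier_freq * disp_px))
  structure(list(frames = frames, centers = centers, k = k,
                 radius_um = radius * 1e6, roi_size = as.integer(roi_size),
                 phase_step = step),
            class = "frame_triplet")
}

#' @export
print.frame_triplet <- function(x, ...) {
  cat(sprintf("frame_triplet: frames (%d, %d, %d), k = %d, ROI %d px, carrier step %.3f rad\n",
              x$frames[1], x$frames[2], x$frames[3], x$k, x$roi_size,
              x$phase_step))
  invisible(x)
}

#' Extract a cell-registered ROI from a full-resolution hologram
#'
#' Crops a square region of interest around the cell from the original
#' (not down-sampled) hologram, so the carrier fringes are preserved, and
#' registers the cell to the ROI center with sub-pixel accuracy via the
#' Fourier shift theorem.  Registration aligns the cell across a triplet
#' while the carrier phase steps with the displacement.
#'
#' @param frame Full-resolution hologram matrix.
#' @param center_um Cell center, length-2 (x, y) in micrometers.
#' @param roi_size ROI side in pixels.
#' @param pitch Object pitch in meters.
#' @param pad Guard border in pixels: the crop is enlarged by \code{pad} on
#'   every side, tapered to its mean over that border (so the crop is
#'   effectively periodic and the spectral shift neither wraps content into
#'   the ROI nor rings from the boundary discontinuity), shifted, and
#'   trimmed back to \code{roi_size}.
#' @return \code{roi_size} x \code{roi_size} numeric matrix.
#' @export
extract_roi <- function(frame, center_um, roi_size, pitch, pad = 16L) {
  half <- roi_size %/% 2
  ## 1-based (possibly fractional) pixel position of the center
  p <- center_um * 1e-6 / pitch + 1
  ip <- round(p)
  frac <- p - ip
  if (all(abs(frac) <= 1e-9)) pad <- 0L
  r0 <- ip[1] - half - pad; r1 <- ip[1] + half - 1 + pad
  c0 <- ip[2] - half - pad; c1 <- ip[2] + half - 1 + pad
  if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame))
    stop("ROI clipped by the frame edge")
  roi <- frame[r0:r1, c0:c1]
  if (pad > 0 || any(abs(frac) > 1e-9)) {
    n <- nrow(roi)
    if (pad > 0) {
      ramp <- 0.5 * (1 - cos(pi * (seq_len(pad) - 0.5) / pad))
      w1 <- c(ramp, rep(1, n - 2 * pad), rev(ramp))
      w <- outer(w1, w1)
      mu <- mean(roi)
      roi <- mu + (roi - mu) * w
    }
    ph <- exp(2i * pi * outer(fft_freq(n) * frac[1],
                              fft_freq(n) * frac[2], `+`))
    roi <- Re(ifft2(fft2(roi) * ph))
    if (pad > 0)
      roi <- roi[(pad + 1):(pad + roi_size), (pad + 1):(pad + roi_size)]
  }
  roi
}

#' Assemble the spatiotemporal phase-shifted field
#'
#' The three-step combination
#' \deqn{E = 1 + \frac{i}{4}\left[(U_1 - U_2) + i (U_3 - U_2)\right]}
#' of three cell-registered hologram ROIs in which the carrier supplies
#' quarter-period phase steps.  The result is a partial complex-amplitude
#' estimate: sufficient for axial localization of the cell, but not a valid
#' quantitative reconstruction of its interior.
#'
#' @param U1,U2,U3 Numeric matrices of identical shape.
#' @param pitch Object pitch in meters.
#' @return A [complex_field()].
#' @export
stps_field <- function(U1, U2, U3, pitch) {
  if (!identical(dim(U1), dim(U2)) || !identical(dim(U2), dim(U3)))
    stop("triplet ROIs must share one shape")
  complex_field(1 + (1i / 4) * ((U1 - U2) + 1i * (U3 - U2)), pitch)
}

#' Axial position from a spatiotemporal phase-shifted triplet
#'
#' Assembles the field \code{E} from the triplet, removes the unit DC
#' offset, re-centers the dominant carrier sideband of \code{E - 1} in the
#' spectrum, and scans the Tamura coefficient of the propagated amplitude
#' over the axial search range; the TC minimum gives the cell's axial
#' position, assigned to the middle frame.  Depending on the sign of the
#' realized carrier step the combination extracts the object wave or its
#' conjugate (whose TC minimum appears at -z); the dominant sideband's
#' location relative to the configured carrier identifies which, and the
#' reported z accounts for it.
#'
#' @param U1,U2,U3 Cell-registered full-resolution ROIs (see
#'   [extract_roi()]).
#' @param config An [optical_config()].
#' @param z_range Length-2 search range in meters.
#' @param coarse_step,fine_step Autofocus grid steps in meters.
#' @param phase_step Carrier phase step between consecutive ROIs in radians
#'   (from [select_triplet()]); a warning is issued when its magnitude
#'   deviates from pi/2 by more than \code{step_tol} (relative).
#' @param step_tol Relative tolerance on the step before warning.
#' @param notch_radius Radius (cycles/px) of the spectral notches applied
#'   at the baseband and conjugate-sideband locations of \code{E - 1}
#'   before refocusing.
#' @return List with \code{z} (meters; NA when low confidence),
#'   \code{tc_curve}, \code{low_confidence} flag and \code{phase_step}.
#' @export
stps_axial_position <- function(U1, U2, U3, config,
                                z_range = c(-15e-6, 15e-6),
                                coarse_step = 1e-6, fine_step = 0.1e-6,
                                phase_step = NULL, step_tol = 0.2,
                                notch_radius = 0.2) {
  if (!is.null(phase_step)) {
    if (abs(abs(phase_step) - pi / 2) > step_tol * pi / 2)
      warning(sprintf(
        "carrier phase step %.3f rad deviates from pi/2 by more than %.0f%%",
        phase_step, 100 * step_tol))
  }
  E <- stps_field(U1, U2, U3, config$object_pitch)
  D <- E$values - 1
  S <- fft2(D)
  ## The phase-shifted combination suppresses, but does not annihilate, the
  ## baseband residuals (imperfect steps, sub-pixel registration error) and
  ## the conjugate sideband.  With the dominant sideband at kappa, those
  ## residuals sit at zero frequency and at -kappa; notch them out instead
  ## of band-passing the sideband, so no object signal is sacrificed.
  frx <- fft_freq(nrow(S)); fry <- fft_freq(ncol(S))
  pk <- arrayInd(which.max(Mod(S)), dim(S))
  kap <- c(frx[pk[1]], fry[pk[2]])
  notch <- function(c1, c2) {
    dx <- abs(frx - c1); dx <- pmin(dx, 1 - dx)
    dy <- abs(fry - c2); dy <- pmin(dy, 1 - dy)
    outer(dx^2, dy^2, `+`) <= notch_radius^2
  }
  S[notch(0, 0) | notch(-kap[1], -kap[2])] <- 0
  ## Which sideband did we latch onto?  The one at +carrier holds the
  ## conjugated object wave (its TC minimum appears at -z), the one at
  ## -carrier the direct wave.  A dominant peak that is near neither
  ## carrier means no stepped interference term was present in the
  ## triplet (e.g. cell-free or static ROIs): flag, do not refocus.
  tdist <- function(a, b) {
    d <- abs(a - b); sqrt(sum(pmin(d, 1 - d)^2))
  }
  d_conj <- tdist(kap, config$carrier_freq)
  d_direct <- tdist(kap, -config$carrier_freq)
  if (min(d_conj, d_direct) > 0.1)
    return(list(z = NA_real_, tc_curve = NULL, low_confidence = TRUE,
                phase_step = phase_step))
  conjugated <- d_conj < d_direct
  Dc <- .remove_residual_tilt(ifft2(circshift_to_origin(S, pk[1], pk[2])))
  af <- suppressWarnings(
    autofocus_tc(complex_field(Dc, config$object_pitch),
                 z_range[1], z_range[2], coarse_step, fine_step,
                 config$wavelength, flat_tol = 0.02))
  if (af$flat)
    return(list(z = NA_real_, tc_curve = af$tc_curve, low_confidence = TRUE,
                phase_step = phase_step))
  z <- if (conjugated) -af$z_star else af$z_star
  list(z = z, tc_curve = af$tc_curve, low_confidence = FALSE,
       phase_step = phase_step, conjugated = conjugated)
}

#' Axial positions along a track by spatiotemporal phase shifting
#'
#' For each anchor frame, selects the one-diameter triplet, extracts the
#' three registered ROIs from the full-resolution stack, and retrieves the
#' axial position from the phase-shifted field.  Anchors whose triplet or
#' ROIs cannot be formed (track edges, frame borders, too-slow cells) are
#' skipped, so a track may end with fewer axial estimates than anchors.
#'
#' @param track A \code{cell_track}.
#' @param stack The full-resolution [hologram_stack()].
#' @param config An [optical_config()].
#' @param anchors Anchor frames; the default uses the track's temporal
#'   middle.
#' @param roi_size ROI side in pixels.
#' @param z_range,coarse_step,fine_step Autofocus search parameters.
#' @return The track with its \code{z_estimates} data.frame filled
#'   (\code{frame}, \code{z_um}, \code{low_confidence}).
#' @export
track_axial_positions <- function(track, stack, config, anchors = NULL,
                                  roi_size = 256L,
                                  z_range = c(-15e-6, 15e-6),
                                  coarse_step = 1e-6, fine_step = 0.1e-6) {
  if (is.null(anchors)) {
    d <- track$detections
    anchors <- d$frame[which.min(abs(d$frame - stats::median(d$frame)))]
  }
  est <- list()
  for (a in anchors) {
    res <- tryCatch({
      tri <- select_triplet(track, config, a, roi_size)
      rois <- lapply(1:3, function(i)
        extract_roi(stack$frames[[tri$frames[i]]], tri$centers[i, ],
                    tri$roi_size, config$object_pitch))
      stps_axial_position(rois[[1]], rois[[2]], rois[[3]], config,
                          z_range, coarse_step, fine_step,
                          phase_step = tri$phase_step)
    }, error = function(e) NULL)
    if (is.null(res)) next
    est[[length(est) + 1]] <- data.frame(
      frame = a, z_um = res$z * 1e6, low_confidence = res$low_confidence)
  }
  if (length(est)) track$z_estimates <- do.call(rbind, est)
  track
}
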