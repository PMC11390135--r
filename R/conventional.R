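## DCT machinery for the least-squares unwrapper.  Unnormalized DCT-II
## matrices are cached per size; BLAS matmuls keep Mpx rasters tractable.
.dct_cache <- new.env(parent = emptyenv())
.dct_mat <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1)
  A <- cos(pi * outer(k, 2 * k + 1) / (2 * n))
  .dct_cache[[key]] <- A
  A
}
dct2d <- function(x) .dct_mat(nrow(x)) %*% x %*% t(.dct_mat(ncol(x)))
idct2d <- function(C) {
  n <- nrow(C); m <- ncol(C)
  Dr <- c(n, rep(n / 2, n - 1)); Dc <- c(m, rep(m / 2, m - 1))
  t(.dct_mat(n)) %*% (C / outer(Dr, Dc)) %*% .dct_mat(m)
}

wrap_phase <- function(x) -((-x + pi) %% (2 * pi) - pi)

## Fine carrier compensation: the off-axis carrier rarely falls on an
## integer FFT bin, so integer-bin re-centering leaves a residual linear
## phase ramp on the demodulated field.  That tilt destroys the relative
## phase between the transmitted background and the scattered wave on which
## amplitude-contrast refocusing relies.  The residual frequency is
## estimated from the mean phase step between neighboring pixels (the flat
## background dominates the estimate for sparse scenes) and divided out.
.remove_residual_tilt <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  dfx <- Arg(sum(v[-1, ] * Conj(v[-nr, ]))) / (2 * pi)
  dfy <- Arg(sum(v[, -1] * Conj(v[, -nc]))) / (2 * pi)
  if (abs(dfx) < 1e-12 && abs(dfy) < 1e-12) return(v)
  v * exp(-2i * pi * outer(dfx * (0:(nr - 1)), dfy * (0:(nc - 1)), `+`))
}

#' Two-dimensional phase unwrapping
#'
#' Unweighted least-squares unwrapping (Poisson solve under Neumann
#' boundaries via the discrete cosine transform) of a wrapped phase map,
#' followed by congruence rounding so that the output differs from the
#' input by an integer multiple of 2\eqn{\pi} at every pixel.  Exact for
#' residue-free phases; residues (inconsistent wrapped gradients) are
#' counted and reported via an attribute.
#'
#' @param wrapped Numeric matrix of wrapped phases in (-pi, pi].
#' @return Unwrapped phase matrix; attribute \code{residues} holds the
#'   number of phase residues encountered.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), all(is.finite(wrapped)))
  n <- nrow(wrapped); m <- ncol(wrapped)
  gx <- wrap_phase(diff(wrapped))           # (n-1) x m
  gy <- wrap_phase(t(diff(t(wrapped))))     # n x (m-1)
  ## residues: circulation of wrapped gradients around elementary loops
  res <- 0L
  if (n > 1 && m > 1) {
    circ <- gx[, -m, drop = FALSE] + gy[-1, , drop = FALSE] -
      gx[, -1, drop = FALSE] - gy[-n, , drop = FALSE]
    res <- sum(abs(circ) > pi)
  }
  rho <- matrix(0, n, m)
  rho[1:(n - 1), ] <- rho[1:(n - 1), ] + gx
  rho[2:n, ] <- rho[2:n, ] - gx
  rho[, 1:(m - 1)] <- rho[, 1:(m - 1)] + gy
  rho[, 2:m] <- rho[, 2:m] - gy
  eig <- outer(2 * cos(pi * (0:(n - 1)) / n) - 2,
               2 * cos(pi * (0:(m - 1)) / m) - 2, `+`)
  eig[1, 1] <- 1
  C <- dct2d(rho) / eig
  C[1, 1] <- 0
  ls <- idct2d(C)
  out <- wrapped + 2 * pi * round((ls - wrapped) / (2 * pi))
  if (res > 0)
    message(res, " phase residue(s) detected; unwrapping is least-squares")
  attr(out, "residues") <- res
  out
}

#' Demodulate an off-axis hologram into its complex field
#'
#' Fourier-filters the hologram: the object sideband is cropped with a
#' circular aperture around the carrier peak, re-centered to zero frequency
#' and inverse-transformed, yielding the (out-of-focus) complex amplitude.
#' The sideband location defaults to minus the configured carrier (the
#' component carrying the non-conjugated object wave) and is refined to the
#' local spectral peak; set \code{carrier = NULL} to auto-detect the
#' brightest peak outside a DC exclusion disk.
#'
#' @param hologram Full-resolution intensity matrix.
#' @param config An [optical_config()].
#' @param aperture_radius Aperture radius in cycles/pixel; default half the
#'   carrier offset from DC.  Must stay below the carrier offset (else the
#'   DC term leaks into the passband).
#' @param carrier Length-2 sideband frequency in cycles/pixel, or
#'   \code{NULL} to auto-detect.
#' @return A [complex_field()] at the object pitch.
#' @export
reconstruct_complex <- function(hologram, config, aperture_radius = NULL,
                                carrier = -config$carrier_freq) {
  stopifnot(is.matrix(hologram))
  nr <- nrow(hologram); nc <- ncol(hologram)
  S <- fft2(hologram)
  fx <- fft_freq(nr); fy <- fft_freq(nc)
  torus_d2 <- function(c1, c2) {
    dx <- abs(outer(fx - c1, rep(0, nc), `+`)); dx <- pmin(dx, 1 - dx)
    dy <- abs(outer(rep(0, nr), fy - c2, `+`)); dy <- pmin(dy, 1 - dy)
    dx^2 + dy^2
  }
  A <- Mod(S)
  if (is.null(carrier)) {
    excl <- torus_d2(0, 0) < 0.1^2
    A2 <- A; A2[excl] <- 0
    pk <- arrayInd(which.max(A2), dim(A2))
  } else {
    near <- torus_d2(carrier[1], carrier[2]) < 0.05^2
    A2 <- A; A2[!near] <- 0
    pk <- arrayInd(which.max(A2), dim(A2))
  }
  cf <- c(fx[pk[1]], fy[pk[2]])
  off <- sqrt(sum(pmin(abs(cf), 1 - abs(cf))^2))  # torus distance to DC
  if (off < 0.02)
    stop("carrier peak indistinguishable from the DC term")
  if (is.null(aperture_radius)) aperture_radius <- off / 2
  if (aperture_radius >= off)
    stop("aperture radius reaches the DC term: choose a smaller aperture")
  mask <- torus_d2(cf[1], cf[2]) <= aperture_radius^2
  S[!mask] <- 0
  field <- .remove_residual_tilt(ifft2(circshift_to_origin(S, pk[1], pk[2])))
  complex_field(field, config$object_pitch)
}

#' Locate cells on a quantitative phase map
#'
#' The same morphological chain as the hologram-domain detector (Gaussian
#' blur, gradient edges, automatic threshold, closing, filling, components,
#' area filter, centroids) applied to an unwrapped phase map at full
#' resolution, where cell contrast is higher than in the raw hologram.
#'
#' @param qpm Unwrapped phase matrix (radians).
#' @param config An [optical_config()].
#' @param params See [detect_params()]; defaults are rescaled for full
#'   resolution (sigma 4 px, min area 80 px).
#' @return data.frame with \code{x_um}, \code{y_um}, \code{radius_um},
#'   \code{area} (full-resolution px).
#' @export
locate_cells_qpm <- function(qpm, config,
                             params = detect_params(sigma = 4,
                                                    min_area = 80)) {
  det <- .locate_raster(qpm, params)
  pitch <- config$object_pitch
  out <- data.frame(
    x_um = (det$row - 1) * pitch * 1e6,
    y_um = (det$col - 1) * pitch * 1e6,
    radius_um = sqrt(det$area / pi) * pitch * 1e6,
    area = det$area)
  out[order(out$x_um), , drop = FALSE]
}

#' Conventional holographic 3D tracking
#'
#' The reference pipeline: per frame, demodulate the hologram, unwrap the
#' phase, and locate cells on the quantitative phase map; link detections
#' into tracks; then, per track, crop a complex ROI around the cell at the
#' anchor frame(s) and refocus it by Tamura-coefficient minimization to
#' obtain the axial position.
#'
#' @param stack Full-resolution [hologram_stack()].
#' @param config An [optical_config()].
#' @param z_range Length-2 axial search range in meters.
#' @param with_z Compute axial positions (slower).
#' @param anchors Anchor policy for z: \code{"middle"} (one estimate per
#'   track) or an integer vector of frames.
#' @param roi_size Complex ROI side for refocusing, full-resolution px.
#' @param params Detection parameters for [locate_cells_qpm()].
#' @param coarse_step,fine_step Autofocus grid steps (meters).
#' @return List with \code{tracks} (list of \code{cell_track}) and
#'   \code{detections} (per-frame data.frame).
#' @export
conventional_track <- function(stack, config, z_range = c(-15e-6, 15e-6),
                               with_z = TRUE, anchors = "middle",
                               roi_size = 256L,
                               params = detect_params(sigma = 4,
                                                      min_area = 80),
                               coarse_step = 1e-6, fine_step = 0.1e-6) {
  stopifnot(inherits(stack, "hologram_stack"))
  fields <- vector("list", length(stack))
  dets <- lapply(seq_along(stack$frames), function(f) {
    fld <- reconstruct_complex(stack$frames[[f]], config)
    fields[[f]] <<- fld
    qpm <- unwrap_phase(Arg(fld$values))
    d <- locate_cells_qpm(qpm, config, params)
    if (nrow(d)) cbind(frame = f, d) else NULL
  })
  detections <- do.call(rbind, dets)
  if (is.null(detections))
    return(list(tracks = list(), detections = data.frame()))
  tracks <- link_tracks(detections, config$frame_interval)
  if (with_z) {
    half <- roi_size %/% 2
    for (i in seq_along(tracks)) {
      tr <- tracks[[i]]
      afr <- if (identical(anchors, "middle")) {
        d <- tr$detections
        d$frame[which.min(abs(d$frame - stats::median(d$frame)))]
      } else intersect(anchors, tr$detections$frame)
      est <- list()
      for (a in afr) {
        d <- tr$detections[tr$detections$frame == a, ]
        ip <- round(c(d$x_um, d$y_um) * 1e-6 / config$object_pitch + 1)
        fld <- fields[[a]]
        r0 <- ip[1] - half; r1 <- ip[1] + half - 1
        c0 <- ip[2] - half; c1 <- ip[2] + half - 1
        if (r0 < 1 || c0 < 1 || r1 > nrow(fld$values) ||
            c1 > ncol(fld$values)) next
        roi <- complex_field(fld$values[r0:r1, c0:c1], config$object_pitch)
        af <- suppressWarnings(
          autofocus_tc(roi, z_range[1], z_range[2], coarse_step, fine_step,
                       config$wavelength, flat_tol = 0.02))
        est[[length(est) + 1]] <- data.frame(frame = a, z_um = af$z_star * 1e6,
                                             low_confidence = af$flat)
      }
      if (length(est)) tracks[[i]]$z_estimates <- do.call(rbind, est)
    }
  }
  list(tracks = tracks, detections = detections)
}

#' Compare two sets of tracks position-by-position
#'
#' Matches tracks across the two pipelines by spatiotemporal overlap (mean
#' distance over common frames, greedy minimum under a gate) and reports
#' per-axis absolute error statistics, per-track slope differences and the
#' matched counts.
#'
#' @param proposed,baseline Lists of \code{cell_track} objects.
#' @param gate_um Maximum mean transverse distance for a match (um).
#' @param min_overlap Minimum number of common frames for a candidate pair.
#' @return An object of class \code{track_comparison}: matched pair table,
#'   error vectors \code{dx}, \code{dy}, \code{dz} (um), slope differences
#'   (um/s), and a summary data.frame of mean +/- sd of the absolute errors.
#' @export
compare_tracks <- function(proposed, baseline, gate_um = 5, min_overlap = 3) {
  if (!length(proposed) || !length(baseline))
    stop("no tracks to compare")
  cost <- matrix(Inf, length(proposed), length(baseline))
  for (i in seq_along(proposed)) for (j in seq_along(baseline)) {
    a <- proposed[[i]]$detections; b <- baseline[[j]]$detections
    common <- intersect(a$frame, b$frame)
    if (length(common) < min_overlap) next
    ia <- match(common, a$frame); ib <- match(common, b$frame)
    d <- mean(sqrt((a$x_um[ia] - b$x_um[ib])^2 +
                   (a$y_um[ia] - b$y_um[ib])^2))
    if (d <= gate_um) cost[i, j] <- d
  }
  pairs <- list(); dx <- dy <- dz <- dslope <- numeric(); npos <- 0L
  repeat {
    m <- which.min(cost)
    if (!length(m) || !is.finite(cost[m])) break
    i <- ((m - 1) %% nrow(cost)) + 1
    j <- ((m - 1) %/% nrow(cost)) + 1
    a <- proposed[[i]]$detections; b <- baseline[[j]]$detections
    common <- intersect(a$frame, b$frame)
    ia <- match(common, a$frame); ib <- match(common, b$frame)
    dx <- c(dx, a$x_um[ia] - b$x_um[ib])
    dy <- c(dy, a$y_um[ia] - b$y_um[ib])
    npos <- npos + length(common)
    za <- proposed[[i]]$z_estimates; zb <- baseline[[j]]$z_estimates
    if (nrow(za) && nrow(zb)) {
      zca <- za[!za$low_confidence, , drop = FALSE]
      zcb <- zb[!zb$low_confidence, , drop = FALSE]
      if (nrow(zca) && nrow(zcb))
        for (r in seq_len(nrow(zca))) {
          nb <- which.min(abs(zcb$frame - zca$frame[r]))
          dz <- c(dz, zca$z_um[r] - zcb$z_um[nb])
        }
    }
    dslope <- c(dslope, proposed[[i]]$slope_um_s - baseline[[j]]$slope_um_s)
    pairs[[length(pairs) + 1]] <- data.frame(proposed = i, baseline = j,
                                             mean_dist_um = cost[m])
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  if (!length(pairs)) stop("no matched tracks under the gate")
  summary <- data.frame(
    axis = c("x", "y", "z"),
    mean_abs_um = c(mean(abs(dx)), mean(abs(dy)),
                    if (length(dz)) mean(abs(dz)) else NA_real_),
    sd_abs_um = c(stats::sd(abs(dx)), stats::sd(abs(dy)),
                  if (length(dz) > 1) stats::sd(abs(dz)) else NA_real_))
  structure(list(pairs = do.call(rbind, pairs), dx = dx, dy = dy, dz = dz,
                 slope_diff_um_s = dslope, n_matched = length(pairs),
                 n_positions = npos, summary = summary),
            class = "track_comparison")
}

#' @export
print.track_comparison <- function(x, ...) {
  cat(sprintf("track_comparison: %d matched cells, %d positions\n",
              x$n_matched, x$n_positions))
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  |d%s| = %.3f +/- %.3f um\n", s$axis[r], s$mean_abs_um[r],
                s$sd_abs_um[r]))
  cat(sprintf("  slope difference: mean |ds| = %.3f um/s over %d tracks\n",
              mean(abs(x$slope_diff_um_s)), length(x$slope_diff_um_s)))
  invisible(x)
}
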