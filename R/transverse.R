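#' Default parameters of the hologram-domain cell detector
#'
#' @param sigma Gaussian low-pass width in (down-sampled) pixels.
#' @param min_area Minimum component area in (down-sampled) pixels.
#' @param floor_k Robust noise floor: the edge threshold never drops below
#'   \code{median + floor_k * mad} of the gradient magnitude, so a cell-free
#'   frame yields no detections.
#' @param brush Diameter of the disc structuring element for morphological
#'   closing (odd integer).
#' @return Named list of parameters.
#' @export
detect_params <- function(sigma = 2, min_area = 20, floor_k = 8, brush = 5) {
  list(sigma = sigma, min_area = min_area, floor_k = floor_k, brush = brush)
}

## Core morphological localization chain on one raster.  Returns subpixel
## centroids in 1-based pixel units plus areas (px).
.locate_raster <- function(img, params) {
  g <- EBImage::gblur(img, sigma = params$sigma)
  nr <- nrow(g); nc <- ncol(g)
  gx <- g[c(2:nr, nr), ] - g[c(1, 1:(nr - 1)), ]
  gy <- g[, c(2:nc, nc)] - g[, c(1, 1:(nc - 1))]
  gm <- sqrt(gx^2 + gy^2)
  mx <- max(gm)
  if (mx <= 0) return(data.frame(row = numeric(), col = numeric(),
                                 area = numeric()))
  th_otsu <- EBImage::otsu(EBImage::Image(gm / mx)) * mx
  th_floor <- stats::median(gm) + params$floor_k * stats::mad(gm)
  mask <- gm > max(th_otsu, th_floor)
  mask <- EBImage::closing(mask, EBImage::makeBrush(params$brush, "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(data.frame(row = numeric(), col = numeric(),
                                area = numeric()))
  idx <- which(lab > 0)
  labs <- lab[idx]
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  area <- tabulate(labs, n)
  rmean <- rowsum(rr, labs)[, 1] / area
  cmean <- rowsum(cc, labs)[, 1] / area
  keep <- area >= params$min_area
  data.frame(row = rmean[keep], col = cmean[keep], area = area[keep])
}

#' Locate cells in one background-free down-sampled hologram
#'
#' Detection chain: Gaussian low-pass, gradient-magnitude edge map,
#' automatic (Otsu) threshold with a robust noise floor, morphological
#' closing, hole filling, connected components, area filter, and per
#' component the binary centroid and equivalent radius
#' \eqn{\sqrt{area/\pi}}.  Positions are reported in object-space
#' micrometers at full resolution (a down-sampled pixel covers two camera
#' pixels).
#'
#' @param frame Normalized down-sampled frame (values ~1 off cells).
#' @param pitch Down-sampled pixel pitch in meters (= 2x the object pitch).
#' @param params See [detect_params()].
#' @return data.frame with columns \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{area} (down-sampled px); empty when nothing is
#'   found.
#' @export
locate_cells_frame <- function(frame, pitch, params = detect_params()) {
  det <- .locate_raster(frame - mean(frame) + 1, params)
  ## down-sampled pixel k spans camera pixels 2k-1, 2k; its center sits at
  ## full-resolution coordinate (2k - 1.5) * object_pitch
  half_pitch <- pitch / 2
  out <- data.frame(
    x_um = (2 * det$row - 1.5) * half_pitch * 1e6,
    y_um = (2 * det$col - 1.5) * half_pitch * 1e6,
    radius_um = sqrt(det$area / pi) * pitch * 1e6,
    area = det$area)
  out[order(out$x_um), , drop = FALSE]
}

#' Detect cells in every frame of a normalized stack
#'
#' @param stack Normalized down-sampled [hologram_stack()].
#' @param params See [detect_params()].
#' @return data.frame of detections with a \code{frame} column.
#' @export
detect_stack <- function(stack, params = detect_params()) {
  stopifnot(inherits(stack, "hologram_stack"))
  res <- lapply(seq_along(stack$frames), function(f) {
    d <- locate_cells_frame(stack$frames[[f]], stack$pitch, params)
    if (nrow(d)) cbind(frame = f, d) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      radius_um = numeric(), area = numeric())
  out
}

#' Spatiotemporal tracking line (STTL) matrix
#'
#' Encodes, for every frame (column), the transverse x-positions of the
#' detected cells (rows, at full camera resolution: a detection at
#' down-sampled row r marks full-resolution row 2r).  Each flowing cell
#' appears as a quasi-straight line across the matrix.
#'
#' @param detections data.frame with \code{frame} and \code{x_um} columns.
#' @param config An [optical_config()] (provides sensor rows, object pitch
#'   and frame interval).
#' @param n_frames Number of columns (default: largest frame index seen).
#' @return An object of class \code{sttl_matrix}: list with \code{values}
#'   (sensor_rows x n_frames 0/1 matrix), \code{x_scale} (um per row) and
#'   \code{t_scale} (seconds per column).
#' @export
build_sttl <- function(detections, config, n_frames = max(detections$frame)) {
  stopifnot(nrow(detections) >= 1)
  nx <- config$sensor_rows
  v <- matrix(0L, nx, n_frames)
  rows <- pmin(pmax(round(detections$x_um * 1e-6 / config$object_pitch) + 1,
                    1), nx)
  v[cbind(rows, detections$frame)] <- 1L
  structure(list(values = v, x_scale = config$object_pitch * 1e6,
                 t_scale = config$frame_interval),
            class = "sttl_matrix")
}

#' @export
print.sttl_matrix <- function(x, ...) {
  cat(sprintf("sttl_matrix: %d x %d (x rows x frames), %d marks\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Display an STTL matrix
#'
#' @param x An \code{sttl_matrix}.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sttl_matrix <- function(x, ...) {
  nt <- ncol(x$values)
  graphics::image(x = (seq_len(nt) - 1) * x$t_scale,
                  y = (seq_len(nrow(x$values)) - 1) * x$x_scale,
                  z = t(x$values), col = c("white", "black"),
                  xlab = "time (s)", ylab = "x (um)", useRaster = TRUE, ...)
}

#' Link per-frame detections into cell tracks
#'
#' Greedy nearest-neighbor association between consecutive frames, gated by
#' a maximum jump distance (scaled by the frame gap when bridging short
#' detection gaps); unmatched detections open new tracks, and tracks
#' shorter than \code{min_length} detections are discarded.
#'
#' @param detections data.frame from [detect_stack()] (columns \code{frame},
#'   \code{x_um}, \code{y_um}, \code{radius_um}).
#' @param frame_interval Seconds between frames.
#' @param max_jump Gate distance in micrometers per frame step.
#' @param bridge Number of missing frames a track may bridge (default 1).
#' @param min_length Minimum number of detections per kept track.
#' @return List of \code{cell_track} objects, each carrying its detections,
#'   fitted transverse slope/intercept and flow velocity.
#' @export
link_tracks <- function(detections, frame_interval, max_jump = 3,
                        bridge = 1, min_length = 5) {
  if (!nrow(detections)) return(list())
  detections <- detections[order(detections$frame), , drop = FALSE]
  open <- list()    # each: list(rows = indices into detections, last = c(x, y), last_frame)
  done <- list()
  for (f in sort(unique(detections$frame))) {
    ## retire tracks too stale to extend
    if (length(open)) {
      stale <- vapply(open, function(tr) f - tr$last_frame > bridge + 1,
                      logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    di <- which(detections$frame == f)
    if (!length(di)) next
    used_det <- rep(FALSE, length(di))
    if (length(open)) {
      cost <- outer(seq_along(open), seq_along(di),
                    Vectorize(function(i, j) {
                      dt <- f - open[[i]]$last_frame
                      d <- sqrt((open[[i]]$last[1] - detections$x_um[di[j]])^2 +
                                (open[[i]]$last[2] - detections$y_um[di[j]])^2)
                      if (d <= max_jump * dt) d else Inf
                    }))
      repeat {
        m <- which.min(cost)
        if (!length(m) || !is.finite(cost[m])) break
        i <- ((m - 1) %% nrow(cost)) + 1
        j <- ((m - 1) %/% nrow(cost)) + 1
        open[[i]]$rows <- c(open[[i]]$rows, di[j])
        open[[i]]$last <- c(detections$x_um[di[j]], detections$y_um[di[j]])
        open[[i]]$last_frame <- f
        cost[i, ] <- Inf; cost[, j] <- Inf
        used_det[j] <- TRUE
      }
    }
    for (j in which(!used_det))
      open[[length(open) + 1]] <- list(rows = di[j],
                                       last = c(detections$x_um[di[j]],
                                                detections$y_um[di[j]]),
                                       last_frame = f)
  }
  done <- c(done, open)
  done <- done[vapply(done, function(tr) length(tr$rows) >= min_length,
                      logical(1))]
  tracks <- vector("list", length(done))
  for (i in seq_along(done)) {
    d <- detections[done[[i]]$rows, c("frame", "x_um", "y_um", "radius_um",
                                      "area")]
    d$t_s <- (d$frame - 1) * frame_interval
    rownames(d) <- NULL
    tr <- structure(list(cell_id = i,
                         detections = d[, c("frame", "t_s", "x_um", "y_um",
                                            "radius_um", "area")],
                         slope_um_s = NA_real_, intercept_um = NA_real_,
                         v_um_s = NA_real_,
                         z_estimates = data.frame(frame = integer(),
                                                  z_um = numeric(),
                                                  low_confidence = logical())),
                    class = "cell_track")
    fit <- fit_track_line(tr)
    tr$slope_um_s <- fit["slope"]
    tr$intercept_um <- fit["intercept"]
    tr$v_um_s <- tryCatch(estimate_velocity(tr), error = function(e) NA_real_)
    tracks[[i]] <- tr
  }
  tracks
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("cell_track %d: %d detections, frames %d-%d, v = %.1f um/s, slope = %.2f um/s, %d z estimates\n",
              x$cell_id, nrow(x$detections), min(x$detections$frame),
              max(x$detections$frame), x$v_um_s, x$slope_um_s,
              nrow(x$z_estimates)))
  invisible(x)
}

#' Least-squares transverse line of a track
#'
#' Fits x (um) against time (s) by ordinary least squares; the slope is the
#' transverse drift velocity used in the proposed-vs-conventional slope
#' comparison.
#'
#' @param track A \code{cell_track} with >= 2 detections.
#' @return Named numeric: \code{slope} (um/s), \code{intercept} (um).
#' @export
fit_track_line <- function(track) {
  d <- track$detections
  if (nrow(d) < 2) stop("need at least 2 detections to fit a line")
  co <- stats::coef(stats::lm.fit(cbind(1, d$t_s), d$x_um))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Average flow velocity of a track
#'
#' v = flow-axis distance traversed / track duration; under the constant
#' flow assumption the per-frame flow positions are reconstructible as
#' \code{y(t) = y_first + v (t - t_first)}.
#'
#' @param track A \code{cell_track}.
#' @return Velocity along the flow axis in um/s.
#' @export
estimate_velocity <- function(track) {
  d <- track$detections
  dur <- max(d$t_s) - min(d$t_s)
  if (dur <= 0) stop("zero-duration track: velocity undefined")
  (d$y_um[which.max(d$t_s)] - d$y_um[which.min(d$t_s)]) / dur
}

#' Monitoring period of a recording
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Seconds per frame (> 0).
#' @return \code{n_frames * frame_interval}, seconds.
#' @examples
#' monitoring_period(11618, 0.998e-3)   # 11.6 s
#' @export
monitoring_period <- function(n_frames, frame_interval) {
  stopifnot(n_frames >= 1, frame_interval > 0)
  n_frames * frame_interval
}

#' Cell throughput of the monitored channel volume
#'
#' Number of cells per unit volume and unit time,
#' \eqn{N_c / [\pi (N_x \Delta / 2)^2 \, N_y \Delta \, N_t \Delta t]},
#' modeling the channel as a cylinder whose diameter spans the transverse
#' field of view.
#'
#' @param n_cells Number of observed cells (>= 0).
#' @param config An [optical_config()].
#' @param n_frames Frames in the monitoring period.
#' @return Throughput in cells / (m^3 s).
#' @export
cell_throughput <- function(n_cells, config, n_frames) {
  stopifnot(n_cells >= 0, n_frames >= 1)
  delta <- config$object_pitch
  vol <- pi * (config$sensor_rows * delta / 2)^2 *
    (config$sensor_cols * delta)
  period <- monitoring_period(n_frames, config$frame_interval)
  if (vol <= 0 || period <= 0) stop("zero monitored volume or period")
  n_cells / (vol * period)
}

#' Throughput resolved over equal time intervals
#'
#' Splits the monitoring period into equal bins and counts, per bin, the
#' cells whose first detection falls inside it.
#'
#' @param tracks List of \code{cell_track} objects.
#' @param config An [optical_config()].
#' @param n_frames Frames in the monitoring period.
#' @param intervals Number of equal bins (default 20).
#' @return data.frame with \code{interval}, \code{t_start_s},
#'   \code{n_cells}, \code{throughput} (cells / m^3 s within the bin).
#' @export
throughput_by_interval <- function(tracks, config, n_frames, intervals = 20) {
  stopifnot(intervals >= 1)
  first <- vapply(tracks, function(tr) min(tr$detections$frame), numeric(1))
  edges <- seq(0, n_frames, length.out = intervals + 1)
  bin <- pmin(findInterval(first - 1, edges, rightmost.closed = TRUE),
              intervals)
  counts <- tabulate(bin, intervals)
  delta <- config$object_pitch
  vol <- pi * (config$sensor_rows * delta / 2)^2 *
    (config$sensor_cols * delta)
  bin_t <- monitoring_period(n_frames, config$frame_interval) / intervals
  data.frame(interval = seq_len(intervals),
             t_start_s = edges[-(intervals + 1)] * config$frame_interval,
             n_cells = counts,
             throughput = counts / (vol * bin_t))
}
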