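#' Proposed spatiotemporal 3D tracking pipeline
#'
#' Runs the full rapid localization chain on a full-resolution hologram
#' video: carrier-cancelling half-size down-sampling, background
#' elimination (SSM or SBMM) and division, hologram-domain transverse
#' localization and track linking, and, per track, axial retrieval by
#' spatiotemporal phase shifting with Tamura-coefficient refocusing.  No
#' frame-by-frame holographic reconstruction is performed.
#'
#' @param stack Full-resolution [hologram_stack()].
#' @param config An [optical_config()] matching the stack.
#' @param background_method \code{"ssm"} or \code{"sbmm"}.
#' @param with_z Compute axial positions via STPS.
#' @param anchors Anchor policy for axial estimates: \code{"middle"} or an
#'   integer vector of frames.
#' @param detect See [detect_params()].
#' @param roi_size STPS ROI side in full-resolution pixels.
#' @param z_range,coarse_step,fine_step Axial search parameters (meters).
#' @param max_jump,bridge,min_length Track-linking parameters
#'   (see [link_tracks()]).
#' @param block_grid,ncc_threshold SBMM parameters.
#' @param ssm_frames Number of frames superimposed by SSM (default all).
#' @return List with \code{tracks}, \code{detections}, \code{background}
#'   (the fitted \code{background_model}), \code{normalized} (the
#'   background-free down-sampled stack) and \code{sttl} (the
#'   [build_sttl()] matrix).
#' @export
track_proposed <- function(stack, config, background_method = c("ssm", "sbmm"),
                           with_z = TRUE, anchors = "middle",
                           detect = detect_params(), roi_size = 256L,
                           z_range = c(-15e-6, 15e-6), coarse_step = 1e-6,
                           fine_step = 0.1e-6, max_jump = 3, bridge = 1,
                           min_length = 5, block_grid = c(10L, 10L),
                           ncc_threshold = 0.98, ssm_frames = NULL) {
  background_method <- match.arg(background_method)
  ds <- downsample_stack(stack)
  bg <- if (background_method == "ssm")
    ssm_background(ds, ssm_frames %||% length(ds))
  else
    sbmm_background(ds, block_grid, ncc_threshold)
  norm <- remove_background(ds, bg)
  detections <- detect_stack(norm, detect)
  tracks <- link_tracks(detections, config$frame_interval, max_jump,
                        bridge, min_length)
  if (with_z)
    tracks <- lapply(tracks, function(tr) {
      a <- if (identical(anchors, "middle")) NULL else anchors
      track_axial_positions(tr, stack, config, anchors = a,
                            roi_size = roi_size, z_range = z_range,
                            coarse_step = coarse_step,
                            fine_step = fine_step)
    })
  sttl <- if (nrow(detections))
    build_sttl(detections, config, n_frames = length(stack)) else NULL
  list(tracks = tracks, detections = detections, background = bg,
       normalized = norm, sttl = sttl)
}

#' Match estimated tracks to simulator ground truth
#'
#' Associates each track with the ground-truth cell minimizing the mean
#' transverse distance over common frames, and reports per-position and
#' per-cell errors.  Used by the synthetic-data validation studies.
#'
#' @param tracks List of \code{cell_track}.
#' @param truth Ground-truth data.frame from [render_video()].
#' @param gate_um Maximum mean distance for a valid match (um).
#' @return List with \code{matches} (track row per matched track:
#'   \code{cell_id} of the truth cell, errors), \code{dx}, \code{dy}
#'   per-position error vectors (um), and per matched track the velocity
#'   error and, when available, the axial error \code{dz} (um).
#' @export
match_truth <- function(tracks, truth, gate_um = 5) {
  ids <- unique(truth$cell_id)
  rows <- list(); dx <- dy <- numeric(); dz <- numeric()
  used <- integer()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]; d <- tr$detections
    best <- NULL; best_cost <- Inf
    for (cid in setdiff(ids, used)) {
      g <- truth[truth$cell_id == cid, ]
      common <- intersect(d$frame, g$frame)
      if (length(common) < 3) next
      ia <- match(common, d$frame); ig <- match(common, g$frame)
      cost <- mean(sqrt((d$x_um[ia] - g$x_um[ig])^2 +
                        (d$y_um[ia] - g$y_um[ig])^2))
      if (cost < best_cost) { best_cost <- cost; best <- cid }
    }
    if (is.null(best) || best_cost > gate_um) next
    used <- c(used, best)
    g <- truth[truth$cell_id == best, ]
    common <- intersect(d$frame, g$frame)
    ia <- match(common, d$frame); ig <- match(common, g$frame)
    dx <- c(dx, d$x_um[ia] - g$x_um[ig])
    dy <- c(dy, d$y_um[ia] - g$y_um[ig])
    v_true <- g$v_um_s[1]
    z_true <- g$z_um[1]
    zt <- tr$z_estimates
    zt <- if (nrow(zt)) zt[!zt$low_confidence & !is.na(zt$z_um), ,
                           drop = FALSE] else zt
    if (nrow(zt)) dz <- c(dz, zt$z_um - z_true)
    rows[[length(rows) + 1]] <- data.frame(
      track = i, cell_id = best, mean_dist_um = best_cost,
      v_err_rel = (tr$v_um_s - v_true) / v_true,
      z_mean_abs_err_um = if (nrow(zt)) mean(abs(zt$z_um - z_true))
                          else NA_real_)
  }
  list(matches = if (length(rows)) do.call(rbind, rows) else NULL,
       dx = dx, dy = dy, dz = dz)
}
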