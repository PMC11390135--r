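#' Axial-accuracy study on simulated flowing-cell videos
#'
#' Renders a sequence of default flow scenarios (radii 5-8 um, peak phase
#' 1-3 rad, defocus uniform in +/-10 um, velocities 300-700 um/s snapped to
#' carrier quadrature), runs the full proposed pipeline (SSM background,
#' hologram-domain transverse tracking, STPS axial retrieval) on each, and
#' accumulates per-cell axial errors against the simulator ground truth
#' until at least \code{min_cells} cells have an axial estimate.  Cells
#' without an estimate (near-focus cells invisible in the hologram domain,
#' tracks whose triplet cannot be formed) are counted but excluded from the
#' error mean, as in any per-triplet-availability accounting.
#'
#' @param min_cells Minimum number of cells with an axial estimate.
#' @param n_cells,n_frames Scenario size per video.
#' @param seed Master seed; per-video seeds are derived from it.
#' @param optics Recording configuration (default: a 600 x 960 px sensor
#'   with the standard optics, sized so a video fits in memory).
#' @param max_videos Safety cap on the number of rendered videos.
#' @param background_method Passed to [track_proposed()].
#' @return List: \code{cells} (per-cell data.frame with truth, estimate and
#'   error columns), \code{mean_abs_dz_um}, \code{n_with_z},
#'   \code{n_cells_total}, \code{n_videos}, \code{mean_abs_dx_um},
#'   \code{mean_abs_dy_um}, \code{max_abs_v_rel}.
#' @export
axial_accuracy_study <- function(min_cells = 20, n_cells = 2,
                                 n_frames = 120, seed = 1,
                                 optics = default_optics(sensor_rows = 600L,
                                                         sensor_cols = 960L),
                                 max_videos = 40,
                                 background_method = "ssm") {
  rows <- list(); dx <- dy <- numeric()
  n_total <- 0L; n_videos <- 0L
  for (i in seq_len(max_videos)) {
    vid_seed <- (abs(seed) %% 100000L) * 1000L + i
    cfg <- sim_scenario_flow(optics, n_cells = n_cells, n_frames = n_frames,
                             seed = vid_seed)
    vid <- render_video(cfg)
    res <- suppressWarnings(
      track_proposed(vid$stack, optics, background_method))
    mt <- match_truth(res$tracks, vid$truth)
    n_videos <- i
    n_total <- n_total + length(cfg$cells)
    dx <- c(dx, mt$dx); dy <- c(dy, mt$dy)
    if (!is.null(mt$matches)) {
      m <- mt$matches
      truth1 <- vid$truth[!duplicated(vid$truth$cell_id), ]
      m$z_true_um <- truth1$z_um[match(m$cell_id, truth1$cell_id)]
      m$video_seed <- vid_seed
      rows[[length(rows) + 1]] <- m
    }
    rm(vid, res); gc(FALSE)
    cells <- do.call(rbind, rows)
    if (sum(is.finite(cells$z_mean_abs_err_um)) >= min_cells) break
  }
  cells <- do.call(rbind, rows)
  dz <- cells$z_mean_abs_err_um[is.finite(cells$z_mean_abs_err_um)]
  list(cells = cells,
       mean_abs_dz_um = mean(dz),
       n_with_z = length(dz),
       n_cells_total = n_total,
       n_videos = n_videos,
       mean_abs_dx_um = mean(abs(dx)),
       mean_abs_dy_um = mean(abs(dy)),
       max_abs_v_rel = max(abs(cells$v_err_rel)))
}
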