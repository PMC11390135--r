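#' Write a hologram stack as a multi-page TIFF
#'
#' Frames are stored as 32-bit float TIFF pages.  The TIFF float writer
#' clamps values to \\[0, 1\\], so the stack is scaled by its maximum and the
#' scale, frame interval and pitch are recorded in a JSON sidecar
#' (\code{<path>.json}) that [read_stack()] re-applies.
#'
#' @param stack A [hologram_stack()].
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "hologram_stack"))
  ## power-of-two scale: dividing float32-representable values by it is
  ## exact in binary, so a second write/read round trip is bit-stable
  scale <- 2^ceiling(log2(max(1, max(vapply(stack$frames, max,
                                            numeric(1))))))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / scale), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, frame_interval = stack$frame_interval,
         pitch = stack$pitch, n_frames = length(stack$frames)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hologram stack from TIFF
#'
#' Accepts a multi-page TIFF or a directory of single-frame TIFFs (read in
#' lexicographic order).  A JSON sidecar written by [write_stack()]
#' restores intensity scale and metadata; otherwise \code{frame_interval}
#' and \code{pitch} must be given.
#'
#' @param path TIFF file or directory.
#' @param frame_interval,pitch Metadata overrides (seconds, meters).
#' @return A [hologram_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL, pitch = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF files in ", path)
    frames <- lapply(files, function(f) {
      pages <- tiff::readTIFF(f, all = TRUE)
      if (length(pages) != 1) stop("expected single-page TIFFs in directory")
      pages[[1]]
    })
    side <- file.path(path, "stack.json")
  } else {
    if (!file.exists(path)) stop("unreadable file: ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    side <- paste0(path, ".json")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mismatching shapes")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  scale <- meta$scale %||% 1
  fi <- frame_interval %||% meta$frame_interval %||%
    stop("frame_interval not given and no sidecar found")
  pt <- pitch %||% meta$pitch %||%
    stop("pitch not given and no sidecar found")
  hologram_stack(lapply(frames, function(f) {
    m <- f * scale
    storage.mode(m) <- "double"
    m
  }), fi, pt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.track_table <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    d <- tr$detections
    z <- tr$z_estimates
    zi <- match(d$frame, if (nrow(z)) z$frame else integer())
    data.frame(cell_id = tr$cell_id, frame = d$frame, t_s = d$t_s,
               x_um = d$x_um, y_um = d$y_um,
               z_um = if (nrow(z)) z$z_um[zi] else NA_real_,
               radius_um = d$radius_um, v_um_s = tr$v_um_s,
               z_confidence = if (nrow(z))
                 ifelse(is.na(zi), NA, !z$low_confidence[zi]) else NA)
  })
  do.call(rbind, rows)
}

#' Write tracks to CSV
#'
#' One row per (cell, frame) detection with columns \code{cell_id, frame,
#' t_s, x_um, y_um, z_um, radius_um, v_um_s, z_confidence}; frames without
#' an axial estimate leave \code{z_um} empty.
#'
#' @param tracks List of \code{cell_track} objects, or a data.frame already
#'   in the output layout.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else .track_table(tracks)
  if (is.null(df))
    df <- data.frame(cell_id = integer(), frame = integer(), t_s = numeric(),
                     x_um = numeric(), y_um = numeric(), z_um = numeric(),
                     radius_um = numeric(), v_um_s = numeric(),
                     z_confidence = logical())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tracks CSV
#'
#' @param path CSV written by [write_tracks()].
#' @return data.frame; duplicated (cell_id, frame) rows raise an error.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "frame", "t_s", "x_um", "y_um", "z_um", "radius_um",
            "v_um_s", "z_confidence")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing track columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df[, c("cell_id", "frame")]))
    stop("duplicate (cell_id, frame) rows")
  df
}

#' Write a run-provenance record
#'
#' Every scripted pipeline run records its configuration, seed and package
#' version as JSON next to its outputs.
#'
#' @param path Output JSON path.
#' @param config An [optical_config()] (or any serializable list).
#' @param seed Integer seed used.
#' @param extra Optional named list merged into the record.
#' @return \code{path}, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  rec <- c(list(package = "holoflow",
                version = as.character(utils::packageVersion("holoflow")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                config = unclass(config)),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write a pipeline run configuration
#'
#' YAML round-trip of the optical configuration plus method parameters;
#' \code{read_run_config} rebuilds the [optical_config()] object.
#'
#' @param path YAML file.
#' @return For \code{read_run_config}, a list with an \code{optics} element
#'   of class \code{optical_config} plus any other stored entries.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$optics)) {
    o <- cfg$optics
    cfg$optics <- optical_config(
      wavelength = o$wavelength, magnification = o$magnification,
      na = o$na, camera_pitch = o$camera_pitch,
      sensor_rows = o$sensor_rows, sensor_cols = o$sensor_cols,
      frame_interval = o$frame_interval,
      carrier_freq = unlist(o$carrier_freq),
      reference_amplitude = o$reference_amplitude %||% 1)
  }
  cfg
}

#' @rdname read_run_config
#' @param config List (with optional \code{optics} entry) to serialize.
#' @export
write_run_config <- function(config, path) {
  if (!is.null(config$optics)) {
    o <- unclass(config$optics)
    o$object_pitch <- NULL          # derived, not stored
    config$optics <- o
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
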