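#' Ordered stack of hologram frames
#'
#' A time series of 2D non-negative intensity rasters of uniform shape, with
#' its frame interval and pixel pitch (object space).
#'
#' @param frames List of numeric matrices, all the same shape, intensities
#'   >= 0.
#' @param frame_interval Seconds between frames.
#' @param pitch Object-space pixel pitch in meters.
#' @return An object of class \code{hologram_stack}.
#' @export
hologram_stack <- function(frames, frame_interval, pitch) {
  if (!is.list(frames) || length(frames) < 1)
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share one shape")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("hologram intensities must be non-negative")
  stopifnot(frame_interval > 0, pitch > 0)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pitch = pitch),
            class = "hologram_stack")
}

#' @export
length.hologram_stack <- function(x) length(x$frames)

#' @export
print.hologram_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("hologram_stack: %d frames of %d x %d px, dt %.4g ms, pitch %.4g um\n",
              length(x$frames), d[1], d[2], x$frame_interval * 1e3,
              x$pitch * 1e6))
  invisible(x)
}

#' @export
`[.hologram_stack` <- function(x, i) {
  hologram_stack(x$frames[i], x$frame_interval, x$pitch)
}
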