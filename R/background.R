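#' Carrier-cancelling half-size down-sampling
#'
#' 2x2 block averaging that halves each axis.  Averaging adjacent pixel
#' pairs nulls a fringe of period exactly 2 px and strongly suppresses
#' near-Nyquist carriers, so the down-sampled hologram shows the cells
#' without the off-axis fringes.  Odd trailing rows/columns are trimmed
#' (with a message).
#'
#' @param frame Numeric matrix, at least 2 x 2.
#' @return Matrix of half the size per axis.
#' @export
downsample_half <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 2 || ncol(frame) < 2)
    stop("raster smaller than 2 x 2 cannot be down-sampled")
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr %% 2 == 1 || nc %% 2 == 1) {
    message("trimming one edge row/column to make dimensions even")
    frame <- frame[seq_len(nr - nr %% 2), seq_len(nc - nc %% 2), drop = FALSE]
    nr <- nrow(frame); nc <- ncol(frame)
  }
  half_rows <- frame[seq(1, nr, 2), , drop = FALSE] +
    frame[seq(2, nr, 2), , drop = FALSE]
  (half_rows[, seq(1, nc, 2), drop = FALSE] +
     half_rows[, seq(2, nc, 2), drop = FALSE]) / 4
}

#' Down-sample every frame of a stack
#'
#' @param stack A [hologram_stack()].
#' @return A [hologram_stack()] at half size and doubled pitch.
#' @export
downsample_stack <- function(stack) {
  stopifnot(inherits(stack, "hologram_stack"))
  hologram_stack(lapply(stack$frames, downsample_half),
                 stack$frame_interval, stack$pitch * 2)
}

#' Normalized cross-correlation at zero lag
#'
#' Zero-mean NCC (Pearson correlation of the flattened rasters), in
#' \\[-1, 1\\].
#'
#' @param a,b Numeric matrices of identical shape, each with nonzero
#'   variance.
#' @return Scalar correlation.
#' @export
ncc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero-variance input: NCC undefined")
  stats::cor(av, bv)
}

.background_model <- function(background, method, params) {
  eps <- max(1e-6 * mean(background), .Machine$double.eps)
  structure(list(background = pmax(background, eps), method = method,
                 params = params),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model (%s): %d x %d px\n", x$method,
              nrow(x$background), ncol(x$background)))
  invisible(x)
}

#' Superimposed spectrum method (SSM) background
#'
#' Averages the 2D Fourier spectra of the first \code{n_frames} frames and
#' inverse-transforms the superimposed spectrum: the spatial frequencies of
#' the quasi-static background are reinforced while the contributions of
#' flowing cells average out.  By linearity of the transform pair the result
#' equals the temporal pixel-wise mean of those frames, which serves as an
#' exact oracle in the tests.
#'
#' @param stack A down-sampled [hologram_stack()].
#' @param n_frames Number of leading frames to superimpose (default: all;
#'   must be >= 2).
#' @return A \code{background_model}.
#' @export
ssm_background <- function(stack, n_frames = length(stack)) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (n_frames < 2) stop("SSM needs at least 2 frames")
  if (n_frames > length(stack)) stop("n_frames exceeds stack length")
  spec <- Reduce(`+`, lapply(stack$frames[seq_len(n_frames)], fft2)) / n_frames
  bg <- Re(ifft2(spec))
  .background_model(bg, "SSM", list(n_frames = n_frames))
}

#' Static background matching method (SBMM) background
#'
#' Partitions the frames into a grid of blocks and, for every block
#' position, computes the NCC between the block in adjacent frame pairs.
#' Pairs whose NCC reaches the threshold are declared static (no cell was
#' crossing the block); the background block is the average of the block
#' over all frames participating in a static pair.  Blocks that are never
#' static fall back to the temporal median (robust to transient cells),
#' with a warning.
#'
#' Blocks whose content is essentially constant (relative contrast below
#' \code{flat_tol}) carry no correlation signal and are treated as static.
#'
#' @param stack A down-sampled [hologram_stack()] with >= 2 frames.
#' @param block_grid Integer length-2: blocks along (rows, cols);
#'   default 10 x 10.
#' @param ncc_threshold Static-pair threshold on the NCC (default 0.98).
#' @param flat_tol Relative-contrast floor below which a block pair is
#'   trivially static.
#' @return A \code{background_model}; \code{params$static_pairs} holds, per
#'   block, the indices i of adjacent pairs (i, i+1) declared static, and
#'   \code{params$fallback_blocks} the blocks that used the median fallback.
#' @export
sbmm_background <- function(stack, block_grid = c(10L, 10L),
                            ncc_threshold = 0.98, flat_tol = 1e-6) {
  stopifnot(inherits(stack, "hologram_stack"))
  nt <- length(stack)
  if (nt < 2) stop("SBMM needs at least 2 frames")
  d <- dim(stack$frames[[1]])
  gb <- as.integer(block_grid)
  stopifnot(length(gb) == 2, all(gb >= 1), all(gb <= d))
  row_cut <- .block_bounds(d[1], gb[1])
  col_cut <- .block_bounds(d[2], gb[2])
  bg <- matrix(0, d[1], d[2])
  static_pairs <- vector("list", gb[1] * gb[2])
  fallback <- character()
  for (bi in seq_len(gb[1])) {
    for (bj in seq_len(gb[2])) {
      rows <- row_cut[[bi]]; cols <- col_cut[[bj]]
      blk <- vapply(stack$frames,
                    function(f) as.vector(f[rows, cols]),
                    numeric(length(rows) * length(cols)))
      mu <- colMeans(blk)
      cen <- sweep(blk, 2, mu)
      ss <- sqrt(colMeans(cen^2))
      contrast <- ss / pmax(abs(mu), .Machine$double.eps)
      num <- colMeans(cen[, -nt, drop = FALSE] * cen[, -1, drop = FALSE])
      den <- ss[-nt] * ss[-1]
      r <- ifelse(den > 0, num / den, 0)
      trivially_static <- contrast[-nt] < flat_tol & contrast[-1] < flat_tol
      ok <- which(r >= ncc_threshold | trivially_static)
      idx <- (bi - 1) * gb[2] + bj
      static_pairs[[idx]] <- ok
      if (length(ok)) {
        fr <- sort(unique(c(ok, ok + 1)))
        bg[rows, cols] <- matrix(rowMeans(blk[, fr, drop = FALSE]),
                                 length(rows), length(cols))
      } else {
        fallback <- c(fallback, sprintf("(%d,%d)", bi, bj))
        bg[rows, cols] <- matrix(apply(blk, 1, stats::median),
                                 length(rows), length(cols))
      }
    }
  }
  if (length(fallback))
    warning("no static adjacent pair for block(s) ",
            paste(fallback, collapse = " "), "; used temporal median")
  .background_model(bg, "SBMM",
                    list(block_grid = gb, ncc_threshold = ncc_threshold,
                         static_pairs = static_pairs,
                         fallback_blocks = fallback))
}

.block_bounds <- function(n, g) {
  cuts <- floor(seq(0, n, length.out = g + 1))
  lapply(seq_len(g), function(i) (cuts[i] + 1):cuts[i + 1])
}

#' Divide a stack by its background
#'
#' Element-wise division by the (epsilon-floored) background: the result is
#' ~1 wherever nothing moved, with flowing cells appearing as deviations
#' from 1.
#'
#' @param stack A down-sampled [hologram_stack()].
#' @param model A \code{background_model} of matching shape.
#' @return A normalized [hologram_stack()].
#' @export
remove_background <- function(stack, model) {
  stopifnot(inherits(stack, "hologram_stack"),
            inherits(model, "background_model"))
  if (!identical(dim(stack$frames[[1]]), dim(model$background)))
    stop("shape mismatch between stack and background")
  hologram_stack(lapply(stack$frames, function(f) f / model$background),
                 stack$frame_interval, stack$pitch)
}
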