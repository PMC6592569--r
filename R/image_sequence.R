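#' Registered image sequence with temporal and spatial calibration
#'
#' The universal container for video data in pixflow: a 3-D intensity array
#' `[row, col, time]` together with the frame rate and the on-sample pixel
#' size. All pipeline stages consume and return this class (epochs are a
#' subclass carrying their start time).
#'
#' @param frames numeric 3-D array `[row, col, time]` with at least 2 frames.
#' @param fps frame rate in frames per second (> 0).
#' @param pixel_um pixel diameter on the sample in micrometres (> 0).
#'   Typical adaptive-optics retinal data is 1 um/pixel after 2x2 binning.
#' @return An object of class `image_sequence`.
#' @examples
#' seq <- image_sequence(array(runif(16 * 16 * 10), c(16, 16, 10)),
#'                       fps = 300, pixel_um = 1)
#' n_frames(seq)
#' @export
image_sequence <- function(frames, fps, pixel_um) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_pixflow("`frames` must be a 3-D array [row, col, time]")
  if (dim(frames)[3] < 2L)
    stop_pixflow("an image sequence needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop_pixflow("`fps` must be a single positive number")
  if (!is.numeric(pixel_um) || length(pixel_um) != 1L || pixel_um <= 0)
    stop_pixflow("`pixel_um` must be a single positive number")
  structure(list(frames = frames, fps = fps, pixel_um = pixel_um),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d x %d px, %d frames @ %g fps, %g um/px\n",
              d[1], d[2], d[3], x$fps, x$pixel_um))
  if (!is.null(x$start_ms))
    cat(sprintf("  epoch starting at %g ms (%g ms duration)\n",
                x$start_ms, x$duration_ms))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq an [image_sequence].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' @rdname n_frames
#' @export
frame_dim <- function(seq) dim(seq$frames)[1:2]

as_epoch <- function(seq, frames_idx, start_ms) {
  ep <- image_sequence(seq$frames[, , frames_idx, drop = FALSE],
                       seq$fps, seq$pixel_um)
  ep$start_ms <- start_ms
  ep$duration_ms <- length(frames_idx) / seq$fps * 1000
  class(ep) <- c("pix_epoch", class(ep))
  ep
}

# Pixel-by-time matrix view (column-major pixel order).
trace_matrix <- function(seq) {
  d <- dim(seq$frames)
  matrix(seq$frames, d[1] * d[2], d[3])
}
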