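#' Normalize every frame to unit mean intensity
#'
#' Divides each frame by its spatial mean so that slow global intensity
#' changes (photoreceptor bleaching, illumination drift) do not masquerade
#' as temporal signal. First step of the standard pipeline.
#'
#' @param seq an [image_sequence].
#' @return An [image_sequence] whose every frame has mean 1.
#' @export
normalize_frame_means <- function(seq) {
  d <- dim(seq$frames)
  mu <- colMeans(matrix(seq$frames, d[1] * d[2], d[3]))
  if (any(mu == 0))
    stop_pixflow("frame(s) with zero mean intensity: invalid input")
  out <- seq
  out$frames <- sweep(seq$frames, 3, mu, "/")
  out
}

#' Frames spanned by a millisecond interval
#'
#' Rounds `ms * fps / 1000` to the nearest frame; the frame-rate/window
#' combinations used in practice (200 ms at 300 fps = 60 frames, 100 ms at
#' 300 fps = 30 frames, 100 ms at 400 fps = 40 frames) are exact.
#'
#' @param ms interval in milliseconds.
#' @param fps frame rate in frames/s.
#' @return Integer number of frames.
#' @export
window_frames <- function(ms, fps) as.integer(round(ms * fps / 1000))

#' Subtract a rolling temporal mean from every pixel trace
#'
#' Removes each pixel's local baseline, computed over a centered rolling
#' window (truncated at the sequence ends), which greatly increases the
#' visibility of passing blood cells against static structure.
#'
#' @param seq an [image_sequence].
#' @param window_ms rolling window length in ms (default 200, i.e. 60
#'   frames at 300 fps).
#' @return An [image_sequence] of baseline-subtracted traces.
#' @export
subtract_rolling_mean <- function(seq, window_ms = 200) {
  T_ <- n_frames(seq)
  n <- window_frames(window_ms, seq$fps)
  if (n < 2L)
    stop_pixflow("rolling window shorter than 2 frames")
  if (n > T_)
    stop_pixflow("sequence shorter than one rolling window")
  M <- trace_matrix(seq)                     # P x T
  csum <- M
  for (t in 2:T_) csum[, t] <- csum[, t - 1L] + M[, t]
  half_lo <- (n - 1L) %/% 2L
  half_hi <- n - 1L - half_lo
  out <- M
  for (t in seq_len(T_)) {
    lo <- max(1L, t - half_lo)
    hi <- min(T_, t + half_hi)
    s <- csum[, hi] - (if (lo > 1L) csum[, lo - 1L] else 0)
    out[, t] <- M[, t] - s / (hi - lo + 1L)
  }
  res <- seq
  res$frames <- array(out, dim(seq$frames))
  res
}

#' Detrend and high-pass filter every pixel trace
#'
#' Subtracts each pixel's best straight-line fit over time, then zeroes the
#' lowest Fourier modes (all frequencies up to `cycles` cycles/sequence,
#' both conjugate bins), suppressing residual drift from bleaching or pupil
#' misalignment while leaving flow-rate fluctuations intact.
#'
#' Detrending and Fourier filtering are applied as one orthogonal
#' projection: each trace loses its least-squares fit onto the span of
#' intercept, linear ramp and the Fourier harmonics up to `cycles`
#' cycles/sequence. A pure ramp or a pure low-frequency sinusoid therefore
#' maps to exactly zero, and the operation is idempotent; fitting the
#' components jointly avoids the leakage a sequential detrend-then-FFT
#' would leave behind (the ramp is not orthogonal to the Fourier bins on a
#' finite grid).
#'
#' @param seq an [image_sequence] of at least 4 frames.
#' @param cycles highest whole frequency to remove, in cycles per sequence
#'   (default 2).
#' @return Filtered [image_sequence]; every pixel trace has mean ~0.
#' @export
temporal_filter <- function(seq, cycles = 2) {
  T_ <- n_frames(seq)
  if (T_ < 4L) stop_pixflow("temporal_filter needs at least 4 frames")
  M <- trace_matrix(seq)                     # P x T
  t_idx <- seq_len(T_)
  X <- cbind(1, t_idx - (T_ + 1) / 2)
  for (k in seq_len(min(cycles, (T_ - 1L) %/% 2))) {
    X <- cbind(X, cos(2 * pi * k * (t_idx - 1) / T_),
               sin(2 * pi * k * (t_idx - 1) / T_))
  }
  Q <- qr.Q(qr(X))                           # orthonormal basis, T x p
  M <- M - (M %*% Q) %*% t(Q)
  res <- seq
  res$frames <- array(M, dim(seq$frames))
  res
}

#' Motion contrast image
#'
#' Per-pixel temporal standard deviation (population convention, divide by
#' N). Perfused vessels fluctuate as cells pass and light up against the
#' static background; this image drives the vessel segmentation and the
#' similarity normalization in the PIX core.
#'
#' @param seq an [image_sequence].
#' @return Numeric matrix of per-pixel temporal standard deviations.
#' @export
motion_contrast <- function(seq) {
  M <- trace_matrix(seq)
  mu <- rowMeans(M)
  v <- rowMeans(M * M) - mu * mu
  matrix(sqrt(pmax(v, 0)), dim(seq$frames)[1], dim(seq$frames)[2])
}

#' Split a sequence into overlapping analysis epochs
#'
#' Velocimetry is computed over short temporal windows: long enough for a
#' stable estimate, short enough that the true velocity does not drift
#' within the window. Defaults are 100 ms epochs spaced 50 ms apart
#' (two-fold temporal redundancy). A trailing partial epoch is discarded.
#'
#' @param seq an [image_sequence].
#' @param epoch_ms epoch duration in ms (default 100).
#' @param step_ms spacing between epoch starts in ms (default 50).
#' @return List of epochs (subclass of [image_sequence] with `start_ms`).
#' @export
split_epochs <- function(seq, epoch_ms = 100, step_ms = 50) {
  T_ <- n_frames(seq)
  ne <- window_frames(epoch_ms, seq$fps)
  st <- window_frames(step_ms, seq$fps)
  if (ne < 2L || st < 1L) stop_pixflow("epoch or step too short")
  if (T_ < ne) stop_pixflow("sequence shorter than one epoch")
  starts <- seq.int(1L, T_ - ne + 1L, by = st)
  lapply(starts, function(s0) {
    as_epoch(seq, s0:(s0 + ne - 1L), start_ms = (s0 - 1L) / seq$fps * 1000)
  })
}

#' Standard preprocessing chain
#'
#' Applies, in the documented fixed order: frame-mean normalization,
#' rolling-mean subtraction, and temporal detrend/Fourier filtering.
#' Filtering runs on the full sequence before any epoch splitting.
#'
#' @inheritParams subtract_rolling_mean
#' @param detrend_cycles passed to [temporal_filter()].
#' @return Filtered [image_sequence].
#' @export
preprocess_sequence <- function(seq, window_ms = 200, detrend_cycles = 2) {
  seq <- normalize_frame_means(seq)
  seq <- subtract_rolling_mean(seq, window_ms = window_ms)
  temporal_filter(seq, cycles = detrend_cycles)
}
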