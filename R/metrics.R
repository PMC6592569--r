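#' Segment-wise median filling of a velocity map
#'
#' Render-only smoothing/interpolation: within each labelled segment, every
#' pixel's value (NaN for missing data) is replaced by the median of the
#' valid same-segment pixels lying within `radius_um` of the *closest valid
#' pixel* to the target. Values never cross segment labels (junctions and
#' crossings are not disambiguated, so interpolation between segments is
#' not allowed). Segments with no valid pixel stay NaN. All quantitative
#' metrics in this package are computed from raw, unfilled maps.
#'
#' @param field a `velocity_field`.
#' @param seg a `vessel_segmentation` sharing the field's shape.
#' @param radius_um median neighbourhood radius (default 5 um).
#' @return A `velocity_field` with the filled `speed` matrix.
#' @export
fill_segments <- function(field, seg, radius_um = 5) {
  stopifnot(all(dim(field$speed) == dim(seg$labels)))
  px <- seg$pixel_um
  r2 <- (radius_um / px)^2
  out <- field
  out$speed <- matrix(NA_real_, nrow(field$speed), ncol(field$speed))
  nr <- nrow(field$speed)
  for (lab in seq_along(seg$segment_lengths_um)) {
    lab_idx <- which(seg$labels == lab)
    vals <- field$speed[lab_idx]
    valid <- which(!is.na(vals))
    if (length(valid) == 0L) next
    v_rc <- idx_to_rc(lab_idx[valid], nr)
    v_val <- vals[valid]
    t_rc <- idx_to_rc(lab_idx, nr)
    for (i in seq_along(lab_idx)) {
      d2 <- (v_rc[, 1] - t_rc[i, 1])^2 + (v_rc[, 2] - t_rc[i, 2])^2
      nearest <- which.min(d2)
      nd2 <- (v_rc[, 1] - v_rc[nearest, 1])^2 +
             (v_rc[, 2] - v_rc[nearest, 2])^2
      out$speed[lab_idx[i]] <- stats::median(v_val[nd2 <= r2])
    }
  }
  out
}

#' Per-segment velocity time traces
#'
#' For each labelled segment and each epoch, the mean of the valid (non-NaN)
#' raw speeds over the segment's support; NaN when the segment has no valid
#' pixel in that epoch.
#'
#' @param fields list of `velocity_field`s (successive epochs, raw).
#' @param seg the shared `vessel_segmentation`.
#' @return A `segment_traces` list: `speed` (epochs x segments matrix),
#'   `epoch_start_ms`, `length_um` (per segment).
#' @export
segment_traces <- function(fields, seg) {
  labs <- seq_along(seg$segment_lengths_um)
  sup <- lapply(labs, function(l) which(seg$labels == l))
  sp <- t(vapply(fields, function(f) {
    vapply(sup, function(ix) {
      v <- f$speed[ix]
      if (all(is.na(v))) NaN else mean(v, na.rm = TRUE)
    }, 0)
  }, numeric(length(labs))))
  sp <- matrix(sp, nrow = length(fields))
  structure(list(speed = sp,
                 epoch_start_ms = vapply(fields, `[[`, 0, "epoch_start_ms"),
                 length_um = unname(seg$segment_lengths_um)),
            class = "segment_traces")
}

#' Pulsatility index of a velocity trace
#'
#' `PI = (max - min) / mean` over the non-NaN entries; 0 for a constant
#' trace, and `2 * depth` for a fully sampled sinusoid of fractional
#' modulation `depth`.
#'
#' @param speeds numeric vector of speeds (NaN allowed).
#' @return Dimensionless pulsatility index.
#' @export
pulsatility_index <- function(speeds) {
  v <- speeds[!is.na(speeds)]
  if (length(v) < 1L) stop_pixflow("no valid speeds")
  m <- mean(v)
  if (m <= 0) stop_pixflow("nonpositive mean speed")
  (max(v) - min(v)) / m
}

#' Goodness of fit of a trace against a reference trace
#'
#' `R2` is the squared Pearson correlation (equivalently the R-squared of
#' the least-squares linear fit) between the paired non-NaN entries;
#' `rms_resid` is the root-mean-square of the *direct* differences
#' (trace - reference), not of fit residuals, so a constant offset shows up
#' in the RMS but not in R2.
#'
#' @param trace,reference equal-length numeric vectors (NaN allowed;
#'   pairwise deletion).
#' @return List with `R2` and `rms_resid`.
#' @export
goodness_of_fit <- function(trace, reference) {
  stopifnot(length(trace) == length(reference))
  ok <- !is.na(trace) & !is.na(reference)
  if (sum(ok) < 3L) stop_pixflow("need >= 3 paired non-NaN entries")
  x <- trace[ok]; y <- reference[ok]
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
        else stats::cor(x, y)^2
  list(R2 = r2, rms_resid = sqrt(mean((x - y)^2)))
}

#' Correlation of each segment to the field-average waveform
#'
#' The per-epoch mean across all segments (NaN-aware) serves as a surrogate
#' for the cardiac influence at the capillary level; each segment's squared
#' Pearson correlation against this field model measures how
#' physiologically plausible its trace is. Segments with zero variance get
#' R2 = 0 by convention (flagged via the `degenerate` attribute).
#'
#' @param traces a `segment_traces` object with >= 2 segments.
#' @return Numeric vector of per-segment R2 values.
#' @export
field_average_correlation <- function(traces) {
  sp <- traces$speed
  if (ncol(sp) < 2L) stop_pixflow("need >= 2 segments")
  model <- rowMeans(sp, na.rm = TRUE)
  if (stats::sd(model[!is.na(model)]) == 0)
    stop_pixflow("degenerate (constant) field model")
  degenerate <- logical(ncol(sp))
  r2 <- vapply(seq_len(ncol(sp)), function(j) {
    ok <- !is.na(sp[, j]) & !is.na(model)
    if (sum(ok) < 3L || stats::sd(sp[ok, j]) == 0) {
      degenerate[j] <<- TRUE
      return(0)
    }
    stats::cor(sp[ok, j], model[ok])^2
  }, 0)
  attr(r2, "degenerate") <- degenerate
  r2
}

#' Capillary transit time statistics
#'
#' Per epoch, each segment's transit time is its length divided by its
#' speed (`um / (mm/s) = ms`); `CTT` is the mean and `CTTH` the standard
#' deviation over segments (spatial heterogeneity). Across epochs the line
#' `CTTH = m * CTT + b` is fit by least squares; its slope gauges how
#' equitably flow increases are distributed over the network.
#'
#' @param traces a `segment_traces` object (lengths must be present).
#' @return List: `table` (data.frame epoch_start_ms, CTT_ms, CTTH_ms,
#'   n_segments), `slope`, `intercept`, `R2` of the CTTH-vs-CTT fit
#'   (NA with a warning when CTT has no variance across epochs).
#' @export
ctt_analysis <- function(traces) {
  sp <- traces$speed
  len <- traces$length_um
  stopifnot(length(len) == ncol(sp))
  res <- lapply(seq_len(nrow(sp)), function(e) {
    v <- sp[e, ]
    ok <- !is.na(v) & v > 0
    if (any(!is.na(v) & v <= 0))
      warning("zero/negative speeds excluded from CTT")
    if (sum(ok) < 2L) return(c(NA_real_, NA_real_, sum(ok)))
    ctt <- len[ok] / v[ok]                     # ms
    c(mean(ctt), stats::sd(ctt), sum(ok))
  })
  res <- do.call(rbind, res)
  tab <- data.frame(epoch_start_ms = traces$epoch_start_ms,
                    CTT_ms = res[, 1], CTTH_ms = res[, 2],
                    n_segments = res[, 3])
  ok <- !is.na(tab$CTT_ms) & !is.na(tab$CTTH_ms)
  if (sum(ok) < 3L || stats::sd(tab$CTT_ms[ok]) == 0) {
    warning("CTT has no usable variance across epochs: slope undefined")
    return(list(table = tab, slope = NA_real_, intercept = NA_real_,
                R2 = NA_real_))
  }
  fit <- stats::lm(CTTH_ms ~ CTT_ms, data = tab[ok, ])
  list(table = tab, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       R2 = summary(fit)$r.squared)
}

#' Summary flow statistics for one segment trace
#'
#' Average velocity (AV), pulsatility index (PI), and optionally goodness
#' of fit against a reference trace.
#'
#' @param speeds numeric speed trace (mm/s, NaN allowed).
#' @param reference optional reference trace of the same length.
#' @return List with `AV`, `PI`, and (given a reference) `R2`,
#'   `rms_resid`.
#' @export
flow_stats <- function(speeds, reference = NULL) {
  out <- list(AV = mean(speeds, na.rm = TRUE),
              PI = pulsatility_index(speeds))
  if (!is.null(reference)) out <- c(out, goodness_of_fit(speeds, reference))
  out
}
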