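#' Parameters for the simplified particle-image-velocimetry baseline
#'
#' Tiered region-of-interest scheme: a small template ROI is correlated
#' within progressively larger search ROIs; the estimate from the smallest
#' tier whose implied speed lies inside that tier's validity range
#' `[v_min, v_max_tier]` is accepted, otherwise the next tier is tried.
#' Defaults follow standard adaptive-optics capillary PIV practice.
#'
#' @param roi_small_um template ROI diameter (default 12 um).
#' @param roi_large_um search ROI diameters (default 18, 30, 36 um).
#' @param roi_step_um grid spacing of ROI centres (default 6 um).
#' @param v_min minimum valid speed, mm/s (default 0.3).
#' @param v_max_tiers per-tier maximum valid speed, mm/s (default 2.25,
#'   3.75, 4.5).
#' @param min_corr minimum normalized correlation of an acceptable peak
#'   (default 0.5); the "validity rule" every PIV scheme needs to separate
#'   genuine from spurious single-pair correlations.
#' @return A `piv_params` list.
#' @export
piv_params <- function(roi_small_um = 12, roi_large_um = c(18, 30, 36),
                       roi_step_um = 6, v_min = 0.3,
                       v_max_tiers = c(2.25, 3.75, 4.5), min_corr = 0.5) {
  stopifnot(roi_small_um > 0, all(roi_large_um > roi_small_um),
            length(roi_large_um) == length(v_max_tiers),
            all(v_min < v_max_tiers))
  structure(list(roi_small_um = roi_small_um, roi_large_um = roi_large_um,
                 roi_step_um = roi_step_um, v_min = v_min,
                 v_max_tiers = v_max_tiers, min_corr = min_corr),
            class = "piv_params")
}

# Normalized cross-correlation of template `a` against same-size windows of
# `b` at every offset; returns the (ncc, dr, dc) of the peak.
ncc_peak <- function(a, b) {
  m <- nrow(a); M <- nrow(b)
  mc <- ncol(a); Mc <- ncol(b)
  av <- as.vector(a) - mean(a)
  an <- sqrt(sum(av^2))
  best <- c(-Inf, 0, 0)
  if (an == 0) return(best)
  for (dr in 0:(M - m)) {
    for (dc in 0:(Mc - mc)) {
      sub <- b[dr + seq_len(m), dc + seq_len(mc)]
      sv <- as.vector(sub) - mean(sub)
      sn <- sqrt(sum(sv^2))
      if (sn == 0) next
      ncc <- sum(av * sv) / (an * sn)
      if (ncc > best[1]) best <- c(ncc, dr - (M - m) / 2, dc - (Mc - mc) / 2)
    }
  }
  best
}

#' Simplified PIV velocity map
#'
#' For each ROI centre on a regular grid intersecting the vessel mask, the
#' small-ROI patch of frame t is cross-correlated (normalized) within the
#' large-ROI patch of frame t+1 for every successive frame pair of the
#' epoch; the correlation-peak displacement gives a per-pair speed.
#' Pair estimates outside `[v_min, v_max_tier]` for the smallest admissible
#' tier are escalated to larger tiers, then discarded. The per-ROI epoch
#' estimate is the median of surviving pair estimates (NaN when none
#' survive) and is written at the ROI centre pixel.
#'
#' @param epoch a (preprocessed) epoch.
#' @param mask logical vessel mask; ROIs not intersecting it are skipped.
#' @param params a [piv_params()] object.
#' @return A `velocity_field` with speeds at ROI centres (NaN elsewhere).
#' @export
piv_map <- function(epoch, mask, params = piv_params()) {
  T_ <- n_frames(epoch)
  if (T_ < 2L) stop_pixflow("PIV needs at least 2 frames")
  d <- frame_dim(epoch)
  px <- epoch$pixel_um
  m <- max(3L, round(params$roi_small_um / px))
  m <- m + (1L - m %% 2L)                      # odd template size
  step <- max(1L, round(params$roi_step_um / px))
  half_m <- m %/% 2L
  Ms <- sapply(params$roi_large_um, function(u) {
    M <- max(m + 2L, round(u / px)); M + (1L - M %% 2L)
  })
  half_max <- max(Ms) %/% 2L
  centres_r <- seq(half_max + 1L, d[1] - half_max, by = step)
  centres_c <- seq(half_max + 1L, d[2] - half_max, by = step)
  speed <- matrix(NA_real_, d[1], d[2])
  for (cr in centres_r) for (cc in centres_c) {
    roi_rows <- (cr - half_m):(cr + half_m)
    roi_cols <- (cc - half_m):(cc + half_m)
    if (!any(mask[roi_rows, roi_cols])) next
    est <- c()
    for (t in seq_len(T_ - 1L)) {
      a <- epoch$frames[roi_rows, roi_cols, t]
      sp <- NA_real_
      for (k in seq_along(Ms)) {
        half_M <- Ms[k] %/% 2L
        b <- epoch$frames[(cr - half_M):(cr + half_M),
                          (cc - half_M):(cc + half_M), t + 1L]
        pk <- ncc_peak(a, b)
        v <- displacement_to_speed(pk[2], pk[3], epoch$fps, px)
        if (pk[1] >= params$min_corr && v >= params$v_min &&
            v <= params$v_max_tiers[k]) {
          sp <- v
          break
        }
      }
      if (!is.na(sp)) est <- c(est, sp)
    }
    if (length(est) > 0L) speed[cr, cc] <- stats::median(est)
  }
  structure(list(speed = speed, peak_z = NULL,
                 accepted = !is.na(speed),
                 epoch_start_ms = epoch$start_ms %||% 0, frame_lag = 1L,
                 v_max = max(params$v_max_tiers), z_threshold = NA_real_,
                 n_hypotheses = NA_integer_, fps = epoch$fps,
                 pixel_um = px, combine = "piv"),
            class = "velocity_field")
}

#' Spatiotemporal kymograph plot for a vessel segment
#'
#' Samples the epoch's intensity along the segment's ordered skeleton for
#' every frame, producing a space (rows, um) x time (cols, frames) plot in
#' which moving cells trace sloped streaks.
#'
#' @param epoch a (preprocessed) epoch.
#' @param seg a `vessel_segmentation`.
#' @param label segment label.
#' @return An `stk_plot` list: `intensity` (space x time), `s_um`,
#'   `t_ms`.
#' @export
stk_plot <- function(epoch, seg, label) {
  path <- segment_path(seg, label)
  if (nrow(path$rc) < 3L) stop_pixflow("segment skeleton too short")
  idx <- rc_to_idx(path$rc[, 1], path$rc[, 2], frame_dim(epoch)[1])
  M <- trace_matrix(epoch)
  structure(list(intensity = M[idx, , drop = FALSE], s_um = path$s_um,
                 t_ms = (seq_len(n_frames(epoch)) - 1L) / epoch$fps * 1000),
            class = "stk_plot")
}

# 2D spatial correlogram: correlation of the central position's time trace
# with the trace at every position, over a grid of temporal lags.
stk_spatial_correlogram <- function(K) {
  ns <- nrow(K); nt <- ncol(K)
  c0 <- (ns + 1L) %/% 2L
  lags <- -(nt %/% 2L):(nt %/% 2L)
  out <- matrix(0, ns, length(lags))
  ref <- K[c0, ]
  for (j in seq_along(lags)) {
    l <- lags[j]
    t1 <- max(1L, 1L - l):min(nt, nt - l)
    a <- ref[t1]; Bm <- K[, t1 + l, drop = FALSE]
    if (length(t1) >= 3L && stats::sd(a) > 0) {
      bs <- apply(Bm, 1, function(b)
        if (stats::sd(b) > 0) stats::cor(a, b) else 0)
      out[, j] <- bs
    }
  }
  out
}

# 2D temporal correlogram: correlation of the central frame's spatial
# profile with every frame, over a grid of spatial shifts.
stk_temporal_correlogram <- function(K) {
  ns <- nrow(K); nt <- ncol(K)
  t0 <- (nt + 1L) %/% 2L
  shifts <- -(ns %/% 2L):(ns %/% 2L)
  out <- matrix(0, length(shifts), nt)
  ref <- K[, t0]
  for (i in seq_along(shifts)) {
    s <- shifts[i]
    r1 <- max(1L, 1L - s):min(ns, ns - s)
    a <- ref[r1]; Bm <- K[r1 + s, , drop = FALSE]
    if (length(r1) >= 3L && stats::sd(a) > 0) {
      out[i, ] <- apply(Bm, 2, function(b)
        if (stats::sd(b) > 0) stats::cor(a, b) else 0)
    }
  }
  out
}

# Orientation (in velocity units) maximizing the variance of the profile
# obtained by projecting the plot onto lines of slope v = tan(theta),
# with s in um and t in ms so tan(theta) is mm/s. Returns c(v, score).
stk_slope <- function(intensity, s_um, t_ms, theta_step_deg = 0.5,
                      theta_max_deg = 85) {
  A <- intensity - mean(intensity)
  if (sd_pop(A) == 0) return(c(NA_real_, 0))
  ss <- s_um - mean(s_um)
  tt <- t_ms - mean(t_ms)
  S <- matrix(ss, length(ss), length(tt))
  T_ <- matrix(tt, length(ss), length(tt), byrow = TRUE)
  w <- A^2
  thetas <- seq(-theta_max_deg, theta_max_deg, by = theta_step_deg)
  bin <- max(mean(diff(s_um)), 1e-6)
  best <- c(NA_real_, -Inf)
  for (th in thetas) {
    rad <- th * pi / 180
    off <- S * cos(rad) - T_ * sin(rad)
    prof <- tapply(as.vector(A), round(as.vector(off) / bin),
                   mean)
    score <- stats::var(prof) * length(prof)
    if (is.finite(score) && score > best[2]) best <- c(tan(rad), score)
  }
  best
}

#' Spatiotemporal-kymograph segment velocity
#'
#' Builds the segment's space-time plot and its two correlogram variants,
#' keeps the variant with the highest contrast (standard deviation of the
#' mean-subtracted plot), and estimates the dominant streak slope by a
#' Radon-style orientation sweep (0.5 deg resolution): the orientation
#' maximizing the variance of the projected profile. Slope in um/ms equals
#' speed in mm/s. Estimates above `v_max` and temporally constant plots
#' are rejected (NaN).
#'
#' @inheritParams stk_plot
#' @param v_max physiological speed cap, mm/s (default 4.5).
#' @return List: `speed_mm_s` (NaN when rejected), `variant` (one of
#'   `"raw"`, `"spatial_correlogram"`, `"temporal_correlogram"`),
#'   `contrast`.
#' @export
stk_segment_velocity <- function(epoch, seg, label, v_max = 4.5) {
  K <- stk_plot(epoch, seg, label)
  variants <- list(
    raw = K$intensity,
    spatial_correlogram = stk_spatial_correlogram(K$intensity),
    temporal_correlogram = stk_temporal_correlogram(K$intensity))
  # a temporally constant plot carries no flow information at all
  if (max(apply(K$intensity, 1, sd_pop)) < 1e-12)
    return(list(speed_mm_s = NA_real_, variant = "raw", contrast = 0))
  contrast <- vapply(variants, function(m) sd_pop(m - mean(m)), 0)
  pick <- names(which.max(contrast))
  V <- variants[[pick]]
  # correlogram variants live on their own (centered) coordinate grids
  if (pick == "raw") {
    s_um <- K$s_um; t_ms <- K$t_ms
  } else if (pick == "spatial_correlogram") {
    s_um <- K$s_um
    t_ms <- (seq_len(ncol(V)) - 1L) / epoch$fps * 1000
  } else {
    s_um <- (seq_len(nrow(V)) - 1L) * mean(diff(K$s_um))
    t_ms <- K$t_ms
  }
  if (sd_pop(V) == 0)
    return(list(speed_mm_s = NA_real_, variant = pick, contrast = 0))
  sl <- stk_slope(V, s_um, t_ms)
  sp <- abs(sl[1])
  if (!is.finite(sp) || sp > v_max)
    return(list(speed_mm_s = NA_real_, variant = pick,
                contrast = contrast[[pick]]))
  list(speed_mm_s = sp, variant = pick, contrast = contrast[[pick]])
}
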