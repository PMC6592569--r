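#' Time-shifted trace stacks for an epoch
#'
#' PIX compares each pixel's intensity trace against one-frame time-shifted
#' traces of all other pixels. For a T-frame epoch the three copies are:
#' the original traces, a forward-shifted stack (`forward[t] =
#' original[t+1]`) and a backward-shifted stack (`backward[t] =
#' original[t-1]`). The one non-overlapping frame at each end is dropped
#' from comparisons, so every compared trace has `T - 1` samples: forward
#' comparisons pair `original[, 1:(T-1)]` with `forward`, backward
#' comparisons pair `original[, 2:T]` with `backward`.
#'
#' @param epoch an epoch ([image_sequence]) of at least 3 frames.
#' @return List with `original` (pixels x T), `forward` and `backward`
#'   (pixels x T-1), and `n_compare = T - 1`.
#' @export
shifted_traces <- function(epoch) {
  T_ <- n_frames(epoch)
  if (T_ < 3L) stop_pixflow("epoch too short: need >= 3 frames")
  M <- trace_matrix(epoch)
  list(original = M,
       forward = M[, 2:T_, drop = FALSE],
       backward = M[, 1:(T_ - 1L), drop = FALSE],
       n_compare = T_ - 1L)
}

#' RMS difference between a reference trace and candidate traces
#'
#' @param ref numeric vector (the reference trace).
#' @param cand numeric matrix, one candidate trace per row, `length(ref)`
#'   columns.
#' @return Vector of root-mean-square differences, one per candidate.
#' @export
trace_rms <- function(ref, cand) {
  cand <- rbind(cand)
  sqrt(rowMeans(sweep(cand, 2, ref)^2))
}

#' Similarity map for one reference pixel
#'
#' Computes the RMS trace difference between the reference pixel and the
#' appropriately time-shifted trace of every candidate pixel: the lowest
#' RMS difference marks the most likely destination (forward) or source
#' (backward) of the flow information seen at the reference.
#'
#' @param epoch a (preprocessed) epoch of at least 3 frames.
#' @param ref_pixel integer `(row, col)` of the reference pixel.
#' @param direction `"forward"` or `"backward"`.
#' @param support optional logical mask restricting the candidate pixels
#'   (e.g. the binary vessel mask); default considers every pixel.
#' @return A `similarity_map` object with the `rms` matrix (NA outside the
#'   support), ready for [normalize_similarity()].
#' @export
similarity_map <- function(epoch, ref_pixel,
                           direction = c("forward", "backward"),
                           support = NULL) {
  direction <- match.arg(direction)
  st <- shifted_traces(epoch)
  d <- frame_dim(epoch)
  if (ref_pixel[1] < 1 || ref_pixel[1] > d[1] ||
      ref_pixel[2] < 1 || ref_pixel[2] > d[2])
    stop_pixflow("reference pixel outside the frame")
  if (is.null(support)) support <- matrix(TRUE, d[1], d[2])
  sup_idx <- which(support)
  if (length(sup_idx) == 0L) stop_pixflow("empty candidate support")
  ridx <- rc_to_idx(ref_pixel[1], ref_pixel[2], d[1])
  T_ <- n_frames(epoch)
  if (direction == "forward") {
    ref <- st$original[ridx, 1:(T_ - 1L)]
    cand <- st$forward[sup_idx, , drop = FALSE]
  } else {
    ref <- st$original[ridx, 2:T_]
    cand <- st$backward[sup_idx, , drop = FALSE]
  }
  rms <- matrix(NA_real_, d[1], d[2])
  rms[sup_idx] <- trace_rms(ref, cand)
  structure(list(reference_pixel = as.integer(ref_pixel),
                 direction = direction, rms = rms, z = NULL,
                 support_idx = sup_idx, dim = d),
            class = "similarity_map")
}

#' Normalize a similarity map against the motion-contrast background
#'
#' For uncorrelated pixel pairs the expected mean-square trace difference
#' is proportional to the sum of the two trace variances; the reference's
#' variance is common to the whole map, so the background of the raw
#' RMS-error image is essentially the candidate's own standard deviation,
#' which can be subtracted away after putting both maps on a common scale.
#' On the similarity scale (`-RMS`, larger = more similar) that subtraction
#' becomes an addition of the standardized standard-deviation map. The
#' result is re-standardized over the candidate support so that genuine
#' matches stand out in units of the residual background's standard
#' deviation (Z-scores), which is what the significance gate thresholds.
#'
#' @param sim a `similarity_map` with `rms` filled.
#' @param std_map motion-contrast (temporal standard deviation) image of
#'   the same epoch, e.g. from [motion_contrast()].
#' @return The `similarity_map` with its `z` matrix filled.
#' @export
normalize_similarity <- function(sim, std_map) {
  idx <- sim$support_idx
  if (length(idx) < 2L)
    stop_pixflow("support of < 2 pixels: variance undefined")
  # The background of the RMS-error map grows with the candidate's own
  # standard deviation (rms^2 ~ var_ref + var_cand for uncorrelated
  # pixels), so the standardized std map is subtracted from the
  # standardized RMS error; on the similarity scale (-rms) that is an
  # addition. The result is re-standardized so the residual background has
  # unit variance: the significance gate reads z in background-sd units.
  zs <- standardize_pop(-sim$rms[idx])
  zstd <- standardize_pop(std_map[idx])
  z <- matrix(NA_real_, sim$dim[1], sim$dim[2])
  z[idx] <- standardize_pop(zs + zstd)
  sim$z <- z
  sim
}

#' Significance and physiology gate parameters
#'
#' The best match is accepted only if (a) its implied speed does not exceed
#' the physiological cap `v_max`, and (b) its normalized similarity exceeds
#' a Z threshold derived from a one-tailed p-value Bonferroni-corrected for
#' the number of candidate pixels ("hypotheses") considered:
#' `z_threshold = qnorm(1 - p_one_tail / n_hypotheses)`.
#'
#' @param n_hypotheses number of candidate pixels actually compared.
#' @param v_max physiological speed cap, mm/s (default 4.5, the highest
#'   velocity reported in high-frame-rate capillary surveys).
#' @param p_one_tail one-tailed family-wise p-value (default 0.025).
#' @return A `gate_params` list including the derived `z_threshold`.
#' @export
gate_params <- function(n_hypotheses, v_max = 4.5, p_one_tail = 0.025) {
  stopifnot(n_hypotheses >= 1, v_max > 0, p_one_tail > 0, p_one_tail < 1)
  structure(list(v_max = v_max, p_one_tail = p_one_tail,
                 n_hypotheses = as.integer(n_hypotheses),
                 z_threshold = stats::qnorm(1 - p_one_tail / n_hypotheses)),
            class = "gate_params")
}

#' Convert a pixel displacement to speed
#'
#' Speed is the Euclidean displacement between the matched pixels divided
#' by the frame-lag period:
#' `sqrt(drow^2 + dcol^2) * pixel_um * fps / frame_lag / 1000` mm/s.
#' At 300 fps and 1 um/pixel, a 15-pixel displacement is 4.5 mm/s.
#'
#' @param drow,dcol displacement in pixels.
#' @param fps frame rate, frames/s.
#' @param pixel_um pixel size, um/pixel.
#' @param frame_lag temporal lag in frames (fixed at 1 in this pipeline).
#' @return Speed in mm/s.
#' @export
displacement_to_speed <- function(drow, dcol, fps, pixel_um,
                                  frame_lag = 1) {
  stopifnot(frame_lag >= 1)
  sqrt(drow^2 + dcol^2) * pixel_um * fps / frame_lag / 1000
}

#' Gate the best match of a normalized similarity map
#'
#' The best candidate is the global argmax of `z` over the full candidate
#' support (deliberately not restricted to the physiologically plausible
#' radius: unreliable pixels tend to form their strongest spurious
#' correlations at implausible displacements and are thereby rejected).
#' Exact ties are broken by smaller displacement, then by (row, col) scan
#' order. The match is rejected when its implied speed exceeds
#' `gate$v_max` or its peak z falls below `gate$z_threshold`.
#'
#' @param sim a `similarity_map` with `z` filled.
#' @param gate a [gate_params()] object.
#' @param fps,pixel_um temporal and spatial calibration.
#' @return List: `accepted`, `drow`, `dcol`, `speed_mm_s`, `z_peak`,
#'   `reason` (`"ok"`, `"speed"` or `"significance"`).
#' @export
gate_and_match <- function(sim, gate, fps, pixel_um) {
  if (is.null(sim$z)) stop_pixflow("normalize_similarity() must run first")
  idx <- sim$support_idx
  zv <- sim$z[idx]
  best <- pick_best(zv, idx, sim$reference_pixel, sim$dim[1])
  speed <- displacement_to_speed(best$drow, best$dcol, fps, pixel_um)
  z_peak <- best$z
  if (speed > gate$v_max) {
    list(accepted = FALSE, drow = best$drow, dcol = best$dcol,
         speed_mm_s = NA_real_, z_peak = z_peak, reason = "speed")
  } else if (z_peak < gate$z_threshold) {
    list(accepted = FALSE, drow = best$drow, dcol = best$dcol,
         speed_mm_s = NA_real_, z_peak = z_peak, reason = "significance")
  } else {
    list(accepted = TRUE, drow = best$drow, dcol = best$dcol,
         speed_mm_s = speed, z_peak = z_peak, reason = "ok")
  }
}

# Argmax of z with deterministic tie-breaking: smaller displacement first,
# then (row, col) lexicographic order.
pick_best <- function(zv, idx, ref_rc, nr) {
  mx <- max(zv)
  tie <- which(zv == mx)
  rc <- idx_to_rc(idx[tie], nr)
  dr <- as.numeric(rc[, 1] - ref_rc[1])
  dc <- as.numeric(rc[, 2] - ref_rc[2])
  if (length(tie) > 1L) {
    o <- order(dr^2 + dc^2, rc[, 1], rc[, 2])[1]
  } else {
    o <- 1L
  }
  list(drow = dr[o], dcol = dc[o], z = mx)
}

#' Combine forward- and backward-shifted velocity estimates
#'
#' @param fwd,bwd match results from [gate_and_match()] for the same pixel
#'   and epoch.
#' @param mode `"mean"` (average the two accepted speeds; the default) or
#'   `"best"` (keep the direction with the higher peak z, advisable near
#'   junctions where averaging can mix segments).
#' @return List: `accepted`, `speed_mm_s` (NA when both rejected).
#' @export
combine_directions <- function(fwd, bwd, mode = c("mean", "best")) {
  mode <- match.arg(mode)
  if (fwd$accepted && bwd$accepted) {
    sp <- if (mode == "mean") (fwd$speed_mm_s + bwd$speed_mm_s) / 2
          else if (fwd$z_peak >= bwd$z_peak) fwd$speed_mm_s
          else bwd$speed_mm_s
    list(accepted = TRUE, speed_mm_s = sp)
  } else if (fwd$accepted) {
    list(accepted = TRUE, speed_mm_s = fwd$speed_mm_s)
  } else if (bwd$accepted) {
    list(accepted = TRUE, speed_mm_s = bwd$speed_mm_s)
  } else {
    list(accepted = FALSE, speed_mm_s = NA_real_)
  }
}

#' Per-epoch PIX velocity map
#'
#' Runs the full per-pixel chain (shifted traces, RMS similarity against
#' every candidate, background normalization, significance and physiology
#' gating, forward/backward combination) for every reference pixel within
#' the candidate support. The inner comparisons are evaluated with blocked
#' matrix algebra but are numerically identical to the per-pixel chain of
#' [similarity_map()] + [normalize_similarity()] + [gate_and_match()].
#'
#' @param epoch a preprocessed epoch of at least 3 frames.
#' @param segmentation optional `vessel_segmentation`; when supplied both
#'   the reference and candidate pixels are restricted to its binary mask,
#'   otherwise every pixel of the frame is considered.
#' @param v_max,p_one_tail gate parameters (see [gate_params()]);
#'   `n_hypotheses` is always the actual candidate count.
#' @param combine `"mean"` or `"best"`, see [combine_directions()].
#' @param ref_pixels optional integer vector of column-major pixel indices
#'   to evaluate (must lie in the support); used for Monte Carlo
#'   calibration studies. Default: all support pixels.
#' @param min_ref_sd reference pixels whose temporal standard deviation is
#'   below this are rejected up front (no information).
#' @return A `velocity_field`: `speed` (matrix, mm/s, NaN where rejected),
#'   `peak_z`, `accepted`, per-direction displacements, `epoch_start_ms`,
#'   `frame_lag`, `v_max`, `z_threshold`, `n_hypotheses`.
#' @export
velocity_map <- function(epoch, segmentation = NULL, v_max = 4.5,
                         p_one_tail = 0.025, combine = c("mean", "best"),
                         ref_pixels = NULL, min_ref_sd = 1e-10) {
  combine <- match.arg(combine)
  d <- frame_dim(epoch)
  T_ <- n_frames(epoch)
  if (T_ < 3L) stop_pixflow("epoch too short: need >= 3 frames")
  support <- if (is.null(segmentation)) matrix(TRUE, d[1], d[2])
             else segmentation$mask
  sup_idx <- which(support)
  nS <- length(sup_idx)
  if (nS < 2L) stop_pixflow("candidate support too small")
  gate <- gate_params(nS, v_max = v_max, p_one_tail = p_one_tail)
  refs <- if (is.null(ref_pixels)) sup_idx else as.integer(ref_pixels)
  if (!all(refs %in% sup_idx))
    stop_pixflow("ref_pixels must lie within the candidate support")

  M <- trace_matrix(epoch)
  n <- T_ - 1L
  cand_f <- M[sup_idx, 2:T_, drop = FALSE]
  cand_b <- M[sup_idx, 1:(T_ - 1L), drop = FALSE]
  nf2 <- rowSums(cand_f^2)
  nb2 <- rowSums(cand_b^2)
  std_map <- motion_contrast(epoch)
  zstd <- standardize_pop(std_map[sup_idx])
  sup_rc <- idx_to_rc(sup_idx, d[1])

  speed <- matrix(NA_real_, d[1], d[2])
  peak_z <- matrix(NA_real_, d[1], d[2])
  acc <- matrix(FALSE, d[1], d[2])
  disp <- list(f = matrix(NA_real_, d[1], d[2]),
               b = matrix(NA_real_, d[1], d[2]))

  block <- 256L
  for (b0 in seq(1L, length(refs), by = block)) {
    bidx <- refs[b0:min(length(refs), b0 + block - 1L)]
    nb <- length(bidx)
    ref_f <- M[bidx, 1:(T_ - 1L), drop = FALSE]
    ref_b <- M[bidx, 2:T_, drop = FALSE]
    rms_f <- rms_block(ref_f, cand_f, nf2, n)
    rms_b <- rms_block(ref_b, cand_b, nb2, n)
    z_f <- row_standardize(sweep(row_standardize(-rms_f), 2, zstd, `+`))
    z_b <- row_standardize(sweep(row_standardize(-rms_b), 2, zstd, `+`))
    ref_rc <- idx_to_rc(bidx, d[1])
    ref_sd <- std_map[bidx]
    for (i in seq_len(nb)) {
      if (ref_sd[i] < min_ref_sd) {
        # no temporal information at the reference: rejected up front
        peak_z[bidx[i]] <- NA_real_
        next
      }
      m_f <- gate_one(z_f[i, ], sup_rc, ref_rc[i, ], gate,
                      epoch$fps, epoch$pixel_um)
      m_b <- gate_one(z_b[i, ], sup_rc, ref_rc[i, ], gate,
                      epoch$fps, epoch$pixel_um)
      cmb <- combine_directions(m_f, m_b, mode = combine)
      speed[bidx[i]] <- if (cmb$accepted) cmb$speed_mm_s else NA_real_
      acc[bidx[i]] <- cmb$accepted
      peak_z[bidx[i]] <- max(m_f$z_peak, m_b$z_peak)
      disp$f[bidx[i]] <- sqrt(m_f$drow^2 + m_f$dcol^2)
      disp$b[bidx[i]] <- sqrt(m_b$drow^2 + m_b$dcol^2)
    }
  }
  structure(list(speed = speed, peak_z = peak_z, accepted = acc,
                 displacement_px = disp,
                 epoch_start_ms = epoch$start_ms %||% 0,
                 frame_lag = 1L, v_max = v_max,
                 z_threshold = gate$z_threshold, n_hypotheses = nS,
                 fps = epoch$fps, pixel_um = epoch$pixel_um,
                 combine = combine),
            class = "velocity_field")
}

# Vectorized counterpart of gate_and_match operating on a z vector over
# the support; identical tie-break and gating rules.
gate_one <- function(zv, sup_rc, ref_rc, gate, fps, pixel_um) {
  mx <- max(zv)
  tie <- which(zv == mx)
  dr <- as.numeric(sup_rc[tie, 1] - ref_rc[1])
  dc <- as.numeric(sup_rc[tie, 2] - ref_rc[2])
  o <- if (length(tie) > 1L)
    order(dr^2 + dc^2, sup_rc[tie, 1], sup_rc[tie, 2])[1] else 1L
  drow <- dr[o]; dcol <- dc[o]
  sp <- displacement_to_speed(drow, dcol, fps, pixel_um)
  if (sp > gate$v_max)
    list(accepted = FALSE, drow = drow, dcol = dcol,
         speed_mm_s = NA_real_, z_peak = mx, reason = "speed")
  else if (mx < gate$z_threshold)
    list(accepted = FALSE, drow = drow, dcol = dcol,
         speed_mm_s = NA_real_, z_peak = mx, reason = "significance")
  else
    list(accepted = TRUE, drow = drow, dcol = dcol, speed_mm_s = sp,
         z_peak = mx, reason = "ok")
}

# RMS difference between every reference row and every candidate row via
# the polarization identity, computed with one BLAS matrix product.
rms_block <- function(ref, cand, cand_norm2, n) {
  G <- tcrossprod(ref, cand)                     # nref x ncand
  r2 <- rowSums(ref^2)
  d2 <- sweep(sweep(-2 * G, 1, r2, `+`), 2, cand_norm2, `+`)
  sqrt(pmax(d2, 0) / n)
}

# Standardize each row to zero mean and unit population variance.
row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowMeans(m * m) - mu * mu, 0))
  s[s == 0] <- 1
  (m - mu) / s
}

#' @export
print.velocity_field <- function(x, ...) {
  n_ok <- sum(x$accepted)
  n_eval <- sum(!is.na(x$peak_z) | x$accepted)
  cat(sprintf(paste0("<velocity_field> epoch @ %g ms: %d/%d accepted, ",
                     "median %0.2f mm/s (v_max %g, z_thr %0.2f)\n"),
              x$epoch_start_ms, n_ok, n_eval,
              stats::median(x$speed, na.rm = TRUE), x$v_max, x$z_threshold))
  invisible(x)
}
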