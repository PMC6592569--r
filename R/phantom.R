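#' Specification of a single phantom vessel
#'
#' Describes one capillary tube for the synthetic flow phantom: its
#' centerline geometry and the statistical structure of the cell train
#' flowing through it. The nonzero coefficients of variation are essential:
#' the PIX algorithm relies on nuanced differences between members of the
#' passing cell train, and a degenerate train of identical, identically
#' spaced cells is expected to defeat it (a documented property of the
#' method, not a bug).
#'
#' @param centerline numeric matrix with >= 2 rows of (row, col) points in
#'   pixel units, ordered along the flow direction.
#' @param width_um tube width (um); default 8, a typical capillary lumen
#'   plus wall.
#' @param cell_mean_diam_um mean cell diameter (um); default 6 (human
#'   erythrocyte deformed in a capillary).
#' @param cell_diam_cv coefficient of variation of cell diameter
#'   (default 0.2).
#' @param cell_contrast mean fractional intensity dip of a cell against
#'   the plasma background (default 0.35, dark cells on bright plasma).
#' @param cell_contrast_cv coefficient of variation of cell contrast
#'   (default 0.3).
#' @param mean_gap_um mean plasma gap between consecutive cells (um);
#'   default 8.
#' @param gap_cv coefficient of variation of the gaps (default 0.4).
#' @return A `vessel_spec` object.
#' @export
vessel_spec <- function(centerline, width_um = 8, cell_mean_diam_um = 6,
                        cell_diam_cv = 0.2, cell_contrast = 0.35,
                        cell_contrast_cv = 0.3, mean_gap_um = 8,
                        gap_cv = 0.4) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L)
    stop_pixflow("centerline needs at least 2 points")
  if (width_um <= 0 || mean_gap_um <= 0 || cell_mean_diam_um <= 0)
    stop_pixflow("width, gap and cell diameter must be positive")
  if (cell_diam_cv < 0 || cell_contrast_cv < 0 || gap_cv < 0)
    stop_pixflow("coefficients of variation must be >= 0")
  structure(list(centerline = centerline, width_um = width_um,
                 cell_mean_diam_um = cell_mean_diam_um,
                 cell_diam_cv = cell_diam_cv,
                 cell_contrast = cell_contrast,
                 cell_contrast_cv = cell_contrast_cv,
                 mean_gap_um = mean_gap_um, gap_cv = gap_cv),
            class = "vessel_spec")
}

#' Pulsatile velocity waveform
#'
#' Single shared waveform per vessel (plug flow): a sinusoid around a mean
#' with optional transient dip emulating, e.g., the stall behind a passing
#' white blood cell.
#'
#' @param mean_velocity mean speed, mm/s (>= 0).
#' @param pulsatility_depth fractional modulation amplitude in `[0, 1)`;
#'   the programmed pulsatility index is `2 * depth`.
#' @param period_s cardiac period in seconds (default 1).
#' @param phase phase offset in radians.
#' @param transient optional `list(start_s=, duration_s=, depth=)` with
#'   depth in `[0, 1]`; velocity is multiplied by `1 - depth` inside the
#'   window.
#' @return A `waveform_spec` object.
#' @export
waveform_spec <- function(mean_velocity, pulsatility_depth = 0,
                          period_s = 1, phase = 0, transient = NULL) {
  if (mean_velocity < 0) stop_pixflow("mean_velocity must be >= 0")
  if (pulsatility_depth < 0 || pulsatility_depth >= 1)
    stop_pixflow("pulsatility_depth must lie in [0, 1)")
  if (period_s <= 0) stop_pixflow("period_s must be positive")
  structure(list(mean_velocity = mean_velocity,
                 pulsatility_depth = pulsatility_depth,
                 period_s = period_s, phase = phase, transient = transient),
            class = "waveform_spec")
}

#' Evaluate a waveform at given times
#' @param wf a [waveform_spec].
#' @param t_s numeric vector of times in seconds.
#' @return Speeds in mm/s.
#' @export
waveform_velocity <- function(wf, t_s) {
  v <- wf$mean_velocity *
    (1 + wf$pulsatility_depth * sin(2 * pi * t_s / wf$period_s + wf$phase))
  if (!is.null(wf$transient)) {
    tr <- wf$transient
    inside <- t_s >= tr$start_s & t_s < tr$start_s + tr$duration_s
    v[inside] <- v[inside] * (1 - tr$depth)
  }
  v
}

#' Rasterize a phantom vessel network
#'
#' Converts vessel specs into dense arc-length-parameterized centerline
#' samples plus per-vessel tube masks. Deterministic given the specs. Arc
#' length is the summed Euclidean step length along the polyline, in um.
#'
#' @param specs list of [vessel_spec] objects.
#' @param field_size integer `(rows, cols)` of the image field in pixels.
#' @param pixel_um pixel size, um/pixel (default 1).
#' @return A `phantom_geometry` list: per-vessel dense paths, arc lengths,
#'   tube masks, recorded junction points, and the union vessel mask.
#' @export
build_network <- function(specs, field_size, pixel_um = 1) {
  if (length(specs) == 0L) stop_pixflow("empty vessel spec list")
  field_size <- as.integer(field_size)
  vessels <- lapply(specs, function(sp) {
    cl <- sp$centerline
    steps <- sqrt(rowSums((cl[-1L, , drop = FALSE] -
                           cl[-nrow(cl), , drop = FALSE])^2))
    if (sum(steps) == 0) stop_pixflow("degenerate (zero-length) centerline")
    if (any(cl[, 1] < 1 | cl[, 1] > field_size[1] |
            cl[, 2] < 1 | cl[, 2] > field_size[2]))
      stop_pixflow("centerline points must lie inside the field")
    # densify at ~0.25 px resolution along the polyline
    s_nodes <- c(0, cumsum(steps))
    s_dense <- seq(0, s_nodes[length(s_nodes)], by = 0.25)
    path <- cbind(stats::approx(s_nodes, cl[, 1], s_dense)$y,
                  stats::approx(s_nodes, cl[, 2], s_dense)$y)
    mask <- tube_mask(path, sp$width_um / pixel_um / 2, field_size)
    list(spec = sp, path_px = path, s_um = s_dense * pixel_um,
         arc_length_um = s_nodes[length(s_nodes)] * pixel_um, mask = mask)
  })
  # endpoints shared by two or more vessels are junctions
  ends <- do.call(rbind, lapply(vessels, function(v) {
    cl <- v$spec$centerline
    rbind(cl[1L, ], cl[nrow(cl), ])
  }))
  junctions <- unique(ends[duplicated(ends), , drop = FALSE])
  union_mask <- Reduce(`|`, lapply(vessels, `[[`, "mask"))
  structure(list(vessels = vessels, field_size = field_size,
                 pixel_um = pixel_um, junctions = junctions,
                 mask = union_mask),
            class = "phantom_geometry")
}

# Binary tube: pixels within radius_px of the dense centerline path.
tube_mask <- function(path, radius_px, field_size) {
  mask <- matrix(FALSE, field_size[1], field_size[2])
  r <- ceiling(radius_px)
  for (k in seq_len(nrow(path))) {
    r0 <- max(1L, floor(path[k, 1] - r)); r1 <- min(field_size[1], ceiling(path[k, 1] + r))
    c0 <- max(1L, floor(path[k, 2] - r)); c1 <- min(field_size[2], ceiling(path[k, 2] + r))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - path[k, 1])^2, (cc - path[k, 2])^2, `+`)
    mask[rr, cc] <- mask[rr, cc] | (d2 <= radius_px^2)
  }
  mask
}

# Draw a positive quantity with given mean and cv (lognormal; constant at
# cv = 0).
rpos <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sl^2 / 2, sdlog = sl)
}

#' Simulate cell trains flowing through a phantom network
#'
#' Seeds a train of cells along (and upstream of) each vessel, with
#' diameters, contrasts and inter-cell gaps drawn once per cell from the
#' vessel spec's distributions, then advances every cell by
#' `v(t_mid) / fps` per frame (midpoint integration of the shared
#' waveform; plug flow, so cell order is preserved).
#'
#' @param geometry a `phantom_geometry` from [build_network()].
#' @param waveform a [waveform_spec], or a list of one per vessel.
#' @param duration_s sequence duration in seconds (>= 1/fps).
#' @param fps frame rate, frames/s.
#' @param seed integer RNG seed.
#' @return A `phantom_cells` list with per-vessel cell tables and
#'   per-frame arc-length positions (um).
#' @export
simulate_cells <- function(geometry, waveform, duration_s, fps, seed = 1L) {
  if (fps <= 0) stop_pixflow("fps must be positive")
  if (duration_s < 1 / fps) stop_pixflow("duration must cover >= 1 frame")
  nv <- length(geometry$vessels)
  wfs <- if (inherits(waveform, "waveform_spec")) rep(list(waveform), nv)
         else waveform
  if (length(wfs) != nv)
    stop_pixflow("need one waveform, or one per vessel")
  nf <- as.integer(round(duration_s * fps))
  t_mid <- (seq_len(nf) - 0.5) / fps
  set.seed(seed)
  vessels <- vector("list", nv)
  for (i in seq_len(nv)) {
    g <- geometry$vessels[[i]]
    sp <- g$spec
    v_mid <- waveform_velocity(wfs[[i]], t_mid)          # mm/s
    if (any(v_mid < 0))
      stop_pixflow("negative velocity attained (transient depth > 1?)")
    disp <- cumsum(v_mid * 1000 / fps)                   # um since frame 0
    total_disp <- disp[nf]
    span <- g$arc_length_um + total_disp + 6 * sp$cell_mean_diam_um
    n_guess <- ceiling(span / (sp$cell_mean_diam_um + sp$mean_gap_um)) + 8L
    diams <- rpos(n_guess, sp$cell_mean_diam_um, sp$cell_diam_cv)
    gaps <- rpos(n_guess, sp$mean_gap_um, sp$gap_cv)
    contrasts <- rpos(n_guess, sp$cell_contrast, sp$cell_contrast_cv)
    centres <- cumsum(diams + gaps)
    s0 <- centres - centres[1] - total_disp - 3 * sp$cell_mean_diam_um
    keep <- s0 + total_disp > -3 * sp$cell_mean_diam_um &
      s0 < g$arc_length_um + 3 * sp$cell_mean_diam_um
    cells <- data.frame(s0_um = s0[keep], diam_um = diams[keep],
                        contrast = contrasts[keep])
    pos <- outer(disp, cells$s0_um, `+`)                 # nf x ncells
    vessels[[i]] <- list(cells = cells, pos_um = pos, v_mid = v_mid)
  }
  structure(list(vessels = vessels, fps = fps, n_frames = nf,
                 t_mid_s = t_mid, waveforms = wfs, seed = seed),
            class = "phantom_cells")
}

#' Render a phantom image sequence with ground truth
#'
#' Produces the movie the rest of the pipeline consumes: bright plasma in
#' the tubes, dark Gaussian-profiled cells clipped to the tube, a smooth
#' static background texture (correlation length ~4 um, standing in for the
#' photoreceptor mosaic that preprocessing must remove), optional
#' multiplicative bleaching drift and additive photon noise. Ground-truth
#' per-epoch speed maps and per-vessel velocity traces are sampled from the
#' programmed waveform at epoch midpoints.
#'
#' @param cells a `phantom_cells` from [simulate_cells()].
#' @param geometry the matching `phantom_geometry`.
#' @param noise `list(background_texture_amplitude=, photon_noise_sd=,
#'   bleach_drift_per_s=)`; amplitudes are relative to the unit plasma
#'   intensity.
#' @param pixel_um pixel size (um/pixel).
#' @param seed RNG seed for texture and photon noise.
#' @param tube_brightness additive plasma brightness of the tube over the
#'   background (default 0.08).
#' @param epoch_ms,step_ms epoch grid used for the ground-truth maps and
#'   traces (defaults match [split_epochs()]).
#' @return A `phantom_truth` list: `sequence` ([image_sequence]),
#'   `truth_speed_maps` (per-epoch matrices, mm/s, NaN off-vessel),
#'   `truth_traces` (epochs x vessels matrix, mm/s), `epoch_start_ms`,
#'   `mask`, `seed`.
#' @export
render_sequence <- function(cells, geometry,
                            noise = list(background_texture_amplitude = 0.15,
                                         photon_noise_sd = 0.05,
                                         bleach_drift_per_s = 0),
                            pixel_um = geometry$pixel_um, seed = cells$seed,
                            tube_brightness = 0.08,
                            epoch_ms = 100, step_ms = 50) {
  fs <- geometry$field_size
  nf <- cells$n_frames
  fps <- cells$fps
  amp_bg <- noise$background_texture_amplitude %||% 0
  sd_phot <- noise$photon_noise_sd %||% 0
  bleach <- noise$bleach_drift_per_s %||% 0
  set.seed(seed)
  base <- matrix(1, fs[1], fs[2])
  if (amp_bg > 0) {
    tex <- gaussian_blur(matrix(stats::rnorm(prod(fs)), fs[1], fs[2]),
                         sigma = 4 / pixel_um / 2.355)
    base <- base + amp_bg * standardize_pop(tex)
  }
  base <- base + tube_brightness * geometry$mask
  frames <- array(0, c(fs[1], fs[2], nf))
  for (f in seq_len(nf)) {
    img <- base
    for (i in seq_along(geometry$vessels)) {
      g <- geometry$vessels[[i]]
      cl <- cells$vessels[[i]]
      if (nrow(cl$cells) == 0L) next
      pos <- cl$pos_um[f, ]
      vis <- which(pos > -3 * max(cl$cells$diam_um) &
                   pos < g$arc_length_um + 3 * max(cl$cells$diam_um))
      for (j in vis) {
        ctr <- path_point(g, pos[j])
        sig <- cl$cells$diam_um[j] / 2.355 / pixel_um
        img <- stamp_dip(img, ctr, sig, cl$cells$contrast[j], g$mask)
      }
    }
    if (bleach > 0) img <- img * exp(-bleach * (f - 1) / fps)
    frames[, , f] <- img
  }
  if (sd_phot > 0)
    frames <- frames + array(stats::rnorm(length(frames), sd = sd_phot),
                             dim(frames))
  frames[frames < 0] <- 0
  seqc <- image_sequence(frames, fps = fps, pixel_um = pixel_um)
  # ground truth on the epoch grid
  ne <- window_frames(epoch_ms, fps)
  st <- window_frames(step_ms, fps)
  starts <- if (nf >= ne) seq.int(1L, nf - ne + 1L, by = st) else integer(0)
  epoch_start_ms <- (starts - 1L) / fps * 1000
  t_mid <- (starts - 1L + ne / 2) / fps
  truth_traces <- if (length(starts) == 0L) {
    matrix(numeric(0), 0L, length(cells$waveforms))
  } else {
    matrix(vapply(cells$waveforms, waveform_velocity,
                  numeric(length(t_mid)), t_s = t_mid),
           nrow = length(starts))
  }
  truth_speed_maps <- lapply(seq_along(starts), function(e) {
    m <- matrix(NA_real_, fs[1], fs[2])
    for (i in seq_along(geometry$vessels))
      m[geometry$vessels[[i]]$mask] <- truth_traces[e, i]
    m
  })
  structure(list(sequence = seqc, truth_speed_maps = truth_speed_maps,
                 truth_traces = truth_traces,
                 epoch_start_ms = epoch_start_ms,
                 mask = geometry$mask, geometry = geometry, cells = cells,
                 seed = seed),
            class = "phantom_truth")
}

# Interpolate the (row, col) pixel position at arc length s_um.
path_point <- function(vessel, s_um) {
  s <- vessel$s_um
  if (s_um <= s[1]) {
    d <- vessel$path_px[2, ] - vessel$path_px[1, ]
    return(vessel$path_px[1, ] + d / sqrt(sum(d^2)) *
             (s_um - s[1]) / (s[2] - s[1]) * 0.25)
  }
  n <- length(s)
  if (s_um >= s[n]) {
    d <- vessel$path_px[n, ] - vessel$path_px[n - 1, ]
    return(vessel$path_px[n, ] + d / sqrt(sum(d^2)) *
             (s_um - s[n]) / (s[n] - s[n - 1]) * 0.25)
  }
  k <- findInterval(s_um, s)
  w <- (s_um - s[k]) / (s[k + 1] - s[k])
  vessel$path_px[k, ] * (1 - w) + vessel$path_px[k + 1, ] * w
}

# Subtract a Gaussian intensity dip at ctr (row, col), clipped to the tube.
stamp_dip <- function(img, ctr, sigma_px, contrast, tube) {
  r <- ceiling(3 * sigma_px)
  r0 <- max(1L, floor(ctr[1] - r)); r1 <- min(nrow(img), ceiling(ctr[1] + r))
  c0 <- max(1L, floor(ctr[2] - r)); c1 <- min(ncol(img), ceiling(ctr[2] + r))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`)
  dip <- contrast * exp(-d2 / (2 * sigma_px^2)) * tube[rr, cc, drop = FALSE]
  img[rr, cc] <- img[rr, cc] - dip
  img
}

#' One-call phantom generator
#'
#' Convenience wrapper chaining [build_network()], [simulate_cells()] and
#' [render_sequence()].
#'
#' @inheritParams build_network
#' @inheritParams simulate_cells
#' @inheritParams render_sequence
#' @return A `phantom_truth` (see [render_sequence()]).
#' @export
generate_phantom <- function(specs, field_size, waveform, duration_s,
                             fps = 300, pixel_um = 1,
                             noise = list(background_texture_amplitude = 0.15,
                                          photon_noise_sd = 0.05,
                                          bleach_drift_per_s = 0),
                             seed = 1L, epoch_ms = 100, step_ms = 50) {
  geom <- build_network(specs, field_size, pixel_um)
  cl <- simulate_cells(geom, waveform, duration_s, fps, seed = seed)
  render_sequence(cl, geom, noise = noise, pixel_um = pixel_um, seed = seed,
                  epoch_ms = epoch_ms, step_ms = step_ms)
}
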