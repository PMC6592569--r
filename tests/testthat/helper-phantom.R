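# Shared fixtures: small single-vessel phantoms plus the standard pipeline
# stages, cached so that multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A straight horizontal test vessel spanning 120 px at row 20.
straight_spec <- function(...) {
  vessel_spec(rbind(c(20, 10), c(20, 130)), ...)
}

# Phantom + preprocessing + segmentation + epochs for a constant or
# pulsatile single vessel.
phantom_pipeline <- function(speed_mm_s = 0.9, depth = 0, duration_s = 0.5,
                             seed = 42, spec = straight_spec(),
                             field = c(40, 140), fps = 300) {
  truth <- generate_phantom(list(spec), field,
                            waveform_spec(speed_mm_s,
                                          pulsatility_depth = depth),
                            duration_s = duration_s, fps = fps, seed = seed)
  filt <- preprocess_sequence(truth$sequence)
  seg <- segment_vessels(mc = motion_contrast(filt), pixel_um = 1)
  list(truth = truth, filtered = filt, seg = seg,
       epochs = split_epochs(filt))
}

std_phantom <- function() {
  cached("std_phantom", phantom_pipeline())
}

# A plain noise epoch (no flow) of the given size.
noise_epoch <- function(nr = 32, nc = 32, T = 30, seed = 1, fps = 300) {
  set.seed(seed)
  ep <- image_sequence(array(rnorm(nr * nc * T), c(nr, nc, T)),
                       fps = fps, pixel_um = 1)
  ep$start_ms <- 0
  class(ep) <- c("pix_epoch", class(ep))
  ep
}
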