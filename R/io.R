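# Minimal multi-page TIFF I/O (uncompressed grayscale), plus sidecar
# metadata and rendered-map writers. No TIFF package exists in the target
# R stack, so the codec is implemented here; it covers exactly the subset
# the pipeline needs: little-endian, single-sample, strip-based, no
# compression, 8/16-bit unsigned or 32-bit float.

#' Write an image sequence as a multi-page TIFF
#'
#' Frames are stored as uncompressed 32-bit float grayscale pages. Use
#' [write_sidecar()] to record the temporal/spatial calibration alongside.
#'
#' @param seq an [image_sequence] (or a plain matrix for a single page).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_tiff <- function(seq, path) {
  frames <- if (inherits(seq, "image_sequence")) seq$frames
            else array(seq, c(nrow(seq), ncol(seq), 1L))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w(42L, 2)
  nr <- dim(frames)[1]; nc <- dim(frames)[2]; nf <- dim(frames)[3]
  strip_bytes <- nr * nc * 4L
  n_tags <- 10L
  ifd_bytes <- 2L + 12L * n_tags + 4L
  # layout: header(8) then per page [strip][ifd]
  offs_strip <- 8L + (seq_len(nf) - 1L) * (strip_bytes + ifd_bytes)
  offs_ifd <- offs_strip + strip_bytes
  w(offs_ifd[1], 4)
  tag <- function(id, type, count, value) {
    w(id, 2); w(type, 2); w(count, 4)
    if (type == 3L) { w(value, 2); w(0L, 2) } else w(value, 4)
  }
  for (f in seq_len(nf)) {
    writeBin(as.numeric(t(frames[, , f])), con, size = 4,
             endian = "little")
    w(n_tags, 2)
    tag(256L, 4L, 1L, nc)                 # ImageWidth
    tag(257L, 4L, 1L, nr)                 # ImageLength
    tag(258L, 3L, 1L, 32L)                # BitsPerSample
    tag(259L, 3L, 1L, 1L)                 # Compression = none
    tag(262L, 3L, 1L, 1L)                 # Photometric = BlackIsZero
    tag(273L, 4L, 1L, offs_strip[f])      # StripOffsets
    tag(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    tag(278L, 4L, 1L, nr)                 # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)        # StripByteCounts
    tag(339L, 3L, 1L, 3L)                 # SampleFormat = IEEE float
    w(if (f < nf) offs_ifd[f + 1L] else 0L, 4)
  }
  invisible(path)
}

#' Read a multi-page TIFF into an image sequence
#'
#' Supports the uncompressed grayscale subset written by
#' [write_sequence_tiff()] (plus 8/16-bit unsigned pages). Calibration is
#' taken from the arguments or from a sidecar JSON (see
#' [read_sidecar()]).
#'
#' @param path TIFF file path.
#' @param fps,pixel_um calibration; when NULL, a sidecar `<path>.json` is
#'   consulted.
#' @return An [image_sequence].
#' @export
read_sequence_tiff <- function(path, fps = NULL, pixel_um = NULL) {
  if (is.null(fps) || is.null(pixel_um)) {
    sc <- read_sidecar(paste0(path, ".json"))
    fps <- fps %||% sc$fps
    pixel_um <- pixel_um %||% sc$pixel_um
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(o) as.integer(raw[o + 1]) + 256L * as.integer(raw[o + 2])
  u32 <- function(o) sum(as.numeric(raw[o + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop_pixflow("not a little-endian TIFF")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      o <- ifd + 2L + (k - 1L) * 12L
      id <- u16(o); type <- u16(o + 2L); count <- u32(o + 4L)
      val <- if (type == 3L) u16(o + 8L) else u32(o + 8L)
      if (count > 1L) {
        # array values live at an offset
        off <- u32(o + 8L)
        sz <- if (type == 3L) 2L else 4L
        val <- vapply(seq_len(count), function(i)
          if (type == 3L) u16(off + (i - 1L) * sz)
          else u32(off + (i - 1L) * sz), 0)
      }
      tags[[as.character(id)]] <- val
    }
    if ((tags[["259"]] %||% 1) != 1)
      stop_pixflow("compressed TIFF not supported")
    nc <- tags[["256"]]; nr <- tags[["257"]]
    bits <- tags[["258"]] %||% 8
    fmt <- tags[["339"]] %||% 1
    offs <- tags[["273"]]
    counts <- tags[["279"]] %||% (nr * nc * bits / 8)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + counts[s])])
    vals <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = nr * nc, size = 4, endian = "little")
    } else if (bits == 8) {
      as.numeric(buf)
    } else if (bits == 16) {
      readBin(buf, "integer", n = nr * nc, size = 2, signed = FALSE,
              endian = "little")
    } else stop_pixflow("unsupported TIFF sample layout")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nc, nr))  # row-major data
    ifd <- u32(ifd + 2L + n * 12L)
  }
  frames <- array(unlist(pages), c(nrow(pages[[1]]), ncol(pages[[1]]),
                                   length(pages)))
  if (length(pages) >= 2L)
    return(image_sequence(frames, fps = fps, pixel_um = pixel_um))
  # single-page images (masks, label maps) bypass the >= 2 frame invariant
  structure(list(frames = frames, fps = fps, pixel_um = pixel_um),
            class = "image_sequence")
}

#' Sidecar calibration metadata
#'
#' JSON files recording `fps`, `pixel_um`, and optionally a seed and free
#' parameters, written next to image files.
#'
#' @param meta named list to store.
#' @param path file path (conventionally `<image>.json`).
#' @return `path` invisibly / the parsed list.
#' @export
write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop_pixflow("sidecar not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render a velocity map to PNG
#'
#' Fixed perceptually uniform color scale from 0 to `v_max`, NaN (rejected)
#' rendered black.
#'
#' @param field a `velocity_field` (or plain numeric matrix).
#' @param path output PNG path.
#' @param v_max top of the color scale (default: the field's cap).
#' @return `path`, invisibly.
#' @export
write_velocity_png <- function(field, path, v_max = NULL) {
  sp <- if (inherits(field, "velocity_field")) field$speed else field
  v_max <- v_max %||% (if (inherits(field, "velocity_field")) field$v_max
                       else max(sp, na.rm = TRUE))
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmax(1L, pmin(256L, 1L + floor(sp / v_max * 255)))
  cols <- matrix("#000000", nrow(sp), ncol(sp))
  ok <- !is.na(sp)
  cols[ok] <- pal[idx[ok]]
  grDevices::png(path, width = ncol(sp), height = nrow(sp))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(cols), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Write per-segment velocity traces as CSV
#'
#' Long format: `epoch_start_ms, segment_id, speed_mm_s`.
#'
#' @param traces a `segment_traces` (or the phantom truth equivalent).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  sp <- traces$speed
  df <- data.frame(
    epoch_start_ms = rep(traces$epoch_start_ms, ncol(sp)),
    segment_id = rep(seq_len(ncol(sp)), each = nrow(sp)),
    speed_mm_s = as.vector(sp))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
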