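#' Single-scale vesselness (tube-enhancement) filter
#'
#' Hessian-eigenvalue tube enhancement in the style of Frangi et al.,
#' evaluated at the single Gaussian scale `sigma = scale_um / pixel_um`,
#' with bright-tube polarity (tubes brighter than background, as in a
#' motion-contrast image). The scale defaults to 5 um, on the order of a
#' capillary diameter. `beta` (blob suppression) and `c_frac` (structure
#' sensitivity, as a fraction of the maximum Hessian norm) are the usual
#' defaults; only the scale is physiologically meaningful.
#'
#' @param mc nonnegative image (typically a motion-contrast image).
#' @param pixel_um pixel size, um/pixel.
#' @param scale_um Gaussian scale in um (default 5).
#' @param beta Frangi blob-suppression parameter (default 0.5).
#' @param c_frac structure-sensitivity constant as a fraction of the
#'   maximum Hessian norm (default 0.5).
#' @return Nonnegative vesselness image, zero where the local structure is
#'   not tube-like.
#' @export
vesselness_filter <- function(mc, pixel_um, scale_um = 5, beta = 0.5,
                              c_frac = 0.5) {
  if (any(mc < 0)) stop_pixflow("motion-contrast input must be nonnegative")
  sigma <- scale_um / pixel_um
  if (sigma < 1) stop_pixflow("vesselness scale smaller than one pixel")
  g <- gaussian_blur(mc, sigma)
  # scale-normalized Hessian by central differences, replicate edges so
  # the image border does not register as a spurious high-contrast ridge
  sr <- function(dr, dc) shift_replicate(g, dr, dc)
  hxx <- (sr(-1, 0) + sr(1, 0) - 2 * g) * sigma^2
  hyy <- (sr(0, -1) + sr(0, 1) - 2 * g) * sigma^2
  hxy <- (sr(-1, -1) + sr(1, 1) - sr(-1, 1) - sr(1, -1)) / 4 * sigma^2
  tmp <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
  l1 <- (hxx + hyy + tmp) / 2
  l2 <- (hxx + hyy - tmp) / 2
  # order |lam1| <= |lam2|
  swap <- abs(l1) > abs(l2)
  lam1 <- ifelse(swap, l2, l1)
  lam2 <- ifelse(swap, l1, l2)
  S2 <- lam1^2 + lam2^2
  c2 <- (c_frac * sqrt(max(S2)))^2
  if (c2 == 0) return(matrix(0, nrow(mc), ncol(mc)))
  Rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
  v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
  v[lam2 >= 0] <- 0          # bright tubes have lam2 < 0
  v
}

#' Otsu threshold binarization
#'
#' Thresholds an image by maximizing the between-class variance of its
#' 256-bin histogram; the mask contains pixels strictly above the
#' threshold. A constant image is degenerate: an empty mask is returned
#' with a warning.
#'
#' @param img numeric image.
#' @param n_bins number of histogram bins (default 256).
#' @return Logical mask; the chosen threshold is attached as attribute
#'   `"threshold"`.
#' @export
otsu_binarize <- function(img, n_bins = 256) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    warning("constant image: returning empty mask")
    out <- matrix(FALSE, nrow(img), ncol(img))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(img, edges, rightmost.closed = TRUE),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b2[!is.finite(sigma_b2)] <- -Inf
  k <- which.max(sigma_b2)
  thr <- edges[k + 1L]
  out <- img > thr
  attr(out, "threshold") <- thr
  out
}

# Guo-Hall thinning of a binary matrix (vectorized over pixels). Chosen
# over Zhang-Suen because it does not leave two-pixel diagonal staircases,
# which would later be shredded by branch-point removal.
guo_hall_thin <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      x1 <- shift_mat(m, 1, 0); x2 <- shift_mat(m, 1, -1)
      x3 <- shift_mat(m, 0, -1); x4 <- shift_mat(m, -1, -1)
      x5 <- shift_mat(m, -1, 0); x6 <- shift_mat(m, -1, 1)
      x7 <- shift_mat(m, 0, 1); x8 <- shift_mat(m, 1, 1)
      C <- ((x1 == 0) & (x2 == 1 | x3 == 1)) +
           ((x3 == 0) & (x4 == 1 | x5 == 1)) +
           ((x5 == 0) & (x6 == 1 | x7 == 1)) +
           ((x7 == 0) & (x8 == 1 | x1 == 1))
      N1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
      N2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
      N <- pmin(N1, N2)
      if (sub == 1) {
        msk <- ((x5 == 1 | x6 == 1 | x8 == 0) & x7 == 1)   # (S|SW|!NW) & W
      } else {
        msk <- ((x1 == 1 | x2 == 1 | x4 == 0) & x3 == 1)   # (N|NE|!SE) & E
      }
      del <- m == 1L & C == 1 & N >= 2 & N <= 3 & !msk
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-connectivity neighbour count for each pixel of a binary matrix.
neighbour_count <- function(m) {
  mi <- m * 1L
  shift_mat(mi, 1, 0) + shift_mat(mi, -1, 0) + shift_mat(mi, 0, 1) +
    shift_mat(mi, 0, -1) + shift_mat(mi, 1, 1) + shift_mat(mi, 1, -1) +
    shift_mat(mi, -1, 1) + shift_mat(mi, -1, -1)
}

# Connected components (8-connectivity) of a binary matrix via igraph.
# Returns an integer matrix of component labels (0 = background).
connected_components8 <- function(m) {
  idx <- which(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(m)
  rc <- idx_to_rc(idx, nr)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb_r <- rc[, 1] + off[1]; nb_c <- rc[, 2] + off[2]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= ncol(m)
    nb <- rc_to_idx(nb_r[ok], nb_c[ok], nr)
    here <- idx[ok]
    inmask <- m[nb]
    edges <- rbind(edges, cbind(here[inmask], nb[inmask]))
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges %||% matrix(integer(0), 0, 2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership[as.character(idx)]
  lab
}

# Metric length of a set of skeleton pixels: sum of inter-pixel steps
# (1 axial, sqrt(2) diagonal) over 8-adjacent pairs, times pixel_um.
skeleton_length_um <- function(idx, nr, nc, pixel_um) {
  if (length(idx) < 2L) return(0)
  present <- logical(nr * nc)
  present[idx] <- TRUE
  rc <- idx_to_rc(idx, nr)
  len <- 0
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb_r <- rc[, 1] + off[1]; nb_c <- rc[, 2] + off[2]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    nb <- rc_to_idx(nb_r[ok], nb_c[ok], nr)
    hit <- present[nb]
    step <- if (all(off != 0L)) sqrt(2) else 1
    len <- len + sum(hit) * step
  }
  len * pixel_um
}

#' Skeletonize a vessel mask into branch-free segments
#'
#' Morphological (Guo-Hall) thinning, followed by removal of branch
#' points (skeleton pixels with more than 2 neighbours in 8-connectivity)
#' and rejection of remaining pieces shorter than `min_length_um`. Piece
#' length is the summed inter-pixel step length (1 for axial, sqrt(2) for
#' diagonal steps, times `pixel_um`).
#'
#' @param mask logical vessel mask.
#' @param pixel_um pixel size, um/pixel.
#' @param min_length_um minimum retained segment length (default 25 um).
#' @return Logical skeleton matrix; attribute `"piece_labels"` holds the
#'   integer component labelling of the retained pieces.
#' @export
skeletonize_segments <- function(mask, pixel_um, min_length_um = 25) {
  skel <- guo_hall_thin(mask)
  skel[skel & neighbour_count(skel) > 2] <- FALSE
  lab <- connected_components8(skel)
  nr <- nrow(mask); nc <- ncol(mask)
  keep <- matrix(FALSE, nr, nc)
  labs_out <- matrix(0L, nr, nc)
  nxt <- 0L
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (skeleton_length_um(idx, nr, nc, pixel_um) >= min_length_um) {
      nxt <- nxt + 1L
      keep[idx] <- TRUE
      labs_out[idx] <- nxt
    }
  }
  attr(keep, "piece_labels") <- labs_out
  keep
}

#' Label vessel segments by skeleton re-dilation
#'
#' Each retained skeleton piece is dilated by a disk of radius
#' `dilate_um` so that the full vessel thickness can carry the piece's
#' label. Pixels claimed by two or more pieces are removed from all labels,
#' and skeleton pixels within `dilate_um` of such contested pixels are
#' deleted; segment lengths are then recomputed from the surviving
#' skeleton. Label supports are disjoint by construction (asserted).
#'
#' @param skeleton output of [skeletonize_segments()].
#' @param mask the binary vessel mask the skeleton came from.
#' @param pixel_um pixel size, um/pixel.
#' @param dilate_um dilation radius in um (default 5; the radius reading of
#'   the segment-width parameter, giving labels about one capillary
#'   diameter plus wall wide).
#' @return A `vessel_segmentation` list: `mask`, `skeleton`, `labels`
#'   (integer matrix, 0 = background), `skeleton_labels`,
#'   `segment_lengths_um` (named by label), `pixel_um`.
#' @export
label_segments <- function(skeleton, mask, pixel_um, dilate_um = 5) {
  piece_labels <- attr(skeleton, "piece_labels")
  if (is.null(piece_labels))
    stop_pixflow("skeleton must come from skeletonize_segments()")
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  r_px <- dilate_um / pixel_um
  nlab <- max(piece_labels)
  dils <- vector("list", nlab)
  claims <- matrix(0L, nr, nc)
  for (k in seq_len(nlab)) {
    dils[[k]] <- dilate_disk(piece_labels == k, r_px)
    claims <- claims + dils[[k]]
  }
  overlap <- claims >= 2L
  skel_out <- skeleton & !dilate_disk(overlap, r_px)
  labels <- matrix(0L, nr, nc)
  skeleton_labels <- matrix(0L, nr, nc)
  lengths_um <- numeric(0)
  out_k <- 0L
  for (k in seq_len(nlab)) {
    support <- dils[[k]] & !overlap
    skel_k <- which(piece_labels == k & skel_out)
    len <- skeleton_length_um(skel_k, nr, nc, pixel_um)
    if (length(skel_k) == 0L || !any(support)) next
    out_k <- out_k + 1L
    stopifnot(all(labels[support] == 0L))   # label supports stay disjoint
    labels[support] <- out_k
    skeleton_labels[skel_k] <- out_k
    lengths_um[out_k] <- len
  }
  names(lengths_um) <- seq_len(out_k)
  structure(list(mask = mask, skeleton = skeleton_labels > 0L,
                 labels = labels, skeleton_labels = skeleton_labels,
                 segment_lengths_um = lengths_um,
                 pixel_um = pixel_um),
            class = "vessel_segmentation")
}

#' Full vessel segmentation pipeline
#'
#' Motion contrast -> vesselness -> Otsu mask -> skeleton -> labelled
#' segments. A precomputed binary mask may be supplied instead, in which
#' case the vesselness/threshold steps are skipped.
#'
#' @param mc motion-contrast image (ignored when `mask` is given).
#' @param pixel_um pixel size, um/pixel.
#' @param mask optional precomputed logical vessel mask.
#' @param scale_um vesselness scale (default 5 um).
#' @param min_length_um minimum segment length (default 25 um).
#' @param dilate_um label dilation radius (default 5 um).
#' @return A `vessel_segmentation` (see [label_segments()]).
#' @export
segment_vessels <- function(mc = NULL, pixel_um, mask = NULL, scale_um = 5,
                            min_length_um = 25, dilate_um = 5) {
  if (is.null(mask)) {
    if (is.null(mc)) stop_pixflow("need a motion-contrast image or a mask")
    v <- vesselness_filter(mc, pixel_um, scale_um = scale_um)
    mask <- otsu_binarize(v)
  }
  skel <- skeletonize_segments(mask, pixel_um, min_length_um = min_length_um)
  label_segments(skel, mask, pixel_um, dilate_um = dilate_um)
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("<vessel_segmentation> %d segments, %d mask px, %g um/px\n",
              length(x$segment_lengths_um), sum(x$mask), x$pixel_um))
  invisible(x)
}

#' Ordered skeleton path of one segment
#'
#' Walks the (branch-free) skeleton of a labelled segment from one endpoint
#' to the other, returning pixel coordinates and cumulative arc length.
#' Used by the spatiotemporal-kymograph baseline.
#'
#' @param seg a `vessel_segmentation`.
#' @param label segment label.
#' @return List with `rc` (n x 2 matrix of row, col) and `s_um`
#'   (cumulative arc length, um).
#' @export
segment_path <- function(seg, label) {
  idx <- which(seg$skeleton_labels == label)
  if (length(idx) < 2L) stop_pixflow("segment skeleton too short to order")
  nr <- nrow(seg$labels)
  rc <- idx_to_rc(idx, nr)
  n <- length(idx)
  # adjacency among the segment's own pixels
  adj <- vector("list", n)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(idx[i]), i, envir = lookup)
  deg <- integer(n)
  for (i in seq_len(n)) {
    nbrs <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- rc[i, 1] + dr; c <- rc[i, 2] + dc
      if (r < 1 || r > nr || c < 1 || c > ncol(seg$labels)) next
      j <- mget(as.character(rc_to_idx(r, c, nr)), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) nbrs <- c(nbrs, j)
    }
    adj[[i]] <- nbrs
    deg[i] <- length(nbrs)
  }
  start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
  order_ <- integer(n)
  visited <- logical(n)
  cur <- start
  for (k in seq_len(n)) {
    order_[k] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0L) { order_ <- order_[1:k]; break }
    cur <- nxt[1]
  }
  rc_o <- rc[order_, , drop = FALSE]
  steps <- sqrt(rowSums((rc_o[-1, , drop = FALSE] -
                         rc_o[-nrow(rc_o), , drop = FALSE])^2))
  list(rc = rc_o, s_um = c(0, cumsum(steps)) * seg$pixel_um)
}
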