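# Small internal helpers shared across modules. All images are numeric
# matrices indexed [row, col]; stacks are arrays [row, col, time].

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r_src) < 1L || length(c_src) < 1L) return(out)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# Shift with replicate (clamped) edge handling: out[r, c] = m[r - dr, c - dc].
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) - dr, 1L), nr),
    pmin(pmax(seq_len(nc) - dc, 1L), nc)]
}

# Integer offsets of a disk of radius r (pixels), centre included.
disk_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Binary dilation by a disk of radius r pixels.
dilate_disk <- function(mask, r) {
  offs <- disk_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, offs$dr[k], offs$dc[k], fill = FALSE)
  }
  out
}

# Separable Gaussian smoothing with replicate padding.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  img <- apply(img, 2, conv1_replicate, k = k)            # along rows
  t(apply(t(img), 2, conv1_replicate, k = k))             # along cols
}

conv1_replicate <- function(x, k) {
  rad <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1L], rad), x, rep(x[length(x)], rad))
  as.numeric(stats::filter(xp, k, sides = 2L))[(rad + 1L):(rad + length(x))]
}

# Column-major linear index <-> (row, col) for an nr x nc matrix.
idx_to_rc <- function(idx, nr) {
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

rc_to_idx <- function(row, col, nr) {
  (col - 1L) * nr + row
}

# Population (divide-by-N) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Standardize to zero mean, unit population variance.
standardize_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pixflow <- function(...) stop(..., call. = FALSE)
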