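# Internal raster helpers shared by the generator and the analysis code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer (dr, dc) offsets of a disc of radius r around the origin
disc_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# stamp TRUE into `mask` at disc neighbourhoods of the given centres
# (rows, cols, 1-based); out-of-frame pixels are dropped.
stamp_discs <- function(mask, rows, cols, radius) {
  off <- disc_offsets(radius)
  H <- nrow(mask); W <- ncol(mask)
  for (k in seq_len(nrow(off))) {
    rr <- rows + off$dr[k]; cc <- cols + off$dc[k]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    if (any(ok)) mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

# Otsu threshold on a numeric raster (256-bin histogram over the data range)
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(findInterval(x, seq(rng[1], rng[2], length.out = 257),
                             rightmost.closed = TRUE, all.inside = TRUE), 256)
  mids <- seq(rng[1], rng[2], length.out = 257)
  mids <- (mids[-1] + mids[-257]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  wb <- w[-256]; wf <- w[256] - wb
  mb <- m[-256] / wb; mf <- (m[256] - m[-256]) / wf
  between <- wb * wf * (mb - mf)^2
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Crofton perimeter estimate (4 directions) from the 2x2 configuration
# histogram of the zero-padded mask; unbiased for isotropic boundaries.
crofton_perimeter <- function(mask) {
  h <- .config_hist2x2(mask)
  isq2 <- 1 / sqrt(2)
  coefs <- c(0, pi / 4 * (1 + isq2), pi / (4 * sqrt(2)), pi / (2 * sqrt(2)), 0,
             pi / 4 * (1 + isq2), 0, pi / (4 * sqrt(2)), pi / 4, pi / 2,
             pi / (4 * sqrt(2)), pi / (4 * sqrt(2)), pi / 4, pi / 2, 0, 0)
  sum(h * coefs)
}

# area of the convex hull of the pixel corner points of a mask (>= mask area)
hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  pts <- rbind(
    cbind(idx[, 1] - 0.5, idx[, 2] - 0.5), cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] - 0.5), cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(pts)
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# centroid-rows, centroid-cols, areas for labels 1..max(labels)
label_stats <- function(labels) {
  n <- max(labels, 0L)
  if (n == 0L) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[labels > 0L]
  area <- tabulate(lb, n)
  data.frame(
    label = seq_len(n),
    area_px = area,
    centroid_row = as.numeric(rowsum(idx[, 1], lb, reorder = TRUE)) / area,
    centroid_col = as.numeric(rowsum(idx[, 2], lb, reorder = TRUE)) / area)
}

as_mask <- function(x) {
  if (is.logical(x)) {
    m <- x
  } else {
    m <- x > 0
  }
  m[is.na(m)] <- FALSE
  storage.mode(m) <- "logical"
  m
}

check_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix raster")
  invisible(x)
}
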