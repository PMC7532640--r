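# Internal numerical helpers shared across feature modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Pad a matrix by `k` pixels on each side, replicating the border rows/cols.
pad_replicate <- function(x, k) {
  m <- nrow(x); n <- ncol(x)
  ri <- c(rep(1L, k), seq_len(m), rep(m, k))
  ci <- c(rep(1L, k), seq_len(n), rep(n, k))
  x[ri, ci, drop = FALSE]
}

#' Sobel image gradient
#'
#' Horizontal and vertical derivatives with the standard 3x3 Sobel kernels.
#' `dx` is the derivative along columns (the lateral, skin-parallel axis),
#' `dy` along rows (the beam/depth axis). Border pixels use replicate
#' padding, so a constant image has zero gradient everywhere.
#'
#' @param img numeric matrix of intensities.
#' @return list with matrices `dx`, `dy` and `magnitude` = sqrt(dx^2 + dy^2).
#' @export
sobel_gradient <- function(img) {
  stopifnot(is.matrix(img))
  m <- nrow(img); n <- ncol(img)
  p <- pad_replicate(img, 1L)
  i <- 2:(m + 1); j <- 2:(n + 1)
  dx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  dy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  list(dx = dx, dy = dy, magnitude = sqrt(dx^2 + dy^2))
}

# Separable Gaussian blur with replicate padding; sigma in pixels,
# kernel truncated at 3 sigma. sigma = 0 returns the input unchanged.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-k):k)^2 / (2 * sigma^2))
  w <- w / sum(w)
  m <- nrow(img); n <- ncol(img)
  p <- pad_replicate(img, k)
  out <- matrix(0, m, n + 2L * k)
  for (d in -k:k) out <- out + w[d + k + 1L] * p[(1 + k + d):(m + k + d), ]
  res <- matrix(0, m, n)
  for (d in -k:k) res <- res + w[d + k + 1L] * out[, (1 + k + d):(n + k + d)]
  res
}

# Neighbour offsets for a connectivity (4 or 8).
conn_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  }
}

# Label connected foreground components by vectorised frontier expansion.
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  m <- nrow(mask); n <- ncol(mask)
  # pad with a background ring so neighbour indexing never leaves bounds
  pm <- matrix(FALSE, m + 2L, n + 2L)
  pm[2:(m + 1), 2:(n + 1)] <- mask
  M <- m + 2L
  off <- conn_offsets(connectivity)
  doff <- off[, 1L] + off[, 2L] * M
  lab <- integer(length(pm))
  todo <- which(pm)
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, doff, `+`)))
      nb <- nb[pm[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  matrix(lab, M, n + 2L)[2:(m + 1), 2:(n + 1)]
}

# Number of connected foreground components.
n_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}

# Euclidean disc offsets of a given pixel radius.
disc_offsets <- function(radius) {
  o <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  o[o$dr^2 + o$dc^2 <= radius^2, ]
}

# Binary dilation by a Euclidean disc; pixels beyond the border are background.
binary_dilate <- function(mask, radius) {
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(FALSE, m, n)
  o <- disc_offsets(radius)
  for (k in seq_len(nrow(o))) {
    dr <- o$dr[k]; dc <- o$dc[k]
    sr <- max(1, 1 - dr):min(m, m - dr)
    sc <- max(1, 1 - dc):min(n, n - dc)
    out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
  }
  out
}

# Binary erosion by a Euclidean disc (dual of dilation; border is background).
binary_erode <- function(mask, radius) {
  m <- nrow(mask); n <- ncol(mask)
  out <- matrix(TRUE, m, n)
  o <- disc_offsets(radius)
  for (k in seq_len(nrow(o))) {
    dr <- o$dr[k]; dc <- o$dc[k]
    shifted <- matrix(FALSE, m, n)
    sr <- max(1, 1 - dr):min(m, m - dr)
    sc <- max(1, 1 - dc):min(n, n - dc)
    shifted[sr + dr, sc + dc] <- mask[sr, sc]
    out <- out & shifted
  }
  out
}

# Cyclic median filter: window must be odd; the sequence is treated as closed.
cyclic_median <- function(x, window) {
  stopifnot(window %% 2 == 1, length(x) >= window)
  n <- length(x)
  w <- (window - 1L) / 2L
  xp <- c(x[(n - w + 1L):n], x, x[1:w])
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + 2L * w)]), numeric(1))
}

# Fit a least-squares polynomial of `degree` in normalised position t = i/N,
# on the sequence cyclically padded by `pad` samples on each side (the
# boundary is closed; padding keeps the fit's endpoint error outside the
# evaluated range). Uses an orthogonal polynomial basis for conditioning;
# returns the fitted values at the N in-range sample positions.
fit_cyclic_polynomial <- function(y, degree, pad) {
  n <- length(y)
  yp <- if (pad > 0) c(y[(n - pad + 1L):n], y, y[1:pad]) else y
  tt <- ((-pad):(n + pad - 1L)) / n
  X <- cbind(1, stats::poly(tt, degree))
  fit <- stats::lm.fit(X, yp)
  stats::fitted.values(fit)[(pad + 1L):(pad + n)]
}

# Count strict local extrema of a closed (cyclic) sequence, merging plateaus,
# then prune oscillations whose swing is below `prominence` by repeatedly
# collapsing the smallest adjacent max/min pair (hysteresis counting).
count_cyclic_extrema <- function(f, prominence = 0) {
  n <- length(f)
  if (n < 3 || max(f) - min(f) <= prominence) return(0L)
  # collapse plateaus: keep one representative per run of equal values
  keep <- c(TRUE, diff(f) != 0)
  g <- f[keep]
  m <- length(g)
  if (m < 3) return(0L)
  gc <- c(g[m], g, g[1])
  is_max <- gc[2:(m + 1)] > gc[1:m] & gc[2:(m + 1)] > gc[3:(m + 2)]
  is_min <- gc[2:(m + 1)] < gc[1:m] & gc[2:(m + 1)] < gc[3:(m + 2)]
  idx <- which(is_max | is_min)
  if (length(idx) < 2) return(length(idx))
  v <- g[idx]
  k <- length(v)
  repeat {
    if (k <= 2) break
    swings <- abs(v - c(v[-1], v[1]))
    j <- which.min(swings)
    if (swings[j] >= prominence) break
    drop <- c(j, if (j < k) j + 1L else 1L)
    v <- v[-drop]
    k <- length(v)
  }
  if (k == 2 && abs(v[1] - v[2]) < prominence) return(0L)
  as.integer(k)
}
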