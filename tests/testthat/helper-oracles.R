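# Independent brute-force oracles. These deliberately share no code with the
# package internals: slow loops, textbook formulas, different algorithms.

# Crossing-number point-in-polygon test (strict interior).
oracle_point_in_polygon <- function(poly, pr, pc) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    if ((yi > pr) != (yj > pr)) {
      xint <- xi + (pr - yi) / (yj - yi) * (xj - xi)
      if (pc < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Foreground pixels with at least one background 4-neighbour.
oracle_inner_boundary <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  pm <- matrix(FALSE, m + 2, n + 2)
  pm[2:(m + 1), 2:(n + 1)] <- mask
  bf <- (!pm[1:m, 2:(n + 1)] | !pm[3:(m + 2), 2:(n + 1)] |
         !pm[2:(m + 1), 1:n] | !pm[2:(m + 1), 3:(n + 2)]) & mask
  which(bf)
}

# O(N^2) direct-summation DFT magnitudes.
oracle_dft_mod <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))
  }, numeric(1))
}

# Spicule ratio computed entirely from the direct DFT.
oracle_spicules <- function(r) {
  n <- length(r)
  R <- oracle_dft_mod(r)
  k <- 0:(n %/% 2)
  w <- 2 * pi * k / n
  num <- sum(R[k[w <= pi / 4] + 1])
  den <- sum(R[k[w > pi / 4 & w <= pi] + 1])
  if (den < 1e-9 * num) return(Inf)
  num / den
}

# Cyclic mean absolute successive difference, as an explicit loop.
oracle_coarseness <- function(r) {
  n <- length(r)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + abs(r[i] - r[j])
  }
  s / n
}

# Double-loop Sobel with replicate padding; returns the magnitude image.
oracle_sobel_magnitude <- function(img) {
  m <- nrow(img); n <- ncol(img)
  at <- function(i, j) img[min(max(i, 1), m), min(max(j, 1), n)]
  out <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      dx <- (at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
            (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))
      dy <- (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1)) -
            (at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1))
      out[i, j] <- sqrt(dx^2 + dy^2)
    }
  }
  out
}

# GLGCM tallied pixel by pixel with loops, fixed [0,255] grey quantization.
oracle_glgcm_counts <- function(image, mask, L_s, L_g) {
  grad <- oracle_sobel_magnitude(image)
  gmax <- max(grad[mask])
  H <- matrix(0L, L_s, L_g)
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      if (!mask[i, j]) next
      gi <- min(L_s, floor(image[i, j] * L_s / 256) + 1)
      gj <- if (gmax <= 0) 1 else max(1, min(L_g, ceiling(grad[i, j] / gmax * L_g)))
      H[gi, gj] <- H[gi, gj] + 1L
    }
  }
  H
}

oracle_energy <- function(P) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) s <- s + P[i, j]^2
  s
}

oracle_entropy <- function(P) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    q <- sum(P[i, ])
    if (q > 0) s <- s - q * log(q)
  }
  s
}

oracle_grey_mean <- function(P) {
  L_s <- nrow(P)
  s <- 0
  for (i in seq_len(L_s)) s <- s + (i - 1) / (L_s - 1) * sum(P[i, ])
  s
}

# Union-find connected-component count (8- or 4-connectivity).
oracle_component_count <- function(mask, connectivity = 8) {
  m <- nrow(mask); n <- ncol(mask)
  parent <- seq_len(m * n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(0, -1), c(-1, -1), c(-1, 1))
  } else {
    list(c(-1, 0), c(0, -1))
  }
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      if (!mask[i, j]) next
      for (d in offs) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= m && jj >= 1 && jj <= n && mask[ii, jj]) {
          union((j - 1) * m + i, (jj - 1) * m + ii)
        }
      }
    }
  }
  length(unique(vapply(which(mask), find, integer(1))))
}

# Independent calcification counter: zero outside mask, threshold at
# mu + alpha (max - mu), disc closing by explicit max/min filters,
# size filter, union-find count.
oracle_calc_count <- function(image, mask, alpha = 0.5, struct_radius = 1,
                              min_blob_px = 4, connectivity = 8) {
  vals <- image[mask]
  mu <- mean(vals); mx <- max(vals)
  if (mx <= mu) return(0L)
  thr <- mu + alpha * (mx - mu)
  bin <- image > thr & mask
  offs <- expand.grid(dr = -struct_radius:struct_radius,
                      dc = -struct_radius:struct_radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= struct_radius^2, ]
  m <- nrow(bin); n <- ncol(bin)
  px_dilate <- function(b) {
    out <- matrix(FALSE, m, n)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      if (!b[i, j]) next
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii >= 1 && ii <= m && jj >= 1 && jj <= n) out[ii, jj] <- TRUE
      }
    }
    out
  }
  px_erode <- function(b) {
    out <- matrix(FALSE, m, n)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      keep <- TRUE
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii < 1 || ii > m || jj < 1 || jj > n || !b[ii, jj]) { keep <- FALSE; break }
      }
      out[i, j] <- keep
    }
    out
  }
  bin <- px_erode(px_dilate(bin))
  if (!any(bin)) return(0L)
  # drop components below min_blob_px
  labs <- matrix(0L, nrow(bin), ncol(bin))
  cur <- 0L
  count <- 0L
  for (s in which(bin)) {
    if (labs[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    members <- integer(0)
    labs[s] <- cur
    while (length(stack)) {
      p <- stack[[1]]; stack <- stack[-1]
      members <- c(members, p)
      i <- (p - 1) %% nrow(bin) + 1; j <- (p - 1) %/% nrow(bin) + 1
      nb <- if (connectivity == 8) {
        expand.grid(i = (i - 1):(i + 1), j = (j - 1):(j + 1))
      } else {
        data.frame(i = c(i - 1, i + 1, i, i), j = c(j, j, j - 1, j + 1))
      }
      for (q in seq_len(nrow(nb))) {
        ii <- nb$i[q]; jj <- nb$j[q]
        if (ii >= 1 && ii <= nrow(bin) && jj >= 1 && jj <= ncol(bin)) {
          p2 <- (jj - 1) * nrow(bin) + ii
          if (bin[p2] && labs[p2] == 0L) { labs[p2] <- cur; stack <- c(stack, p2) }
        }
      }
    }
    if (length(members) >= min_blob_px) count <- count + 1L
  }
  count
}

# Textbook two-sample t statistics.
oracle_ttest <- function(x, y, variant = "pooled") {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# A quick lesion ROI built on a plain rectangular mask (for texture tests).
rect_roi <- function(image, r1, r2, c1, c2) {
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[r1:r2, c1:c2] <- TRUE
  lesion_roi(image, mask = mask)
}

# Small random blob phantoms used by several oracle-equivalence suites.
random_phantom_roi <- function(seed, canvas = c(96, 96), speckle = 0.08,
                               n_calcs = 0) {
  spec <- phantom_spec(
    canvas = canvas, r0 = 22 + (seed %% 7),
    harmonics = list(c(2 + (seed %% 4), 0.05 + 0.01 * (seed %% 5), (seed %% 6))),
    axis_ratio = 1 + 0.15 * (seed %% 3), rotation_deg = (17 * seed) %% 179,
    margin_sigma = seed %% 2, n_calcs = n_calcs, calc_radius = 2,
    interior_mean = 80, exterior_mean = 150, speckle_sigma = speckle,
    n_bands = 1 + (seed %% 3), seed = seed
  )
  ph <- make_phantom(spec)
  list(roi = lesion_roi(ph$image, contour = ph$contour), phantom = ph)
}
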