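# Grey level gradient co-occurrence matrix over the lesion interior.

#' Build the grey level gradient co-occurrence matrix
#'
#' Joint histogram of quantised grey level and quantised Sobel gradient
#' magnitude over the lesion interior. Grey levels are mapped linearly from
#' the fixed range `[0, 255]` (or, with `quantization = "minmax"`, the
#' interior's own range) to `1..L_s`. The gradient magnitude (3x3 Sobel on
#' the full image, sampled at interior pixels) is normalised to the interior
#' maximum and mapped to `1..L_g`; an all-zero gradient maps to level 1.
#' `H` holds counts, `P = H / sum(H)` the normalised matrix.
#'
#' @param roi a [lesion_roi()].
#' @param L_s number of grey levels (default 16).
#' @param L_g number of gradient levels (default 16).
#' @param quantization `"fixed"` (default) or `"minmax"` grey scaling.
#' @return object of class `glgcm`: list with `H`, `P`, `L_s`, `L_g` and
#'   `grey_values` (representative normalised grey value per level).
#' @export
build_glgcm <- function(roi, L_s = 16, L_g = 16,
                        quantization = c("fixed", "minmax")) {
  quantization <- match.arg(quantization)
  stopifnot(inherits(roi, "lesion_roi"), L_s >= 2, L_g >= 2)
  L_s <- as.integer(L_s); L_g <- as.integer(L_g)
  interior <- which(roi$mask)
  if (length(interior) < 16L) stop("lesion interior too small (< 16 pixels)")
  g <- roi$image[interior]
  if (quantization == "fixed") {
    gi <- pmin(L_s, floor(g * L_s / 256) + 1L)
  } else {
    rng <- range(g)
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    gi <- pmin(L_s, floor((g - rng[1]) / span * L_s) + 1L)
  }
  grad <- sobel_gradient(roi$image)$magnitude[interior]
  gmax <- max(grad)
  gj <- if (gmax <= 0) rep(1L, length(grad)) else
        pmax(1L, pmin(L_g, as.integer(ceiling(grad / gmax * L_g))))
  H <- matrix(tabulate((gi - 1L) * L_g + gj, nbins = L_s * L_g),
              nrow = L_s, ncol = L_g, byrow = TRUE)
  structure(
    list(H = H, P = H / sum(H), L_s = L_s, L_g = L_g,
         grey_values = (seq_len(L_s) - 1) / (L_s - 1)),
    class = "glgcm"
  )
}

#' @export
print.glgcm <- function(x, ...) {
  cat("<glgcm>", x$L_s, "grey x", x$L_g, "gradient levels,",
      sum(x$H), "interior pixels\n")
  invisible(x)
}

#' GLGCM energy
#'
#' `E = sum P(i,j)^2`, in `(0, 1]`; 1 exactly when a single cell carries all
#' the mass (a perfectly homogeneous interior).
#'
#' @param g a [build_glgcm()] object.
#' @return number in `(0, 1]`.
#' @export
glgcm_energy <- function(g) {
  stopifnot(inherits(g, "glgcm"))
  sum(g$P^2)
}

#' GLGCM entropy
#'
#' Shannon entropy of the grey marginal `q_i = sum_j P(i,j)` in natural-log
#' units: `-sum q_i * log(q_i)` (empty levels contribute 0). Bounded by
#' `log(L_s)`; zero iff the marginal is degenerate.
#'
#' @param g a [build_glgcm()] object.
#' @return non-negative number.
#' @export
glgcm_entropy <- function(g) {
  stopifnot(inherits(g, "glgcm"))
  q <- rowSums(g$P)
  q <- q[q > 0]
  -sum(q * log(q))
}

#' GLGCM grey mean
#'
#' Mean normalised grey value under the grey marginal:
#' `GM = sum g_i * q_i` with `g_i = (i - 1)/(L_s - 1)` in `[0, 1]`
#' (default), or the raw level index `i` with `gm_scale = "levels"`.
#'
#' @param g a [build_glgcm()] object.
#' @param gm_scale `"normalized"` (default) or `"levels"`.
#' @return number in `[0, 1]` (normalised) or `[1, L_s]` (levels).
#' @export
glgcm_grey_mean <- function(g, gm_scale = c("normalized", "levels")) {
  gm_scale <- match.arg(gm_scale)
  stopifnot(inherits(g, "glgcm"))
  q <- rowSums(g$P)
  if (gm_scale == "normalized") sum(g$grey_values * q) else sum(seq_len(g$L_s) * q)
}
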