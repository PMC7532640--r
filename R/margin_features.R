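# Margin descriptors from the radial boundary sequence and the local
# image gradient.

#' Margin spicules
#'
#' Low-over-high frequency ratio of the one-sided magnitude spectrum of the
#' radial boundary sequence. With DFT bin `k` at angular frequency
#' `w_k = 2*pi*k/N` (radians per boundary sample), the numerator sums
#' `R(w_k)` over `w_k <= pi/4` (the DC term included), the denominator over
#' `pi/4 < w_k <= pi`. A smooth boundary concentrates spectral mass at low
#' frequency, so larger values mean a smoother, less spiculated margin.
#' When the high-frequency mass is numerically zero (denominator below
#' `1e-9` times the numerator) the sequence is a perfect low-frequency
#' boundary and the overflow sentinel `Inf` is returned.
#'
#' @param seq a [to_radial_sequence()] object.
#' @return non-negative number, or `Inf` (overflow sentinel).
#' @export
margin_spicules <- function(seq) {
  stopifnot(inherits(seq, "radial_sequence"))
  r <- seq$r
  n <- length(r)
  if (n < 8L) stop("radial sequence too short (< 8 samples)")
  R <- Mod(stats::fft(r))
  k <- 0:(n %/% 2)          # one-sided spectrum
  w <- 2 * pi * k / n
  num <- sum(R[k[w <= pi / 4] + 1L])
  den <- sum(R[k[w > pi / 4 & w <= pi] + 1L])
  if (den < 1e-9 * num) return(Inf)
  num / den
}

#' Margin coarseness
#'
#' Mean absolute difference between consecutive boundary radii, with cyclic
#' closure (`d_{N+1} = d_1`): `(1/N) * sum |d_i - d_{i+1}|`, in pixel units.
#' Zero for a perfectly smooth (constant-radius) margin.
#'
#' @param seq a [to_radial_sequence()] object, or any list with field `r`.
#' @return non-negative number (pixels).
#' @export
margin_coarseness <- function(seq) {
  r <- if (is.list(seq)) seq$r else seq
  if (length(r) < 2L) stop("radial sequence too short (< 2 samples)")
  mean(abs(r - c(r[-1L], r[1L])))
}

#' Margin indistinctness
#'
#' Total Sobel gradient magnitude over the boundary band: the set of pixels
#' within `band_width` pixels of any boundary pixel (a morphological
#' dilation of the boundary by a disc, covering tissue just inside and just
#' outside the lesion). A sharp margin produces a large value; blurring the
#' margin lowers it. Reported raw; the feature table stores it divided by
#' 1e6.
#'
#' @param roi a [lesion_roi()].
#' @param band_width band radius in pixels (default 5).
#' @return non-negative number.
#' @export
margin_indistinctness <- function(roi, band_width = 5) {
  stopifnot(inherits(roi, "lesion_roi"), band_width >= 1)
  m <- nrow(roi$image); n <- ncol(roi$image)
  band <- matrix(FALSE, m, n)
  bw <- as.integer(band_width)
  off <- expand.grid(dr = -bw:bw, dc = -bw:bw)
  off <- off[off$dr^2 + off$dc^2 <= band_width^2, ]
  for (i in seq_len(nrow(off))) {
    rr <- roi$boundary[, 1] + off$dr[i]
    cc <- roi$boundary[, 2] + off$dc[i]
    ok <- rr >= 1 & rr <= m & cc >= 1 & cc <= n
    band[cbind(rr[ok], cc[ok])] <- TRUE
  }
  if (!any(band)) stop("empty boundary band")
  g <- sobel_gradient(roi$image)
  sum(g$magnitude[band])
}

#' Margin lobulation
#'
#' Counts the undulations of the smoothed radial boundary profile: the
#' radius sequence (clockwise, i.e. ordered by angle) is cyclically median
#' filtered (window `median_frame`), fitted with a least-squares polynomial
#' of degree `poly_degree` in normalised position `t = i/N`, and the
#' lobulation is the number of local maxima plus local minima of the fitted
#' values over the closed boundary. The polynomial is fitted on the
#' sequence cyclically padded by the median half-window so the fit's
#' endpoint error cannot plant spurious extrema at the start-of-sequence
#' seam, and extrema are counted with a hysteresis prominence of
#' `min_prominence * median(r)` so that oscillations far smaller than any
#' anatomical lobe (numerical fit wiggle, residual speckle) are ignored.
#'
#' @param seq a [to_radial_sequence()] object.
#' @param median_frame odd cyclic median filter window (default 21).
#' @param poly_degree polynomial degree (default 20).
#' @param min_prominence minimum extremum swing as a fraction of the median
#'   radius (default 0.02).
#' @return non-negative integer count of extrema.
#' @export
margin_lobulation <- function(seq, median_frame = 21, poly_degree = 20,
                              min_prominence = 0.02) {
  stopifnot(inherits(seq, "radial_sequence"))
  r <- seq$r
  n <- length(r)
  if (n < 2L * median_frame) {
    stop("radial sequence too short: need at least ", 2L * median_frame,
         " samples, got ", n)
  }
  pad <- (median_frame - 1L) %/% 2L
  sm <- cyclic_median(r, median_frame)
  f <- fit_cyclic_polynomial(sm, poly_degree, pad)
  count_cyclic_extrema(f, prominence = min_prominence * stats::median(r))
}
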