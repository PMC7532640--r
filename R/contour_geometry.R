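# Shape features computed from the mask and boundary alone.

#' Circularity
#'
#' `Cir = C^2 / S`, the squared boundary perimeter over the area pixel
#' count. The perimeter is the Euclidean length of the traced boundary
#' chain (diagonal steps weighted `sqrt(2)`), so that a rasterized disc
#' approaches the continuous-circle limit `4*pi`; a pure step count would
#' bias the measure by the lattice direction of each boundary segment.
#' Dimensionless; minimised by a disc and growing with boundary complexity.
#'
#' @param roi a [lesion_roi()].
#' @return positive number.
#' @export
circularity <- function(roi) {
  stopifnot(inherits(roi, "lesion_roi"))
  if (roi$S == 0) stop("empty lesion area")
  roi$perimeter^2 / roi$S
}

#' Height-to-width ratio
#'
#' Ratio of the row (depth) extent to the column (lateral) extent of the
#' axis-aligned rectangle circumscribing the boundary. Extents are inclusive
#' pixel counts (`max - min + 1`), consistent with the pixel-count semantics
#' of the area and boundary counts.
#'
#' @param roi a [lesion_roi()].
#' @return positive number; `< 1` for lesions wider than tall.
#' @export
height_width_ratio <- function(roi) {
  stopifnot(inherits(roi, "lesion_roi"))
  h <- diff(range(roi$boundary[, 1])) + 1
  w <- diff(range(roi$boundary[, 2])) + 1
  if (h <= 0 || w <= 0) stop("degenerate boundary extent")
  h / w
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to boundary points by the numerically stabilised direct
#' algebraic least-squares method (constrained conic fit with
#' `4AC - B^2 = 1`). The orientation `theta_raw` is the angle of the major
#' axis measured from the +col (horizontal) axis toward +row, reported in
#' `[0, 2*pi)` (the axis is direction-free, so the value is defined mod pi).
#'
#' @param boundary matrix of boundary points (columns row, col), >= 8 points,
#'   not collinear.
#' @return object of class `ellipse_fit`: list with `center` (row, col),
#'   semi-axes `a >= b`, and `theta_raw`.
#' @export
fit_ellipse <- function(boundary) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 8L) stop("ellipse fit needs at least 8 points")
  x <- boundary[, 2]; y <- boundary[, 1]
  mx <- mean(x); my <- mean(y)
  s <- max((max(x) - min(x)) / 2, (max(y) - min(y)) / 2)
  if (s == 0) stop("degenerate boundary: all points coincide")
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("ellipse fit failed: degenerate (collinear?) points")
  })
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  pick <- which(cond > 0)
  if (length(pick) == 0) stop("ellipse fit failed: no elliptical solution")
  a1 <- vecs[, pick[1]]
  co <- c(a1, as.vector(Tm %*% a1))
  # unscale the conic back to image coordinates
  A <- co[1] / s^2; B <- co[2] / s^2; C <- co[3] / s^2
  D <- co[4] / s - 2 * co[1] * mx / s^2 - co[2] * my / s^2
  E <- co[5] / s - 2 * co[3] * my / s^2 - co[2] * mx / s^2
  F <- co[6] + co[1] * mx^2 / s^2 + co[2] * mx * my / s^2 +
       co[3] * my^2 / s^2 - co[4] * mx / s - co[5] * my / s
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  rt <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + rt)) / den
  ax2 <- -sqrt(num * (A + C - rt)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0) {
    stop("ellipse fit failed: degenerate conic")
  }
  theta <- if (abs(B) < 1e-12) (if (A <= C) 0 else pi / 2) else atan2(C - A - rt, B)
  if (ax1 < ax2) { tmp <- ax1; ax1 <- ax2; ax2 <- tmp; theta <- theta + pi / 2 }
  structure(
    list(center = c(row = y0, col = x0), a = ax1, b = ax2,
         theta_raw = theta %% (2 * pi)),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.1f, %.1f)  a = %.2f  b = %.2f  theta = %.3f rad\n",
              x$center[1], x$center[2], x$a, x$b, x$theta_raw))
  invisible(x)
}

#' Fold an orientation angle into [0, pi/2]
#'
#' Piecewise reflection mapping a raw axis angle in `[0, 2*pi)` onto the
#' acute angle with the horizontal: `theta` on `[0, pi/2]`, `pi - theta` on
#' `[pi/2, pi]`, `theta - pi` on `[pi, 3*pi/2]`, `2*pi - theta` on
#' `[3*pi/2, 2*pi]`. Idempotent on `[0, pi/2]`, and `fold(t) == fold(t + pi)`.
#'
#' @param theta_raw numeric vector of angles in radians, `[0, 2*pi]`.
#' @return angles in `[0, pi/2]`.
#' @export
fold_angle <- function(theta_raw) {
  if (any(theta_raw < 0 | theta_raw > 2 * pi)) {
    stop("theta_raw must lie in [0, 2*pi]")
  }
  out <- theta_raw
  b2 <- theta_raw > pi / 2 & theta_raw <= pi
  b3 <- theta_raw > pi & theta_raw <= 3 * pi / 2
  b4 <- theta_raw > 3 * pi / 2
  out[b2] <- pi - theta_raw[b2]
  out[b3] <- theta_raw[b3] - pi
  out[b4] <- 2 * pi - theta_raw[b4]
  out
}

#' Angle between the lesion long axis and the skin line
#'
#' Fits an ellipse to the lesion boundary and folds the major-axis
#' orientation into `[0, 90]` degrees. The skin line is taken parallel to
#' the top image edge (standard linear-probe geometry), so the horizontal
#' reference is the image column axis. For near-circular lesions
#' (`a/b < 1.05`) the orientation is ill-defined; the value is still
#' returned, with attribute `low_confidence = TRUE`.
#'
#' @param roi a [lesion_roi()].
#' @return angle in degrees in `[0, 90]`.
#' @export
als_degrees <- function(roi) {
  stopifnot(inherits(roi, "lesion_roi"))
  ef <- fit_ellipse(roi$boundary)
  deg <- fold_angle(ef$theta_raw) * 180 / pi
  if (ef$a / ef$b < 1.05) attr(deg, "low_confidence") <- TRUE
  deg
}
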