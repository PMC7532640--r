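# Internal calcifications: bright connected components inside the lesion.

#' Calcification counting parameters
#'
#' @param alpha position of the binarisation threshold between the interior
#'   mean and maximum: `T = mu + alpha * (max - mu)`, `0 < alpha < 1`.
#' @param struct_radius disc radius (pixels) of the morphological structuring
#'   element.
#' @param min_blob_px smallest component (pixels) kept as a calcification.
#' @param connectivity 4 or 8 (default 8).
#' @param morph_order `"close"` (dilate then erode, the default) or `"open"`
#'   (erode then dilate).
#' @return object of class `calc_params`.
#' @export
calc_params <- function(alpha = 0.5, struct_radius = 1, min_blob_px = 4,
                        connectivity = 8, morph_order = c("close", "open")) {
  morph_order <- match.arg(morph_order)
  stopifnot(alpha > 0, alpha < 1, struct_radius >= 1, min_blob_px >= 1,
            connectivity %in% c(4, 8))
  structure(
    list(alpha = alpha, struct_radius = as.integer(struct_radius),
         min_blob_px = as.integer(min_blob_px),
         connectivity = as.integer(connectivity), morph_order = morph_order),
    class = "calc_params"
  )
}

#' Count internal calcifications
#'
#' Pixels outside the lesion mask are zeroed; the interior is binarised at
#' `T = mu + alpha * (max - mu)` (interior mean and maximum, so the count is
#' invariant to uniform brightness shifts); the binary image is cleaned by
#' morphological dilation-then-erosion (closing) with a disc; components
#' smaller than `min_blob_px` are dropped; the remaining connected-component
#' count is returned. A constant interior yields 0.
#'
#' @param roi a [lesion_roi()].
#' @param params a [calc_params()] object.
#' @return non-negative integer.
#' @export
count_calcifications <- function(roi, params = calc_params()) {
  stopifnot(inherits(roi, "lesion_roi"), inherits(params, "calc_params"))
  vals <- roi$image[roi$mask]
  if (length(vals) == 0) stop("empty lesion interior")
  mu <- mean(vals); mx <- max(vals)
  if (mx <= mu) return(0L)
  thr <- mu + params$alpha * (mx - mu)
  bin <- roi$image > thr & roi$mask
  if (!any(bin)) return(0L)
  if (params$morph_order == "close") {
    bin <- binary_erode(binary_dilate(bin, params$struct_radius),
                        params$struct_radius)
  } else {
    bin <- binary_dilate(binary_erode(bin, params$struct_radius),
                         params$struct_radius)
  }
  if (!any(bin)) return(0L)
  lab <- label_components(bin, params$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= params$min_blob_px)
}
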