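# Seeded ultrasound-like lesion phantoms with planted ground truth.

#' Phantom specification
#'
#' Describes a single hypoechoic lesion phantom: a star-shaped boundary
#' `r(theta) = e(theta) * (1 + sum a_k cos(k*theta + phi_k))`, where
#' `e(theta)` is the radial profile of an ellipse with geometric-mean radius
#' `r0`, axis ratio `axis_ratio` and long axis at `rotation_deg` from the
#' horizontal; a darker interior on a brighter background; optional
#' concentric intensity bands (heterogeneity), Gaussian margin blur,
#' planted bright calcification discs, and multiplicative speckle.
#'
#' @param canvas image size `c(m, n)` in pixels.
#' @param r0 base radius (pixels, >= 20).
#' @param harmonics list of `c(k, a, phi)` boundary harmonics (order,
#'   relative amplitude, phase); total `sum |a| < 0.5` keeps the boundary
#'   star-shaped.
#' @param axis_ratio long-to-short axis ratio of the elliptical base (>= 1).
#' @param rotation_deg planted long-axis orientation, degrees in `[0, 180)`.
#' @param margin_sigma Gaussian blur width at the boundary (pixels; 0 = sharp).
#' @param n_calcs number of planted bright discs.
#' @param calc_radius calcification disc radius (pixels).
#' @param interior_mean,exterior_mean interior/background intensity (0--255);
#'   interior darker by default (hypoechoic convention).
#' @param speckle_sigma multiplicative speckle scale (`x <- x * (1 + eps)`,
#'   `eps ~ N(0, speckle_sigma)`).
#' @param n_bands number of concentric interior intensity bands (1 = uniform).
#' @param band_spread half-range (intensity units) of the band values around
#'   `interior_mean`.
#' @param seed RNG seed; identical spec + seed give bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas = c(128, 128), r0 = 35, harmonics = list(),
                         axis_ratio = 1, rotation_deg = 0, margin_sigma = 0,
                         n_calcs = 0, calc_radius = 3, interior_mean = 70,
                         exterior_mean = 140, speckle_sigma = 0, n_bands = 1,
                         band_spread = 60, seed = 1) {
  if (is.matrix(harmonics)) harmonics <- asplit(harmonics, 1)
  amps <- vapply(harmonics, function(h) abs(h[2]), numeric(1))
  stopifnot(r0 >= 20, length(canvas) == 2, canvas >= 16,
            axis_ratio >= 1, rotation_deg >= 0, rotation_deg < 180,
            margin_sigma >= 0, n_calcs >= 0, calc_radius >= 1,
            interior_mean != exterior_mean, speckle_sigma >= 0, n_bands >= 1)
  if (length(amps) && sum(amps) >= 0.5) {
    stop("total harmonic amplitude must stay below 0.5 (star-shaped boundary)")
  }
  structure(
    list(canvas = as.integer(canvas), r0 = r0, harmonics = harmonics,
         axis_ratio = axis_ratio, rotation_deg = rotation_deg,
         margin_sigma = margin_sigma, n_calcs = as.integer(n_calcs),
         calc_radius = calc_radius, interior_mean = interior_mean,
         exterior_mean = exterior_mean, speckle_sigma = speckle_sigma,
         n_bands = as.integer(n_bands), band_spread = band_spread,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Exact boundary polygon of a phantom spec
#'
#' The analytic lesion boundary sampled at 720 angles, without rendering the
#' image: the polygon [make_phantom()] uses as ground-truth contour.
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix of vertices (columns `row`, `col`).
#' @export
phantom_contour <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cr <- (spec$canvas[1] + 1) / 2; cc <- (spec$canvas[2] + 1) / 2
  tv <- 2 * pi * (0:719) / 720
  rv <- phantom_radius(spec, tv)
  cbind(row = cr + rv * sin(tv), col = cc + rv * cos(tv))
}

# radial boundary profile r(theta) of a spec, vectorised over theta
phantom_radius <- function(spec, theta) {
  rot <- spec$rotation_deg * pi / 180
  ra <- spec$r0 * sqrt(spec$axis_ratio)
  rb <- spec$r0 / sqrt(spec$axis_ratio)
  d <- theta - rot
  r <- ra * rb / sqrt((rb * cos(d))^2 + (ra * sin(d))^2)
  mod <- 1
  for (h in spec$harmonics) mod <- mod + h[2] * cos(h[1] * theta + h[3])
  r * mod
}

#' Generate a lesion phantom
#'
#' Renders the spec to an 8-bit grey image, the exact boundary polygon
#' (720 vertices), and a `phantom_truth` record of the planted parameters.
#' Rendering order: clean interior/exterior image (with concentric bands),
#' Gaussian margin blur, calcification discs (intensity 250, rejection-
#' sampled interior centres with pairwise separation >= 4 * calc_radius),
#' multiplicative speckle, clipping to `[0, 255]` and rounding.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom` with elements `image`, `contour`
#'   (vertex matrix, columns row/col), `mask` (the rasterized lesion mask,
#'   identical to `rasterize_contour(contour, canvas)`), and `truth` (list:
#'   `contour`, `rotation_deg`, `n_lobes`, `n_calcs`, `calc_centers`,
#'   `margin_sigma`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$canvas[1]; n <- spec$canvas[2]
  cr <- (m + 1) / 2; cc <- (n + 1) / 2
  with_seed(spec$seed, {
    contour <- phantom_contour(spec)
    if (any(contour < 1.5) || any(contour[, 1] > m - 0.5) ||
        any(contour[, 2] > n - 0.5)) {
      stop("phantom boundary does not fit the canvas")
    }
    # analytic inside test per pixel
    rr <- matrix(seq_len(m), m, n) - cr
    ccm <- matrix(seq_len(n), m, n, byrow = TRUE) - cc
    rp <- sqrt(rr^2 + ccm^2)
    tp <- atan2(rr, ccm) %% (2 * pi)
    rb <- matrix(phantom_radius(spec, as.vector(tp)), m, n)
    # paint through the same inclusive rasterization the pipeline applies,
    # so the contoured interior is exactly the painted region
    inside <- rasterize_contour(contour, c(m, n))
    img <- matrix(spec$exterior_mean, m, n)
    if (spec$n_bands == 1L) {
      img[inside] <- spec$interior_mean
    } else {
      vals <- spec$interior_mean +
        seq(-spec$band_spread, spec$band_spread, length.out = spec$n_bands)
      band <- matrix(pmin(spec$n_bands, floor(spec$n_bands * rp / rb) + 1L), m, n)
      img[inside] <- vals[band[inside]]
    }
    img <- gaussian_blur(img, spec$margin_sigma)
    # planted calcifications
    centers <- NULL
    if (spec$n_calcs > 0L) {
      centers <- matrix(0, 0, 2)
      tries <- 0L
      while (nrow(centers) < spec$n_calcs) {
        tries <- tries + 1L
        if (tries > 10000L) stop("could not place calcifications with the required separation")
        cand_r <- cr + stats::runif(1, -spec$r0, spec$r0)
        cand_c <- cc + stats::runif(1, -spec$r0, spec$r0)
        dr <- cand_r - cr; dc <- cand_c - cc
        rad <- sqrt(dr^2 + dc^2)
        th <- atan2(dr, dc) %% (2 * pi)
        if (rad > 0.6 * phantom_radius(spec, th)) next
        if (nrow(centers) > 0) {
          dmin <- min(sqrt((centers[, 1] - cand_r)^2 + (centers[, 2] - cand_c)^2))
          if (dmin < 4 * spec$calc_radius) next
        }
        centers <- rbind(centers, c(cand_r, cand_c))
      }
      for (i in seq_len(nrow(centers))) {
        d2 <- (matrix(seq_len(m), m, n) - centers[i, 1])^2 +
              (matrix(seq_len(n), m, n, byrow = TRUE) - centers[i, 2])^2
        img[d2 <= spec$calc_radius^2] <- 250
      }
    }
    if (spec$speckle_sigma > 0) {
      img <- img * (1 + matrix(stats::rnorm(m * n, 0, spec$speckle_sigma), m, n))
    }
    img <- matrix(round(pmin(255, pmax(0, img))), m, n)
    ks <- vapply(spec$harmonics, function(h) if (abs(h[2]) > 0) h[1] else 0, numeric(1))
    truth <- list(
      contour = contour,
      rotation_deg = spec$rotation_deg,
      n_lobes = if (length(ks) && max(ks) > 0) 2L * as.integer(max(ks)) else 0L,
      n_calcs = spec$n_calcs,
      calc_centers = centers,
      margin_sigma = spec$margin_sigma
    )
    structure(list(image = img, contour = contour, mask = inside, truth = truth),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", nrow(x$image), "x", ncol(x$image),
      " rotation", x$truth$rotation_deg, "deg,",
      x$truth$n_lobes, "lobes,", x$truth$n_calcs, "calcifications\n")
  invisible(x)
}

#' Cohort generation profile
#'
#' Group-specific sampling distributions for [make_cohort()]. The default
#' effect profile plants the group structure used throughout validation:
#' the malignant arm draws higher-order, larger-amplitude boundary
#' harmonics (more lobulation), fewer calcifications, smaller long-axis
#' rotation angles, and more interior intensity bands than the benign arm.
#' The `"null"` profile draws both arms from the benign distribution
#' (zero effect, for calibration).
#'
#' Each group entry is a list with fields `r0` (range), `k` (harmonic orders
#' sampled uniformly), `a` (amplitude range), `axis_ratio` (range),
#' `rotation_sd` (half-normal SD in degrees), `calc_mean` (Poisson mean,
#' capped at 6), `n_bands`, `margin_sigma` (range), and shared `canvas`,
#' `speckle_sigma`, `calc_radius`, `interior_mean`, `exterior_mean`.
#'
#' @param effect `"default"` or `"null"`.
#' @param canvas image size used for every phantom in the cohort.
#' @return list with `benign` and `malignant` sampling specs.
#' @export
cohort_profile <- function(effect = c("default", "null"), canvas = c(128, 128)) {
  effect <- match.arg(effect)
  shared <- list(canvas = canvas, speckle_sigma = 0.08, calc_radius = 2,
                 interior_mean = 70, exterior_mean = 140, band_spread = 60)
  benign <- c(list(r0 = c(26, 40), k = 2:3, a = c(0.04, 0.08),
                   axis_ratio = c(1.4, 2.2), rotation_sd = 18,
                   calc_mean = 3.8, n_bands = 2, margin_sigma = c(0.5, 1.5)),
              shared)
  malignant <- c(list(r0 = c(22, 34), k = 5:6, a = c(0.08, 0.14),
                      axis_ratio = c(1.2, 1.8), rotation_sd = 6,
                      calc_mean = 2.5, n_bands = 4, margin_sigma = c(0.5, 1.5)),
                 shared)
  if (effect == "null") malignant <- benign
  list(benign = benign, malignant = malignant)
}

# Draw one phantom_spec from a group profile (uses the current RNG stream).
draw_spec <- function(g, seed) {
  k <- if (length(g$k) == 1L) g$k else sample(g$k, 1L)
  phantom_spec(
    canvas = g$canvas,
    r0 = stats::runif(1, g$r0[1], g$r0[2]),
    harmonics = list(c(k, stats::runif(1, g$a[1], g$a[2]),
                       stats::runif(1, 0, 2 * pi))),
    axis_ratio = stats::runif(1, g$axis_ratio[1], g$axis_ratio[2]),
    rotation_deg = min(179, abs(stats::rnorm(1, 0, g$rotation_sd))),
    margin_sigma = stats::runif(1, g$margin_sigma[1], g$margin_sigma[2]),
    n_calcs = min(6L, stats::rpois(1, g$calc_mean)),
    calc_radius = g$calc_radius,
    interior_mean = g$interior_mean, exterior_mean = g$exterior_mean,
    speckle_sigma = g$speckle_sigma, n_bands = g$n_bands,
    band_spread = g$band_spread,
    seed = seed
  )
}

#' Generate a two-group phantom cohort
#'
#' Draws per-lesion specs from the group distributions in `profile`,
#' renders each phantom, and (when `dir` is given) writes PNG images, JSON
#' contours, `manifest.csv` (lesion_id, image_path, contour_path, group)
#' and `truth.csv` into `dir`. Fully seeded: the same arguments reproduce
#' the cohort bit for bit.
#'
#' @param n_benign,n_malignant group sizes (>= 2 each).
#' @param profile a [cohort_profile()] list.
#' @param seed integer seed.
#' @param dir output directory, or `NULL` to keep phantoms in memory only.
#' @param render render images (`TRUE`, default); with `render = FALSE` only
#'   the sampled specs, ground-truth contours and truth table are produced
#'   (for boundary-geometry studies that need no pixel data).
#' @return list with `phantoms` (list of `phantom` objects, or `NULL` when
#'   not rendered), `contours` (ground-truth polygons), `specs`, `manifest`
#'   (data frame) and `truth` (data frame of planted parameters).
#' @export
make_cohort <- function(n_benign, n_malignant, profile = cohort_profile(),
                        seed = 1, dir = NULL, render = TRUE) {
  stopifnot(n_benign >= 2, n_malignant >= 2)
  if (!is.null(dir) && !render) stop("writing a cohort requires render = TRUE")
  groups <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  n <- length(groups)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      draw_spec(profile[[groups[i]]],
                seed = (as.integer(seed) * 1009L + i) %% 2147483647L)
    })
  })
  phantoms <- if (render) lapply(specs, make_phantom) else NULL
  contours <- if (render) lapply(phantoms, `[[`, "contour")
              else lapply(specs, phantom_contour)
  ids <- sprintf("lesion_%03d", seq_len(n))
  truth <- data.frame(
    lesion_id = ids, group = groups,
    r0 = vapply(specs, function(s) s$r0, 0),
    harmonic_k = vapply(specs, function(s) s$harmonics[[1]][1], 0),
    harmonic_a = vapply(specs, function(s) s$harmonics[[1]][2], 0),
    n_lobes = vapply(specs, function(s) {
      ks <- vapply(s$harmonics, function(h) if (abs(h[2]) > 0) h[1] else 0, 0)
      if (length(ks) && max(ks) > 0) 2L * as.integer(max(ks)) else 0L
    }, 0L),
    rotation_deg = vapply(specs, function(s) s$rotation_deg, 0),
    n_calcs = vapply(specs, function(s) s$n_calcs, 0L),
    n_bands = vapply(specs, function(s) s$n_bands, 0L),
    margin_sigma = vapply(specs, function(s) s$margin_sigma, 0),
    stringsAsFactors = FALSE
  )
  # paths are relative to the manifest's own directory, keeping cohorts portable
  manifest <- data.frame(
    lesion_id = ids,
    image_path = paste0(ids, ".png"),
    contour_path = paste0(ids, ".json"),
    group = groups, stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_grey_image(phantoms[[i]]$image, file.path(dir, manifest$image_path[i]))
      write_contour(phantoms[[i]]$contour, file.path(dir, manifest$contour_path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(phantoms = phantoms, contours = contours, specs = specs,
       manifest = manifest, truth = truth)
}
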