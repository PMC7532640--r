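#' Read a grey-scale image
#'
#' Reads an 8-bit PNG or TIFF image into an integer-valued intensity matrix
#' (0--255), row 1 at the top of the image. The first axis is depth (the
#' beam direction), the second axis is lateral (parallel to the skin line).
#' RGB images are collapsed to luminance (ITU-R 601 weights); an alpha
#' channel, if present, is ignored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix of integer intensities in `[0, 255]`, at least 8x8.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  )
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  img <- round(x * 255)
  validate_grey_image(img)
  img
}

#' Write a grey-scale image as 8-bit PNG
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_grey_image <- function(img, path) {
  validate_grey_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

validate_grey_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a numeric matrix")
  if (nrow(img) < 8L || ncol(img) < 8L) {
    stop("image must be at least 8x8 pixels, got ", nrow(img), "x", ncol(img))
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop("image intensities must lie in [0, 255]")
  }
  invisible(img)
}

#' Read a lesion contour file
#'
#' Two on-disk forms are auto-detected by extension: a JSON file
#' `{"vertices": [[row, col], ...]}` with 0-based image coordinates, or a
#' binary mask PNG (foreground > 50% grey). JSON vertices are converted to
#' the package's 1-based matrix convention.
#'
#' @param path `.json` contour or `.png` mask file.
#' @return for JSON, a numeric matrix of vertices (columns `row`, `col`,
#'   1-based); for a mask PNG, a logical mask matrix.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    v <- jsonlite::fromJSON(path)
    if (is.null(v$vertices)) stop("contour JSON must contain a 'vertices' field")
    m <- if (is.matrix(v$vertices)) v$vertices else do.call(rbind, v$vertices)
    m <- m + 1  # stored 0-based
    colnames(m) <- c("row", "col")
    m
  } else if (ext == "png") {
    load_image(path) > 127
  } else {
    stop("unsupported contour format: .", ext, " (JSON or mask PNG expected)")
  }
}

#' Write a contour polygon as JSON
#'
#' Vertices are stored 0-based as `{"vertices": [[row, col], ...]}`.
#'
#' @param vertices numeric matrix (columns row, col; 1-based).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(vertices, path) {
  v <- unname(as.matrix(vertices)) - 1
  jsonlite::write_json(list(vertices = v), path, digits = 6)
  invisible(path)
}

#' Rasterize a contour polygon to a binary mask
#'
#' Inclusive-boundary polygon fill: a pixel is foreground when its centre
#' lies strictly inside the polygon or on a Bresenham-drawn edge, so every
#' boundary pixel belongs to the filled region.
#'
#' @param contour numeric matrix of polygon vertices (columns row, col;
#'   1-based; closure implied, first vertex not repeated).
#' @param shape integer vector `c(m, n)`, the mask dimensions.
#' @return logical mask matrix with a single foreground component.
#' @export
rasterize_contour <- function(contour, shape) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  r <- contour[, 1]; c <- contour[, 2]
  if (any(r < 1 | r > shape[1] | c < 1 | c > shape[2])) {
    stop("contour vertices fall outside the image")
  }
  area2 <- sum(c * c(r[-1], r[1]) - c(c[-1], c[1]) * r)
  if (abs(area2) < 1e-9) stop("degenerate contour: zero area")

  mask <- matrix(FALSE, shape[1], shape[2])
  # inclusive boundary: pixels whose centre lies exactly on a polygon edge
  # (area-unbiased: for real-valued contours almost no centre is on an edge)
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  vr <- r2 - r; vc <- c2 - c
  len2 <- pmax(vr^2 + vc^2, .Machine$double.eps)
  mark_on_edge <- function(pr, pc, i) {
    tpar <- pmin(1, pmax(0, ((pr - r[i]) * vr[i] + (pc - c[i]) * vc[i]) / len2[i]))
    d2 <- (pr - (r[i] + tpar * vr[i]))^2 + (pc - (c[i] + tpar * vc[i]))^2
    on <- d2 < 1e-18 & pr >= 1 & pr <= shape[1] & pc >= 1 & pc <= shape[2]
    if (any(on)) mask[cbind(pr[on], pc[on])] <<- TRUE
  }
  short <- len2 <= 4
  if (any(short)) {
    # all candidates of every short edge at once: a 4x4 integer grid anchored
    # at the edge's bounding-box corner covers spans up to 2 px
    idx <- which(short)
    br <- floor(pmin(r[idx], r2[idx])); bc <- floor(pmin(c[idx], c2[idx]))
    offs <- as.matrix(expand.grid(0:3, 0:3))
    pr <- rep(br, each = nrow(offs)) + offs[, 1]
    pc <- rep(bc, each = nrow(offs)) + offs[, 2]
    ii <- rep(idx, each = nrow(offs))
    tpar <- pmin(1, pmax(0, ((pr - r[ii]) * vr[ii] + (pc - c[ii]) * vc[ii]) / len2[ii]))
    d2 <- (pr - (r[ii] + tpar * vr[ii]))^2 + (pc - (c[ii] + tpar * vc[ii]))^2
    on <- d2 < 1e-18 & pr >= 1 & pr <= shape[1] & pc >= 1 & pc <= shape[2]
    if (any(on)) mask[cbind(pr[on], pc[on])] <- TRUE
  }
  for (i in which(!short)) {
    cr <- max(1L, floor(min(r[i], r2[i]))):min(shape[1], ceiling(max(r[i], r2[i])))
    cc <- max(1L, floor(min(c[i], c2[i]))):min(shape[2], ceiling(max(c[i], c2[i])))
    if (!length(cr) || !length(cc)) next
    mark_on_edge(rep(cr, times = length(cc)), rep(cc, each = length(cr)), i)
  }
  # interior pixels within the bounding box
  rmin <- max(1L, floor(min(r))); rmax <- min(shape[1], ceiling(max(r)))
  cmin <- max(1L, floor(min(c))); cmax <- min(shape[2], ceiling(max(c)))
  grid <- as.matrix(expand.grid(row = rmin:rmax, col = cmin:cmax))
  poly <- rbind(cbind(r, c), c(r[1], c[1]))
  inside <- mgcv::in.out(poly, grid)
  mask[grid[inside, , drop = FALSE]] <- TRUE

  if (n_components(mask, 8L) != 1L) {
    stop("rasterized contour does not form a single connected component")
  }
  mask
}

#' Trace the boundary of a binary mask
#'
#' Moore neighbour tracing of the inner boundary (foreground pixels 8-adjacent
#' to background), returned in clockwise order in image coordinates (angles
#' from the +col axis increasing toward +row). Consecutive pixels are
#' 8-adjacent; the traced length is the boundary pixel count C.
#'
#' @param mask logical matrix with exactly one foreground component.
#' @return integer matrix of boundary pixels (columns row, col), clockwise.
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  if (n_components(mask, 8L) != 1L) stop("mask must have exactly one component")
  m <- nrow(mask); n <- ncol(mask)
  pm <- matrix(FALSE, m + 2L, n + 2L)
  pm[2:(m + 1), 2:(n + 1)] <- mask
  # start at topmost-then-leftmost foreground pixel (padded coordinates)
  fg <- which(pm, arr.ind = TRUE)
  srow <- min(fg[, 1])
  scol <- min(fg[fg[, 1] == srow, 2])
  # clockwise Moore neighbourhood on screen, starting West
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # index of the neighbour direction pointing from p to b
  npix <- sum(mask)
  if (npix < 8L) stop("boundary too short (< 8 pixels); mask is degenerate")
  cap <- 8L * npix + 8L
  rows <- integer(cap); cols <- integer(cap)
  cur_r <- srow; cur_c <- scol
  bdir <- 1L  # backtrack starts at West (background: start is leftmost in top row)
  len <- 0L
  start_dir <- NA_integer_
  bnd <- NULL
  for (step in seq_len(cap)) {
    d <- NA_integer_
    for (k in seq_len(8L)) {
      dd <- ((bdir - 1L + k - 1L) %% 8L) + 1L  # scan clockwise from backtrack
      if (pm[cur_r + dr[dd], cur_c + dc[dd]]) { d <- dd; break }
    }
    if (is.na(d)) stop("boundary too short (< 8 pixels); mask is degenerate")
    len <- len + 1L
    rows[len] <- cur_r; cols[len] <- cur_c
    # Jacob's stopping criterion: back at the start, leaving the same way
    if (len > 1L && cur_r == srow && cur_c == scol && d == start_dir) {
      len <- len - 1L
      bnd <- cbind(row = rows[1:len] - 1L, col = cols[1:len] - 1L)
      break
    }
    if (len == 1L) start_dir <- d
    # new backtrack points from the next pixel to the last background scanned
    prev <- ((d - 2L) %% 8L) + 1L
    pr <- cur_r + dr[prev]; pc <- cur_c + dc[prev]
    cur_r <- cur_r + dr[d]; cur_c <- cur_c + dc[d]
    bdir <- which(dr == (pr - cur_r) & dc == (pc - cur_c))
  }
  if (is.null(bnd)) stop("boundary tracing failed to close")
  if (nrow(bnd) < 8L) stop("boundary too short (< 8 pixels); mask is degenerate")
  if (anyDuplicated(bnd)) {
    stop("boundary is not a simple closed curve (single-pixel-wide region)")
  }
  orient_clockwise(bnd)
}

# Orient a closed pixel sequence clockwise on screen (positive shoelace area
# in (x = col, y = row) coordinates with y pointing down).
orient_clockwise <- function(bnd) {
  x <- bnd[, 2]; y <- bnd[, 1]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) bnd <- bnd[rev(seq_len(nrow(bnd))), , drop = FALSE]
  bnd
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates.
#'
#' @param mask logical matrix.
#' @return numeric `c(row, col)`.
#' @export
mask_centroid <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Construct a radial sequence
#'
#' A clockwise-ordered sequence of boundary radii about the lesion centroid,
#' the substrate for the margin features. Usually produced by
#' [to_radial_sequence()]; exposed so that analytically sampled boundaries
#' can be analysed directly.
#'
#' @param r positive radii in pixel units (>= 8 samples).
#' @param theta angles in `[0, 2*pi)`, same length as `r`; defaults to a
#'   uniform clockwise sweep.
#' @return object of class `radial_sequence`: list with `r`, `theta`, `n`.
#' @export
radial_sequence <- function(r, theta = NULL) {
  if (length(r) < 8L) stop("radial sequence needs at least 8 samples")
  if (any(!is.finite(r)) || any(r <= 0)) stop("radii must be positive and finite")
  if (is.null(theta)) theta <- 2 * pi * (seq_along(r) - 1) / length(r)
  if (length(theta) != length(r)) stop("r and theta lengths differ")
  if (any(theta < 0 | theta >= 2 * pi)) stop("theta must lie in [0, 2*pi)")
  structure(list(r = as.numeric(r), theta = as.numeric(theta), n = length(r)),
            class = "radial_sequence")
}

#' Radial boundary sequence of a traced boundary
#'
#' Converts an ordered boundary to polar coordinates about the centroid:
#' radii in pixel units and angles in `[0, 2*pi)` measured from the +col
#' axis toward +row (clockwise on screen). Order and length are preserved.
#'
#' @param boundary boundary pixel matrix from [trace_boundary()].
#' @param centroid numeric `c(row, col)`.
#' @return object of class `radial_sequence`: list with `r`, `theta`, `n`.
#' @export
to_radial_sequence <- function(boundary, centroid) {
  dr <- boundary[, 1] - centroid[1]
  dc <- boundary[, 2] - centroid[2]
  r <- sqrt(dr^2 + dc^2)
  if (any(r < .Machine$double.eps)) {
    stop("centroid coincides with a boundary pixel (zero radius)")
  }
  radial_sequence(r, atan2(dr, dc) %% (2 * pi))
}

#' @export
print.radial_sequence <- function(x, ...) {
  cat("<radial_sequence> n =", x$n,
      " r: [", round(min(x$r), 2), ",", round(max(x$r), 2), "]\n")
  invisible(x)
}

#' Assemble a lesion region of interest
#'
#' Canonical unit consumed by all feature functions: the grey image, a
#' single-component lesion mask (rasterized from the contour when a polygon
#' is given), the traced clockwise boundary, the centroid, and the pixel
#' counts S (area) and C (boundary length).
#'
#' @param image intensity matrix in `[0, 255]`.
#' @param contour polygon vertex matrix (columns row, col), or `NULL` when
#'   `mask` is given directly.
#' @param mask logical mask matrix, or `NULL` to rasterize `contour`.
#' @return object of class `lesion_roi`.
#' @export
lesion_roi <- function(image, contour = NULL, mask = NULL) {
  validate_grey_image(image)
  if (is.null(mask)) {
    if (is.null(contour)) stop("either a contour or a mask is required")
    mask <- rasterize_contour(contour, dim(image))
  } else {
    mask <- mask > 0
    if (!all(dim(mask) == dim(image))) stop("mask and image dimensions differ")
    if (!any(mask)) stop("empty mask")
    if (n_components(mask, 8L) != 1L) stop("mask must have exactly one component")
  }
  boundary <- trace_boundary(mask)
  centroid <- mask_centroid(mask)
  bb <- range(boundary[, 1]); cb <- range(boundary[, 2])
  if (centroid[1] < bb[1] || centroid[1] > bb[2] ||
      centroid[2] < cb[1] || centroid[2] > cb[2]) {
    stop("centroid falls outside the boundary bounding box")
  }
  steps <- cbind(diff(c(boundary[, 1], boundary[1, 1])),
                 diff(c(boundary[, 2], boundary[1, 2])))
  structure(
    list(image = image, mask = mask, boundary = boundary, centroid = centroid,
         S = sum(mask), C = nrow(boundary),
         perimeter = sum(sqrt(rowSums(steps^2)))),
    class = "lesion_roi"
  )
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat("<lesion_roi> image", nrow(x$image), "x", ncol(x$image),
      " area S =", x$S, " boundary C =", x$C,
      " centroid (", round(x$centroid[1], 1), ",", round(x$centroid[2], 1), ")\n")
  invisible(x)
}
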