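# Batch orchestration: configuration, per-lesion feature extraction, and
# manifest-driven runs.

config_defaults <- function() {
  list(
    margin = list(band_width = 5),
    lobulation = list(median_frame = 21, poly_degree = 20, min_prominence = 0.02),
    spicules = list(n_resample = 0),
    calc = list(alpha = 0.5, struct_radius = 1, min_blob_px = 4,
                connectivity = 8, morph_order = "close"),
    texture = list(L_s = 16, L_g = 16, gm_scale = "normalized",
                   quantization = "fixed"),
    stats = list(variant = "pooled")
  )
}

#' Pipeline configuration
#'
#' Nested configuration with fully specified defaults; an empty call is a
#' valid configuration. Unknown blocks or keys are rejected.
#'
#' @param ... named blocks (`margin`, `lobulation`, `spicules`, `calc`,
#'   `texture`, `stats`), each a named list overriding individual defaults,
#'   e.g. `run_config(margin = list(band_width = 7))`.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- config_defaults()
  user <- list(...)
  if (length(user)) {
    if (is.null(names(user)) || any(names(user) == "")) {
      stop("configuration blocks must be named")
    }
    for (blk in names(user)) {
      if (!blk %in% names(cfg)) stop("unknown configuration block: ", blk)
      for (key in names(user[[blk]])) {
        if (!key %in% names(cfg[[blk]])) {
          stop("unknown configuration key: ", blk, ".", key)
        }
        cfg[[blk]][[key]] <- user[[blk]][[key]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (blk in names(unclass(x))) {
    kv <- vapply(names(x[[blk]]), function(k) paste0(k, "=", x[[blk]][[k]]), "")
    cat(" ", blk, ": ", paste(kv, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the eleven-feature vector of one lesion
#'
#' Runs the full feature set on a lesion ROI in a fixed order: circularity,
#' height-to-width ratio, margin spicules, margin coarseness, margin
#' indistinctness (stored divided by 1e6), margin lobulation, GLGCM energy,
#' entropy and grey mean, internal calcification count, and the long-axis
#' angle. A failing feature is recorded as `NA` with a flag rather than
#' aborting the lesion; the spicule overflow sentinel is kept as `Inf`.
#'
#' @param roi a [lesion_roi()].
#' @param config a [run_config()].
#' @param lesion_id identifier copied into the output row.
#' @return one-row data frame with the feature columns plus `lesion_id`
#'   and `flags` (semicolon-separated notes, empty when clean).
#' @export
extract_features <- function(roi, config = run_config(), lesion_id = NA_character_) {
  stopifnot(inherits(roi, "lesion_roi"))
  if (!inherits(config, "run_config")) stop("config must be a run_config object")
  flags <- character(0)
  grab <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(label, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  seq <- grab("radial", to_radial_sequence(roi$boundary, roi$centroid))
  g <- grab("glgcm", build_glgcm(roi, config$texture$L_s, config$texture$L_g,
                                 config$texture$quantization))
  cir <- grab("circularity", circularity(roi))
  hwr <- grab("hwr", height_width_ratio(roi))
  ms <- if (inherits(seq, "radial_sequence")) {
    grab("spicules", margin_spicules(seq))
  } else NA_real_
  mc <- if (inherits(seq, "radial_sequence")) {
    grab("coarseness", margin_coarseness(seq))
  } else NA_real_
  mi <- grab("indistinctness",
             margin_indistinctness(roi, config$margin$band_width) / 1e6)
  ml <- if (inherits(seq, "radial_sequence")) {
    grab("lobulation", margin_lobulation(
      seq, config$lobulation$median_frame, config$lobulation$poly_degree,
      config$lobulation$min_prominence))
  } else NA_real_
  en <- if (inherits(g, "glgcm")) grab("energy", glgcm_energy(g)) else NA_real_
  ent <- if (inherits(g, "glgcm")) grab("entropy", glgcm_entropy(g)) else NA_real_
  gm <- if (inherits(g, "glgcm")) {
    grab("grey_mean", glgcm_grey_mean(g, config$texture$gm_scale))
  } else NA_real_
  cal <- grab("calcifications", count_calcifications(
    roi, calc_params(config$calc$alpha, config$calc$struct_radius,
                     config$calc$min_blob_px, config$calc$connectivity,
                     config$calc$morph_order)))
  als <- grab("als", {
    a <- als_degrees(roi)
    if (isTRUE(attr(a, "low_confidence"))) {
      flags <<- c(flags, "als: low confidence (near-circular)")
    }
    as.numeric(a)
  })
  if (is.infinite(ms)) flags <- c(flags, "spicules: overflow sentinel")
  data.frame(
    lesion_id = lesion_id, circularity = cir, hwr = hwr, spicules = ms,
    coarseness_px = mc, indistinctness_e6 = mi,
    lobulation = as.numeric(ml), energy = en, entropy = ent, grey_mean = gm,
    calcifications = as.numeric(cal), als_deg = als,
    flags = paste(flags, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Run feature extraction over a manifest
#'
#' Reads a manifest CSV (`lesion_id`, `image_path`, `contour_path`,
#' `group`), loads each image and contour, extracts the feature vector, and
#' collects per-lesion errors instead of aborting the batch. Relative paths
#' in the manifest are resolved against the manifest's directory.
#'
#' @param manifest path to the manifest CSV, or an equivalent data frame.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, `features.csv` and
#'   `errors.csv` are written there.
#' @return list with `features` (data frame, one row per successful lesion,
#'   including the manifest `group`) and `errors` (data frame lesion_id /
#'   message).
#' @export
run_batch <- function(manifest, config = run_config(), out_dir = NULL) {
  base <- "."
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    base <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("lesion_id", "image_path", "contour_path", "group")
  if (!all(need %in% names(manifest))) {
    stop("malformed manifest: need columns ", paste(need, collapse = ", "))
  }
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  feats <- list(); errs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- load_image(resolve(row$image_path))
      ct <- read_contour(resolve(row$contour_path))
      roi <- if (is.logical(ct)) lesion_roi(img, mask = ct)
             else lesion_roi(img, contour = ct)
      fv <- extract_features(roi, config, lesion_id = row$lesion_id)
      fv$group <- row$group
      fv
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        lesion_id = row$lesion_id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- res
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 14)),
                    c("lesion_id", feature_columns, "flags", "group"))
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(lesion_id = character(0), message = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    utils::write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  }
  list(features = features, errors = errors)
}

#' Write a feature table as CSV
#'
#' The spicule overflow sentinel (`Inf`) is written as the string `"inf"`;
#' missing features are written as empty cells, with reasons in `flags`.
#'
#' @param features data frame from [run_batch()] or rows from
#'   [extract_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- features
  if ("spicules" %in% names(out)) {
    s <- out$spicules
    out$spicules <- ifelse(is.infinite(s), "inf",
                           ifelse(is.na(s), "", format(s, digits = 15)))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
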