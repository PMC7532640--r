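# Descriptive statistics and two-group comparison of feature tables.

feature_columns <- c("circularity", "hwr", "spicules", "coarseness_px",
                     "indistinctness_e6", "lobulation", "energy", "entropy",
                     "grey_mean", "calcifications", "als_deg")

#' Two independent samples t-test
#'
#' Pooled-variance Student t (default) or Welch t, with a two-sided p value.
#' Degenerate inputs are resolved explicitly: zero variance in both samples
#' with equal means gives `t = 0, p = 1`; zero variance in both with unequal
#' means gives `p = 0` flagged `degenerate`.
#'
#' @param x,y numeric samples (>= 2 finite values each).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Per-group feature summaries
#'
#' Sample mean and standard deviation (n - 1 denominator) of every feature
#' column, per group. Non-finite values (e.g. the spicule overflow sentinel)
#' are excluded and counted; a group with fewer than 2 usable values for a
#' feature is flagged rather than summarised.
#'
#' @param features data frame of feature vectors (columns as produced by
#'   [extract_features()]).
#' @param group character/factor vector of group labels, one per row.
#' @return data frame with columns feature, group, n_used, n_excluded,
#'   mean, sd, flag.
#' @export
describe_groups <- function(features, group) {
  stopifnot(nrow(features) == length(group))
  cols <- intersect(feature_columns, names(features))
  if (length(cols) == 0) stop("no feature columns found")
  out <- list()
  for (g in unique(as.character(group))) {
    sub <- features[group == g, , drop = FALSE]
    for (f in cols) {
      v <- sub[[f]]
      usable <- v[is.finite(v)]
      flag <- if (length(usable) < 2) "insufficient" else "ok"
      out[[length(out) + 1L]] <- data.frame(
        feature = f, group = g,
        n_used = length(usable), n_excluded = length(v) - length(usable),
        mean = if (flag == "ok") mean(usable) else NA_real_,
        sd = if (flag == "ok") stats::sd(usable) else NA_real_,
        flag = flag, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Two-group feature comparison
#'
#' One row per feature: per-group mean and SD, the t statistic, degrees of
#' freedom, two-sided p value, and the significance flag at `alpha`.
#' Non-finite feature values are excluded pairwise; rows where either group
#' retains fewer than 2 usable values are flagged, not computed.
#'
#' @param features data frame of feature vectors.
#' @param group vector of group labels with exactly two levels
#'   (conventionally `benign` / `malignant`).
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @param alpha significance level (default 0.05).
#' @return data frame of class `group_comparison`.
#' @export
compare_groups <- function(features, group, variant = c("pooled", "welch"),
                           alpha = 0.05) {
  variant <- match.arg(variant)
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2) stop("exactly two groups required, got ", length(lv))
  lv <- sort(lv)  # benign before malignant
  cols <- intersect(feature_columns, names(features))
  rows <- lapply(cols, function(f) {
    x <- features[[f]][group == lv[1]]
    y <- features[[f]][group == lv[2]]
    xu <- x[is.finite(x)]; yu <- y[is.finite(y)]
    base <- data.frame(
      feature = f,
      mean_1 = if (length(xu) >= 2) mean(xu) else NA_real_,
      sd_1 = if (length(xu) >= 2) stats::sd(xu) else NA_real_,
      mean_2 = if (length(yu) >= 2) mean(yu) else NA_real_,
      sd_2 = if (length(yu) >= 2) stats::sd(yu) else NA_real_,
      n_excluded = (length(x) - length(xu)) + (length(y) - length(yu)),
      stringsAsFactors = FALSE
    )
    if (length(xu) < 2 || length(yu) < 2) {
      cbind(base, t = NA_real_, df = NA_real_, p = NA_real_,
            significant = NA, flag = "insufficient")
    } else {
      tt <- two_sample_ttest(xu, yu, variant)
      cbind(base, t = tt$t, df = tt$df, p = tt$p,
            significant = is.finite(tt$p) && tt$p < alpha,
            flag = if (tt$degenerate) "degenerate" else "ok")
    }
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "mean_1"] <- paste0("mean_", lv[1])
  names(res)[names(res) == "sd_1"] <- paste0("sd_", lv[1])
  names(res)[names(res) == "mean_2"] <- paste0("mean_", lv[2])
  names(res)[names(res) == "sd_2"] <- paste0("sd_", lv[2])
  attr(res, "alpha") <- alpha
  attr(res, "variant") <- variant
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat("Two-group feature comparison (", attr(x, "variant"), " t-test, alpha = ",
      attr(x, "alpha"), ")\n\n", sep = "")
  y <- as.data.frame(x)
  mcols <- names(y)[grep("^(mean|sd)_", names(y))]
  g1 <- sub("^mean_", "", mcols[1]); g2 <- sub("^mean_", "", mcols[3])
  disp <- data.frame(
    feature = y$feature,
    g1 = sprintf("%.*f ± %.*f", digits, y[[mcols[1]]], digits, y[[mcols[2]]]),
    g2 = sprintf("%.*f ± %.*f", digits, y[[mcols[3]]], digits, y[[mcols[4]]]),
    p = signif(y$p, 3),
    sig = ifelse(is.na(y$significant), "", ifelse(y$significant, "*", ""))
  )
  names(disp)[2:3] <- c(g1, g2)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Read a pathology counts table
#'
#' @param path CSV with columns `group`, `type`, `count`; defaults to the
#'   cohort-composition fixture shipped with the package.
#' @return data frame.
#' @export
read_pathology_counts <- function(path = system.file("extdata",
                                                     "pathology_counts.csv",
                                                     package = "lesionmorph")) {
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "type", "count") %in% names(counts)))
  counts
}

#' Cohort composition summary
#'
#' Within-group percentages (rounded half-to-even to one decimal) and group
#' and overall totals for a pathology-type count table.
#'
#' @param counts data frame with columns `group`, `type`, `count`
#'   (positive integers).
#' @return list of class `pathology_summary`: `table` (group, type, n, pct),
#'   `group_totals` (named integer vector), `total` (integer).
#' @export
summarize_pathology <- function(counts) {
  stopifnot(all(c("group", "type", "count") %in% names(counts)))
  if (any(counts$count <= 0) || any(counts$count != round(counts$count))) {
    stop("counts must be positive integers")
  }
  totals <- tapply(counts$count, counts$group, sum)
  if (any(totals == 0)) stop("empty group")
  tab <- data.frame(
    group = counts$group, type = counts$type, n = as.integer(counts$count),
    pct = round(100 * counts$count / as.numeric(totals[counts$group]), 1),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab,
         group_totals = vapply(totals, as.integer, integer(1)),
         total = as.integer(sum(counts$count))),
    class = "pathology_summary"
  )
}

#' @export
print.pathology_summary <- function(x, ...) {
  cat("Cohort composition (n =", x$total, ")\n")
  for (g in names(x$group_totals)) {
    cat("\n", g, " (n = ", x$group_totals[[g]], ")\n", sep = "")
    sub <- x$table[x$table$group == g, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-35s %4d  %5.1f%%\n", sub$type[i], sub$n[i], sub$pct[i]))
    }
  }
  invisible(x)
}
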