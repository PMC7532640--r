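fake_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    lesion_id = sprintf("l%02d", seq_len(n)),
    circularity = stats::rnorm(n, 15, 2), hwr = stats::runif(n, 0.3, 1.2),
    spicules = stats::rlnorm(n, 3, 0.5), coarseness_px = stats::rexp(n, 2),
    indistinctness_e6 = stats::rlnorm(n, 0, 1),
    lobulation = stats::rpois(n, 6), energy = stats::runif(n, 0.01, 0.2),
    entropy = stats::rnorm(n, 2.3, 0.2), grey_mean = stats::runif(n),
    calcifications = stats::rpois(n, 3), als_deg = stats::runif(n, 0, 90),
    flags = "", stringsAsFactors = FALSE
  )
}

test_that("group descriptions use sample mean and n-1 standard deviation", {
  f <- fake_features(6)
  f$entropy <- c(1, 2, 3, 1, 2, 3)
  d <- describe_groups(f, rep(c("a", "b"), each = 3))
  row <- d[d$feature == "entropy" & d$group == "a", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  rb <- d[d$feature == "entropy" & d$group == "b", ]
  expect_equal(c(rb$mean, rb$sd), c(row$mean, row$sd))

  # matches a two-pass oracle on every feature
  f2 <- fake_features(40, seed = 9)
  g <- rep(c("benign", "malignant"), 20)
  d2 <- describe_groups(f2, g)
  for (i in seq_len(nrow(d2))) {
    v <- f2[[d2$feature[i]]][g == d2$group[i]]
    mu <- sum(v) / length(v)
    expect_equal(d2$mean[i], mu, tolerance = 1e-12)
    expect_equal(d2$sd[i], sqrt(sum((v - mu)^2) / (length(v) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("group descriptions are permutation invariant and flag sentinels", {
  f <- fake_features(20, seed = 3)
  f$spicules[c(2, 7)] <- Inf
  g <- rep(c("benign", "malignant"), 10)
  d1 <- describe_groups(f, g)
  perm <- sample(20)
  d2 <- describe_groups(f[perm, ], g[perm])
  expect_equal(d1[order(d1$feature, d1$group), c("mean", "sd")],
               d2[order(d2$feature, d2$group), c("mean", "sd")],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(d1$n_excluded[d1$feature == "spicules"]), 2)

  f$energy[g == "benign"] <- NA
  d3 <- describe_groups(f, g)
  expect_equal(d3$flag[d3$feature == "energy" & d3$group == "benign"],
               "insufficient")
})

test_that("t statistics match the textbook formulas and reference output", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- two_sample_ttest(x, y)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  d <- two_sample_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  e <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_false(e$degenerate)
  expect_equal(e$p, 1)

  for (s in 1:100) {
    set.seed(s)
    x <- stats::rnorm(sample(3:30, 1), stats::runif(1, -2, 2), stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(3:30, 1), stats::runif(1, -2, 2), stats::runif(1, 0.5, 3))
    for (v in c("pooled", "welch")) {
      got <- two_sample_ttest(x, y, v)
      ref <- oracle_ttest(x, y, v)
      expect_equal(got$t, ref$t, tolerance = 1e-10)
      expect_equal(got$df, ref$df, tolerance = 1e-10)
      expect_equal(got$p, ref$p, tolerance = 1e-10)
    }
  }

  # equal-size samples: pooled and Welch statistics coincide
  set.seed(1)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  expect_equal(two_sample_ttest(x, y, "pooled")$t,
               two_sample_ttest(x, y, "welch")$t, tolerance = 1e-12)

  expect_error(two_sample_ttest(1, c(1, 2)), ">= 2")
})

test_that("the t-test holds its nominal level under the null", {
  set.seed(2024)
  rej <- 0
  n_rep <- 600
  for (i in seq_len(n_rep)) {
    if (two_sample_ttest(stats::rnorm(20), stats::rnorm(20))$p < 0.05) {
      rej <- rej + 1
    }
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.025)
})

test_that("group comparison mirrors the feature-table schema", {
  f <- fake_features(40, seed = 5)
  g <- rep(c("benign", "malignant"), each = 20)
  f$lobulation[g == "malignant"] <- f$lobulation[g == "malignant"] + 8
  cmp <- compare_groups(f, g)
  expect_s3_class(cmp, "group_comparison")
  expect_equal(nrow(cmp), 11)
  expect_true(all(c("mean_benign", "sd_benign", "mean_malignant",
                    "sd_malignant", "t", "df", "p", "significant") %in% names(cmp)))
  lob <- cmp[cmp$feature == "lobulation", ]
  expect_true(lob$significant)
  expect_gt(lob$mean_malignant, lob$mean_benign)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1, na.rm = TRUE))
  expect_identical(unname(cmp$significant[!is.na(cmp$p)]),
                   unname(cmp$p[!is.na(cmp$p)] < 0.05))

  f$energy <- Inf
  cmp2 <- compare_groups(f, g)
  expect_equal(cmp2$flag[cmp2$feature == "energy"], "insufficient")
  expect_error(compare_groups(f, rep("benign", 40)), "two groups")
})

test_that("pathology summaries reproduce within-group percentages and totals", {
  counts <- read_pathology_counts()
  s <- summarize_pathology(counts)
  tab <- s$table
  expect_equal(tab$pct[tab$type == "Adenosis"], 38.5)
  expect_equal(tab$pct[tab$type == "Intraductal carcinoma in situ"], 37.5)
  expect_equal(unname(s$group_totals["benign"]), 174L)
  expect_equal(unname(s$group_totals["malignant"]), 32L)
  expect_equal(s$total, 206L)
  for (g in names(s$group_totals)) {
    expect_lt(abs(sum(tab$pct[tab$group == g]) - 100), 0.2)
  }
  expect_error(summarize_pathology(data.frame(group = "a", type = "t",
                                              count = 2.5)), "integers")
})
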