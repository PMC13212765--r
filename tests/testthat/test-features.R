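make_pair_tables <- function(y1, y2) {
  n <- length(y1)
  base <- data.frame(patient_id = rep("P1", n),
                     lesion_id = sprintf("L%02d", seq_len(n)),
                     volume_cm3 = 2, is_largest = seq_len(n) == 1,
                     is_biopsied = FALSE)
  list(first = cbind(base, f = y1), second = cbind(base, f = y2))
}

test_that("ICC equals an explicit ANOVA variance-components oracle", {
  # 5 lesions, two segmentations, hand-listed values
  y1 <- c(10.2, 8.1, 12.5, 9.9, 11.0)
  y2 <- c(10.6, 7.9, 12.1, 10.4, 10.7)
  tabs <- make_pair_tables(y1, y2)
  got <- compute_icc(tabs$first, tabs$second)
  expect_equal(unname(got["f"]), oracle_icc_aov(y1, y2), tolerance = 1e-10)
  # identical tables give ICC 1 exactly
  same <- compute_icc(tabs$first, tabs$first)
  expect_equal(unname(same["f"]), 1)
})

test_that("ICC is invariant to common affine rescaling and recovers a
           simulated true value", {
  set.seed(42)
  b <- rnorm(300, 5, 3)
  y1 <- b + rnorm(300, 0, 1)
  y2 <- b + rnorm(300, 0, 1)
  tabs <- make_pair_tables(y1, y2)
  icc_raw <- compute_icc(tabs$first, tabs$second)
  tabs2 <- make_pair_tables(3 * y1 - 7, 3 * y2 - 7)
  icc_scaled <- compute_icc(tabs2$first, tabs2$second)
  expect_equal(icc_raw, icc_scaled, tolerance = 1e-10)
  # true ICC = 9 / (9 + 1) = 0.9; estimate within +/- 0.03 at n = 1000
  set.seed(43)
  b <- rnorm(1000, 0, 3)
  tabs3 <- make_pair_tables(b + rnorm(1000), b + rnorm(1000))
  expect_lt(abs(compute_icc(tabs3$first, tabs3$second)["f"] - 0.9), 0.03)
})

test_that("ICC guards mismatched keys and tiny samples", {
  tabs <- make_pair_tables(1:5, 1:5)
  bad <- tabs$second
  bad$lesion_id[1] <- "LXX"
  expect_error(compute_icc(tabs$first, bad), "keys")
  tiny <- make_pair_tables(c(1, 2), c(1, 2))
  expect_warning(got <- compute_icc(tiny$first, tiny$second), "undefined")
  expect_true(is.na(got["f"]))
})

test_that("near-zero-variance rule matches its definition", {
  expect_true(near_zero_variance(rep(3.7, 100)))
  # 96 zeros + {1,2,3,4}: ratio 96 > 19 and 5% unique < 10%
  expect_true(near_zero_variance(c(rep(0, 96), 1, 2, 3, 4)))
  set.seed(1)
  expect_false(near_zero_variance(rnorm(100)))
  # conjunction: high ratio but many distinct values -> not flagged
  expect_false(near_zero_variance(c(rep(0, 60), seq_len(40))))
  expect_error(near_zero_variance(numeric(0)), "2 observations")
})

test_that("feature filter applies strict ICC > threshold AND non-NZV", {
  n <- 50
  set.seed(2)
  tab <- data.frame(patient_id = rep(sprintf("P%02d", 1:25), each = 2),
                    lesion_id = sprintf("L%02d", 1:n),
                    volume_cm3 = 2, is_largest = rep(c(TRUE, FALSE), 25),
                    is_biopsied = FALSE,
                    good = rnorm(n), borderline = rnorm(n),
                    weak = rnorm(n), flat = rep(1, n))
  icc <- c(good = 0.9, borderline = 0.85, weak = 0.8, flat = 0.95)
  out <- filter_features(tab, icc)
  expect_identical(
    out$report$retained,
    c(TRUE, FALSE, FALSE, FALSE))  # strict >0.85; flat removed by NZV
  expect_identical(feature_cols(out$table), "good")
  # report records the fate of every feature
  expect_identical(out$report$feature,
                   c("good", "borderline", "weak", "flat"))
  # NA ICC (no duplicate segmentation) passes the ICC criterion
  icc2 <- c(good = NA, borderline = 0.9, weak = 0.9, flat = NA)
  out2 <- filter_features(tab, icc2)
  expect_setequal(out2$report$feature[out2$report$retained],
                  c("good", "borderline", "weak"))
  # column permutation permutes, not changes, the retained set
  perm <- tab[, c(1:5, 8, 6, 9, 7)]
  out3 <- filter_features(perm, icc)
  expect_setequal(out3$report$feature[out3$report$retained], "good")
  expect_error(filter_features(tab, c(good = 0.1, borderline = 0.1,
                                      weak = 0.1, flat = 0.1)),
               class = "radstrat_no_features")
})

test_that("Yeo-Johnson matches its piecewise definition and is monotone", {
  x <- c(-3, -1.5, -0.2, 0, 0.4, 2, 10)
  for (l in c(-2, -0.5, 0, 1, 2, 3.5)) {
    expect_equal(yeo_johnson(x, l), oracle_yj(x, l), tolerance = 1e-12)
    grid <- seq(-6, 6, by = 0.01)
    expect_true(all(diff(yeo_johnson(grid, l)) > 0))
  }
  # identity at lambda = 1, log branch at lambda = 0
  expect_equal(yeo_johnson(x, 1), x, tolerance = 1e-12)
  expect_equal(yeo_johnson(exp(1) - 1, 0), 1, tolerance = 1e-12)
  expect_error(yeo_johnson(c(1, NA), 1), "finite")
})

test_that("profile-ML lambda agrees with a fine grid search and
           improves normality of log-normal data", {
  set.seed(7)
  x <- exp(rnorm(500))
  lam <- fit_yj_lambda(x)
  expect_lt(abs(lam - oracle_yj_lambda_grid(x)), 0.15)
  sw_raw <- shapiro.test(x)$statistic
  sw_tr <- shapiro.test(yeo_johnson(x, lam))$statistic
  expect_gt(sw_tr, sw_raw)
})

test_that("transform centers before Yeo-Johnson and replays exactly", {
  co <- generate_cohort(synth_config(n_patients = 60, n_features = 6,
                                     seed = 13))
  tab <- co$lesions
  feats <- feature_cols(tab)
  fitted <- transform_features(tab)
  # centering: mean subtracted on the pooled lesion population
  for (f in feats) {
    z <- (tab[[f]] - fitted$transform$center[f]) / fitted$transform$scale[f]
    expect_lt(abs(mean(z)), 1e-10)
  }
  # replay with stored constants reproduces the fitted output exactly
  replay <- apply_feature_transform(tab, fitted$transform)
  expect_identical(replay, fitted$table)
  # replay on held-out lesions uses only stored constants
  held <- tab[1:10, ]
  expect_equal(apply_feature_transform(held, fitted$transform),
               fitted$table[1:10, ], tolerance = 1e-12)
  # normality improves for most features
  co2 <- generate_cohort(synth_config(n_patients = 150, n_features = 10,
                                      seed = 21))
  skewed <- co2$lesions
  for (f in feature_cols(skewed)) skewed[[f]] <- exp(skewed[[f]] / 2)
  tr2 <- transform_features(skewed)
  p_before <- vapply(feature_cols(skewed), function(f)
    shapiro.test(sample(skewed[[f]], 500))$p.value, numeric(1))
  set.seed(1)
  improved <- vapply(feature_cols(skewed), function(f) {
    idx <- sample(nrow(skewed), 500)
    shapiro.test(tr2$table[[f]][idx])$p.value >=
      shapiro.test(skewed[[f]][idx])$p.value
  }, logical(1))
  expect_gte(mean(improved), 0.8)
})

test_that("zero pooled SD is a hard error", {
  tab <- data.frame(patient_id = "P1", lesion_id = c("L1", "L2"),
                    volume_cm3 = 2, is_largest = c(TRUE, FALSE),
                    is_biopsied = FALSE, f = c(1, 1))
  expect_error(transform_features(tab), "zero standard deviation")
})
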