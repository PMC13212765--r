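test_that("odds ratios reproduce the published univariable estimates", {
  pub <- published_contingency()
  for (i in seq_len(nrow(pub))) {
    est <- odds_ratio_wald(pub$exposed_case[i], pub$exposed_ref[i],
                           pub$unexposed_case[i], pub$unexposed_ref[i])
    if (pub$printed_or[i] == 0) {
      expect_true(est$degenerate)
      expect_equal(est$estimate, 0)
    } else {
      expect_equal(round(est$estimate, 2), pub$printed_or[i])
      expect_equal(round(est$ci_low, 2), pub$printed_ci_low[i])
      expect_equal(round(est$ci_high, 2), pub$printed_ci_high[i])
    }
  }
})

test_that("odds ratio algebra: balanced table, reciprocity, matrix input", {
  bal <- odds_ratio_wald(10, 10, 10, 10)
  expect_equal(bal$estimate, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    ct <- sample(5:80, 4)
    a <- odds_ratio_wald(ct[1], ct[2], ct[3], ct[4])
    b <- odds_ratio_wald(ct[2], ct[1], ct[4], ct[3])
    expect_equal(a$estimate, 1 / b$estimate, tolerance = 1e-12)
    expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-12)
  }
  m <- odds_ratio_wald(rbind(c(108, 29), c(125, 63)))
  expect_equal(round(m$estimate, 2), 1.88)
  # Haldane correction gives a finite estimate for a zero cell
  h <- odds_ratio_wald(0, 21, 47, 153, haldane = TRUE)
  expect_false(h$degenerate)
  expect_gt(h$estimate, 0)
})

test_that("group comparison picks the declared test battery", {
  # chi-square equals the hand-computed sum((O-E)^2/E)
  x <- rep(c("a", "b"), c(30, 30))
  g <- rep(c("g1", "g2"), 30)
  tab <- matrix(c(20, 10, 10, 20), 2)
  O <- c(tab); E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  val <- group_compare(rep(c("a", "b", "a", "b"), c(20, 10, 10, 20)),
                       rep(c("g1", "g2"), each = 30))
  expect_equal(val$test, "chi-square")
  expect_equal(val$statistic, sum((O - c(E))^2 / c(E)), tolerance = 1e-10)
  # identical proportions: statistic 0
  same <- group_compare(rep(c("a", "b"), 40), rep(c("g1", "g2"), each = 40))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  # sparse table falls back to Fisher
  sparse <- group_compare(rep(c("a", "b"), c(38, 2)),
                          rep(c("g1", "g2"), 20))
  expect_equal(sparse$test, "fisher")
  # clear normal shift: Shapiro gate selects the t-test
  set.seed(5)
  v <- c(rnorm(50), rnorm(50, 2))
  gg <- rep(c("A", "B"), each = 50)
  tt <- group_compare(v, gg)
  expect_equal(tt$test, "t")
  expect_lt(tt$p_value, 0.001)
  # skewed data routes to Mann-Whitney
  sk <- group_compare(c(exp(rnorm(50)), exp(rnorm(50))), gg)
  expect_equal(sk$test, "mann-whitney")
  # three numeric groups go to Kruskal-Wallis
  kw <- group_compare(rnorm(60), rep(c("A", "B", "C"), 20))
  expect_equal(kw$test, "kruskal-wallis")
  expect_error(group_compare(1:3, c("A", "B", "B")), "at least 2")
})

test_that("univariable logistic OR equals the contingency OR", {
  set.seed(6)
  for (i in 1:15) {
    ct <- sample(10:60, 4)  # exposed-case, exposed-ref, unexp-case, unexp-ref
    dat <- expand_counts(c("no", "yes"), c(ct[3], ct[1]), c(ct[4], ct[2]))
    scr <- univariable_screen(dat, "case", "exposure")
    or <- odds_ratio_wald(ct[1], ct[2], ct[3], ct[4])
    expect_equal(scr$estimate, or$estimate, tolerance = 1e-6)
    expect_equal(scr$ci_low, or$ci_low, tolerance = 1e-5)
  }
})

test_that("categorical screening reproduces the published cluster odds
           ratios from the contingency counts", {
  # three merged largest-lesion clusters vs molecular status, counts as
  # published; reference level M3+M4
  dat <- expand_counts(c("M3+M4", "M1", "M2+M5"),
                       case_counts = c(101, 39, 93),
                       ref_counts = c(64, 6, 22))
  scr <- univariable_screen(dat, "case", "exposure",
                            ref_levels = list(exposure = "M3+M4"))
  m1 <- scr[grepl("M1", scr$term), ]
  m25 <- scr[grepl("M2", scr$term), ]
  expect_equal(round(m1$estimate, 2), 4.12)
  expect_equal(round(m1$ci_low, 2), 1.65)
  expect_equal(round(m1$ci_high, 2), 10.28)
  expect_equal(round(m25$estimate, 2), 2.68)
  expect_equal(round(m25$ci_low, 2), 1.53)
  expect_equal(round(m25$ci_high, 2), 4.69)
})

test_that("perfect separation is flagged, not fatal", {
  dat <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                    case = c(rep(0L, 20), rep(1L, 20)))
  scr <- suppressWarnings(univariable_screen(dat, "case", "x"))
  expect_true(scr$degenerate)
})

test_that("a pure-noise candidate is flagged at about the nominal 5% rate", {
  set.seed(7)
  hits <- vapply(1:100, function(i) {
    dat <- data.frame(x = rnorm(300), case = rbinom(300, 1, 0.5))
    univariable_screen(dat, "case", "x")$significant
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.08)
})

test_that("backward stepwise retains the true predictor and is
           order-invariant", {
  set.seed(8)
  n <- 500
  dat <- data.frame(x_true = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n))
  dat$case <- rbinom(n, 1, plogis(dat$x_true))
  fit <- stepwise_logistic(dat, "case",
                           c("x_true", "n1", "n2", "n3", "n4"))
  expect_true("x_true" %in% fit$retained)
  # candidate ordering does not change the result
  fit2 <- stepwise_logistic(dat, "case",
                            c("n4", "n2", "x_true", "n3", "n1"))
  expect_identical(fit$retained, fit2$retained)
  expect_identical(fit$trace$candidate, fit2$trace$candidate)
  # elimination trace records step numbers
  expect_equal(fit$trace$step, seq_len(nrow(fit$trace)))
})

test_that("stepwise with a single candidate equals the univariable fit and
           collinear candidates are dropped with a warning", {
  set.seed(9)
  dat <- data.frame(x = rnorm(200))
  dat$case <- rbinom(200, 1, plogis(dat$x))
  single <- stepwise_logistic(dat, "case", "x")
  uni <- univariable_screen(dat, "case", "x")
  expect_equal(single$estimates$estimate, uni$estimate, tolerance = 1e-10)
  dat$x2 <- 2 * dat$x  # perfectly collinear
  expect_warning(fit <- stepwise_logistic(dat, "case", c("x", "x2")),
                 "collinear")
  expect_length(fit$retained, 1)
  expect_true("rank deficiency" %in% fit$trace$reason)
})

test_that("Kaplan-Meier estimates and log-rank match the product-limit and
           risk-set oracles", {
  # no events: survival identically 1, p undefined
  none <- km_logrank(time = c(3, 5, 7, 9), event = rep(0, 4),
                     group = c("A", "A", "B", "B"))
  expect_true(all(none$fit$surv == 1))
  expect_true(is.na(none$p_value))
  # 5 subjects, one event at t = 5, none censored before: S(5) = 0.8
  km <- km_logrank(time = c(5, 6, 7, 8, 9), event = c(1, 0, 0, 0, 0),
                   group = rep("A", 5))
  expect_equal(summary(km$fit, times = 5)$surv, 0.8)
  # two-group fixture vs explicit risk-set enumeration
  time <- c(2, 3, 3, 5, 8, 1, 4, 4, 6, 9)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("A", "B"), each = 5)
  lr <- km_logrank(time, event, group)
  expect_equal(lr$chisq, oracle_logrank(time, event, group),
               tolerance = 1e-8)
})

test_that("log-rank p under label permutation is approximately uniform", {
  set.seed(11)
  time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.8)
  ps <- replicate(200, {
    g <- sample(rep(c("A", "B"), 30))
    km_logrank(time, event, g)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cox regression recovers a known hazard ratio and flags
           degenerate covariates", {
  set.seed(12)
  hrs <- covered <- numeric(20)
  for (i in 1:20) {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.1 * exp(log(2) * x))
    t_cn <- runif(n, 0, 40)
    d <- data.frame(os_months = pmin(t_ev, t_cn),
                    os_event = as.integer(t_ev <= t_cn), x = x)
    est <- cox_fit(d, covariates = "x")
    hrs[i] <- est$estimate
    covered[i] <- est$ci_low <= 2 && 2 <= est$ci_high
  }
  expect_lt(abs(mean(hrs) - 2) / 2, 0.1)
  expect_gte(mean(covered), 0.9)
  # constant covariate: degenerate flag rather than an error
  d0 <- data.frame(os_months = rexp(30, 0.1), os_event = 1,
                   z = rep(1, 30))
  expect_true(all(cox_fit(d0, covariates = "z")$degenerate))
})

test_that("a positive dispersion log-hazard in the generator yields a
           fitted hazard ratio above 1", {
  cfg <- synth_config(n_patients = 400, seed = 14, os_loghr_range = 0.3)
  co <- generate_cohort(cfg)
  dat <- merge(co$patients, co$truth[, c("patient_id",
                                         "true_dispersion_range")])
  names(dat)[names(dat) == "true_dispersion_range"] <- "dispersion_range"
  est <- cox_fit(dat, covariates = "dispersion_range")
  expect_gt(est$estimate, 1)
  expect_lt(est$p_value, 0.05)
})
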