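#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' For counts `a` (exposed cases), `b` (exposed references), `c`
#' (unexposed cases), `d` (unexposed references):
#' `OR = (a*d)/(b*c)` with the Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald p-value
#' on the log odds ratio. A zero cell makes the estimate degenerate: the
#' OR is reported as 0 or `Inf` according to direction, the interval is
#' undefined, and the `degenerate` flag is set. The optional
#' Haldane-Anscombe correction adds 0.5 to every cell (off by default, so
#' degenerate tables print as `0 (-)`).
#'
#' @param a,b,c,d Nonnegative counts; `a` may also be a 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param alpha Two-sided level (default 0.05, z = 1.959964).
#' @param haldane Apply the +0.5 continuity correction to all cells.
#' @return Data frame of class `effect_estimate`: `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `degenerate`.
#' @export
odds_ratio_wald <- function(a, b = NULL, c = NULL, d = NULL, alpha = 0.05,
                            haldane = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be nonnegative with positive total")
  if (haldane) counts <- counts + 0.5
  zero <- any(counts == 0)
  z <- stats::qnorm(1 - alpha / 2)
  if (zero) {
    est <- if (counts[1] == 0 || counts[4] == 0) 0 else Inf
    out <- data.frame(estimate = est, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      degenerate = TRUE)
  } else {
    or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
    se <- sqrt(sum(1 / counts))
    p <- 2 * stats::pnorm(-abs(log(or)) / se)
    out <- data.frame(estimate = or,
                      ci_low = or * exp(-z * se),
                      ci_high = or * exp(z * se),
                      p_value = p,
                      degenerate = FALSE)
  }
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Compare a variable across groups with the pre-declared test battery
#'
#' Categorical variables: chi-square test without continuity correction,
#' falling back to Fisher's exact test when any expected cell count is
#' below 5 (the fallback is reported in the returned test name). Numeric
#' variables with two groups: Shapiro-Wilk normality gate on each group
#' (both p > 0.05 selects Student's t-test, otherwise the Mann-Whitney
#' test). Numeric variables with more than two groups: Kruskal-Wallis.
#'
#' @param values Vector of observations (numeric, or any type for
#'   categorical).
#' @param groups Group labels, same length; at least 2 groups with at
#'   least 2 observations each.
#' @param type `"auto"` (numeric values -> numeric battery), or force
#'   `"categorical"` / `"numeric"`.
#' @return List: `test` (name of the test actually used), `statistic`,
#'   `p_value`.
#' @export
group_compare <- function(values, groups,
                          type = c("auto", "categorical", "numeric")) {
  type <- match.arg(type)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(droplevels(as.factor(groups[keep])))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (min(table(groups)) < 2) stop("each group needs at least 2 observations")
  if (type == "auto")
    type <- if (is.numeric(values)) "numeric" else "categorical"
  if (type == "categorical") {
    tab <- table(values, groups)
    suppressWarnings(cs <- stats::chisq.test(tab, correct = FALSE))
    if (any(cs$expected < 5)) {
      ft <- stats::fisher.test(tab)
      return(list(test = "fisher", statistic = NA_real_,
                  p_value = ft$p.value))
    }
    return(list(test = "chi-square",
                statistic = unname(cs$statistic),
                p_value = cs$p.value))
  }
  if (nlevels(groups) > 2) {
    kw <- stats::kruskal.test(values, groups)
    return(list(test = "kruskal-wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value))
  }
  sw_p <- tapply(values, groups, function(v)
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) 0
    else stats::shapiro.test(v)$p.value)
  if (all(sw_p > 0.05)) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values ~ groups))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value)
  }
}

# Wald estimates for a fitted binomial glm, one row per non-intercept term
glm_wald_table <- function(fit, alpha = 0.05, model = "univariable") {
  z <- stats::qnorm(1 - alpha / 2)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  degenerate <- abs(sm[, 1]) > 10 | sm[, 2] > 100
  est <- exp(sm[, 1])
  est[degenerate & sm[, 1] < 0] <- 0
  est[degenerate & sm[, 1] > 0] <- Inf
  data.frame(term = rownames(sm),
             model = model,
             estimate = unname(est),
             ci_low = ifelse(degenerate, NA_real_,
                             unname(exp(sm[, 1] - z * sm[, 2]))),
             ci_high = ifelse(degenerate, NA_real_,
                              unname(exp(sm[, 1] + z * sm[, 2]))),
             p_value = unname(sm[, 4]),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' Univariable logistic screening of candidate predictors
#'
#' Fits one single-covariate logistic model per candidate. Categorical
#' candidates are expanded against their declared reference level and the
#' candidate-level p-value is the likelihood-ratio test of the whole
#' block; single-coefficient candidates use the Wald p-value. For a binary
#' candidate the fitted odds ratio equals the contingency-table odds
#' ratio. Perfect separation is flagged (`degenerate`), not an error.
#'
#' @param data Data frame.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param candidates Character vector of candidate columns.
#' @param ref_levels Named list/character vector of reference levels for
#'   categorical candidates, e.g. `list(cluster_m = "M3+M4")`.
#' @param alpha Significance level used to flag candidates (default 0.05).
#' @return Data frame with one row per term: `candidate`, `term`,
#'   `estimate` (OR), `ci_low`, `ci_high`, `p_value` (per-term Wald),
#'   `candidate_p` (block-level), `significant`, `n`, `degenerate`.
#' @export
univariable_screen <- function(data, outcome, candidates,
                               ref_levels = list(), alpha = 0.05) {
  data <- relevel_candidates(data, candidates, ref_levels)
  out <- lapply(candidates, function(cand) {
    cc <- stats::complete.cases(data[, c(outcome, cand)])
    dat <- data[cc, , drop = FALSE]
    fit <- stats::glm(stats::as.formula(
      paste(outcome, "~", sprintf("`%s`", cand))),
      data = dat, family = stats::binomial())
    tab <- glm_wald_table(fit)
    cp <- block_p(fit, dat, outcome, cand)
    tab$candidate <- cand
    tab$candidate_p <- cp
    tab$significant <- cp < alpha
    tab$n <- sum(cc)
    tab
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("candidate", "term", "model", "estimate", "ci_low", "ci_high",
          "p_value", "candidate_p", "significant", "n", "degenerate")]
}

relevel_candidates <- function(data, candidates, ref_levels) {
  for (cand in candidates) {
    if (is.character(data[[cand]]) || is.logical(data[[cand]]))
      data[[cand]] <- factor(data[[cand]])
    if (cand %in% names(ref_levels) && is.factor(data[[cand]]))
      data[[cand]] <- stats::relevel(data[[cand]],
                                     ref = ref_levels[[cand]])
  }
  data
}

# block-level p for one candidate in a fitted model: Wald for 1 df,
# likelihood-ratio against the model without the candidate otherwise
block_p <- function(fit, data, outcome, cand) {
  nterms <- sum(attr(fit$terms, "term.labels") == cand)
  co <- summary(fit)$coefficients
  rows <- grep(paste0("^`?", cand), rownames(co))
  if (length(rows) == 1) return(co[rows, 4])
  d1 <- stats::drop1(fit, scope = stats::as.formula(
    paste("~", sprintf("`%s`", cand))), test = "Chisq")
  d1[["Pr(>Chi)"]][2]
}

#' Backward stepwise logistic regression over screened candidates
#'
#' Starts from the model containing every screened candidate and
#' iteratively removes the candidate with the largest p-value above
#' `p_remove` (Wald p for single-coefficient candidates,
#' likelihood-ratio p for whole categorical blocks); ties are broken by
#' candidate name. Rank-deficient (aliased) candidates are removed first
#' with a logged degeneracy note. The elimination trace records the step
#' at which each candidate left the model.
#'
#' @param data Data frame (complete cases over outcome and candidates are
#'   used, mirroring a complete-case multivariable analysis).
#' @param outcome Binary (0/1) outcome column name.
#' @param candidates Screened candidate columns.
#' @param ref_levels Reference levels for categorical candidates.
#' @param p_remove Removal threshold (default 0.05).
#' @return List of class `stepwise_fit`: `model` (final `glm`),
#'   `estimates` (adjusted ORs for the retained terms), `retained`,
#'   `trace` (data frame `candidate`, `step`, `p_value`, `reason`).
#' @export
stepwise_logistic <- function(data, outcome, candidates,
                              ref_levels = list(), p_remove = 0.05) {
  if (length(candidates) == 0) stop("need at least one screened candidate")
  data <- relevel_candidates(data, candidates, ref_levels)
  cc <- stats::complete.cases(data[, c(outcome, candidates), drop = FALSE])
  dat <- data[cc, , drop = FALSE]
  current <- sort(candidates)
  trace <- data.frame(candidate = character(), step = integer(),
                      p_value = numeric(), reason = character(),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fml <- stats::as.formula(paste(
      outcome, "~", paste(sprintf("`%s`", current), collapse = " + ")))
    fit <- suppressWarnings(
      stats::glm(fml, data = dat, family = stats::binomial()))
    # aliased candidates (collinearity) leave first
    if (anyNA(stats::coef(fit))) {
      alias_terms <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      victim <- current[vapply(current, function(cand)
        any(grepl(paste0("^`?", cand), alias_terms)), logical(1))][1]
      warning("candidate ", victim,
              " is collinear with the others and was removed")
      step <- step + 1L
      trace <- rbind(trace, data.frame(candidate = victim, step = step,
                                       p_value = NA_real_,
                                       reason = "rank deficiency"))
      current <- setdiff(current, victim)
      if (length(current) == 0) break
      next
    }
    ps <- vapply(current, function(cand)
      block_p(fit, dat, outcome, cand), numeric(1))
    worst <- max(ps)
    if (worst <= p_remove) break
    # largest p, ties by name (current is kept sorted)
    victim <- current[which(ps == worst)][1]
    step <- step + 1L
    trace <- rbind(trace, data.frame(candidate = victim, step = step,
                                     p_value = worst,
                                     reason = "p above threshold"))
    current <- setdiff(current, victim)
    if (length(current) == 0) break
  }
  if (length(current) == 0) {
    out <- list(model = NULL, estimates = NULL, retained = character(),
                trace = trace)
    class(out) <- "stepwise_fit"
    return(out)
  }
  est <- glm_wald_table(fit, model = "multivariable")
  out <- list(model = fit, estimates = est, retained = current,
              trace = trace, n = nrow(dat))
  class(out) <- "stepwise_fit"
  out
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backward stepwise logistic model\n")
  if (nrow(x$trace)) {
    cat("removed:\n")
    print(x$trace, row.names = FALSE)
  }
  if (is.null(x$model)) {
    cat("no candidates retained\n")
  } else {
    cat("retained:", paste(x$retained, collapse = ", "), "\n")
    print(x$estimates, row.names = FALSE)
  }
  invisible(x)
}
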