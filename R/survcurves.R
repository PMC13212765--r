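#' Kaplan-Meier curves with log-rank comparison
#'
#' Product-limit survival estimates per group with the log-rank chi-square
#' test over event times, via the `survival` package. With no events in any
#' group the survival curves are identically 1 and the p-value is
#' undefined (`NA`).
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (1 = disease-related death, 0 = censored).
#' @param group Group labels (at least one record per group).
#' @return List of class `km_logrank`: `fit` (a `survfit` object),
#'   `chisq`, `df`, `p_value`, `n_events`.
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  group <- as.factor(group)
  if (any(table(group) < 1)) stop("need at least one record per group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0 || nlevels(group) < 2) {
    out <- list(fit = fit, chisq = NA_real_, df = max(nlevels(group) - 1, 0),
                p_value = NA_real_, n_events = sum(event))
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(sd$n) - 1
    out <- list(fit = fit, chisq = unname(sd$chisq), df = df,
                p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                n_events = sum(event))
  }
  class(out) <- "km_logrank"
  out
}

#' @export
print.km_logrank <- function(x, ...) {
  print(x$fit)
  cat("log-rank chi-square:", round(x$chisq, 3), "on", x$df,
      "df, p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Cox proportional-hazards model with Wald intervals
#'
#' Partial-likelihood Cox regression (Efron tie handling) returning hazard
#' ratios with Wald 95% confidence intervals per term. A covariate that is
#' constant, or a monotone likelihood (infinite coefficient), is flagged
#' `degenerate` rather than raising.
#'
#' @param data Data frame with follow-up columns and covariates.
#' @param time,event Column names of the follow-up time and event
#'   indicator.
#' @param covariates Character vector of covariate column names.
#' @param alpha Two-sided level (default 0.05).
#' @return Data frame of class `effect_estimate`: `term`, `estimate` (HR),
#'   `ci_low`, `ci_high`, `p_value`, `degenerate`, plus the fitted model in
#'   the `fit` attribute.
#' @export
cox_fit <- function(data, time = "os_months", event = "os_event",
                    covariates, alpha = 0.05) {
  cc <- stats::complete.cases(data[, c(time, event, covariates)])
  dat <- data[cc, , drop = FALSE]
  const <- vapply(covariates, function(v)
    length(unique(dat[[v]])) < 2, logical(1))
  if (all(const)) {
    out <- data.frame(term = covariates, estimate = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    class(out) <- c("effect_estimate", "data.frame")
    return(out)
  }
  fml <- stats::as.formula(paste(
    sprintf("survival::Surv(%s, %s)", time, event), "~",
    paste(sprintf("`%s`", covariates[!const]), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  z <- stats::qnorm(1 - alpha / 2)
  sm <- summary(fit)$coefficients
  degenerate <- !is.finite(sm[, "se(coef)"]) | sm[, "se(coef)"] > 100 |
    abs(sm[, "coef"]) > 10
  out <- data.frame(term = rownames(sm),
                    estimate = unname(exp(sm[, "coef"])),
                    ci_low = unname(exp(sm[, "coef"] - z * sm[, "se(coef)"])),
                    ci_high = unname(exp(sm[, "coef"] + z * sm[, "se(coef)"])),
                    p_value = unname(sm[, "Pr(>|z|)"]),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  if (any(const)) {
    out <- rbind(out, data.frame(term = covariates[const],
                                 estimate = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p_value = NA_real_,
                                 degenerate = TRUE))
  }
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimate", "data.frame")
  out
}
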