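#' Inter-segmentation intraclass correlation per feature
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)) between two segmentations of the same lesions, the standard
#' reproducibility measure for radiomic features:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{k = 2} raters (segmentations), \eqn{n} lesions, and mean
#' squares from the two-way layout (rows = lesions, columns = raters).
#'
#' @param first,second Lesion feature tables sharing identical
#'   `(patient_id, lesion_id)` keys.
#' @return Named numeric vector of ICC values, one per feature. With fewer
#'   than 3 lesions the ICC is undefined and `NA` is returned with a
#'   warning.
#' @export
compute_icc <- function(first, second) {
  k1 <- paste(first$patient_id, first$lesion_id)
  k2 <- paste(second$patient_id, second$lesion_id)
  if (length(k1) != length(k2) || anyDuplicated(k1) || !setequal(k1, k2))
    stop("the two tables must share identical (patient_id, lesion_id) keys")
  second <- second[match(k1, k2), , drop = FALSE]
  feats <- intersect(feature_cols(first), feature_cols(second))
  n <- length(k1)
  if (n < 3) {
    warning("ICC undefined with fewer than 3 lesions; returning NA")
    return(stats::setNames(rep(NA_real_, length(feats)), feats))
  }
  vapply(feats, function(f) icc21(first[[f]], second[[f]]), numeric(1))
}

# ICC(2,1) from closed-form two-way ANOVA mean squares (k = 2 raters)
icc21 <- function(y1, y2) {
  y <- cbind(y1, y2)
  n <- nrow(y); k <- 2
  rm_ <- rowMeans(y); cm <- colMeans(y); gm <- mean(y)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Near-zero-variance flag for a feature
#'
#' A feature is flagged as near-zero-variance when the ratio of the
#' frequency of its most common value to that of its second most common
#' value exceeds `freq_ratio` AND the fraction of distinct values is below
#' `unique_frac`. Constant vectors are always flagged.
#'
#' @param values Numeric vector with at least 2 observations.
#' @param freq_ratio Frequency-ratio threshold (default 19, i.e. 95/5).
#' @param unique_frac Distinct-value fraction threshold (default 0.10).
#' @return `TRUE` if the feature is near-zero-variance.
#' @export
near_zero_variance <- function(values, freq_ratio = 19, unique_frac = 0.10) {
  if (length(values) < 2) stop("need at least 2 observations")
  tab <- sort(table(values), decreasing = TRUE)
  if (length(tab) == 1) return(TRUE)
  ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
  uniq <- length(tab) / length(values)
  ratio > freq_ratio && uniq < unique_frac
}

#' Filter radiomic features on reproducibility and informativeness
#'
#' Retains exactly the features whose inter-segmentation ICC exceeds
#' `icc_threshold` (strict) and which are not near-zero-variance. Features
#' with no duplicate measurement (`NA` ICC) pass the ICC criterion, since
#' only a subsample of lesions is typically re-segmented.
#'
#' @param table Lesion feature table.
#' @param icc Named per-feature ICC vector, as from [compute_icc()].
#' @param icc_threshold Strict lower bound on the ICC (default 0.85).
#' @param freq_ratio,unique_frac Passed to [near_zero_variance()].
#' @return List with `table` (filtered) and `report`, a data frame
#'   recording the fate (`icc`, `nzv`, `retained`) of every feature. An
#'   error of class `radstrat_no_features` is raised if nothing survives;
#'   the report is attached to the condition.
#' @export
filter_features <- function(table, icc, icc_threshold = 0.85,
                            freq_ratio = 19, unique_frac = 0.10) {
  feats <- feature_cols(table)
  icc_f <- icc[feats]
  names(icc_f) <- feats
  nzv <- vapply(feats, function(f)
    near_zero_variance(table[[f]], freq_ratio, unique_frac), logical(1))
  pass_icc <- is.na(icc_f) | icc_f > icc_threshold
  retained <- pass_icc & !nzv
  report <- data.frame(feature = feats,
                       icc = unname(icc_f),
                       nzv = unname(nzv),
                       retained = unname(retained),
                       stringsAsFactors = FALSE)
  if (!any(retained)) {
    cond <- structure(
      class = c("radstrat_no_features", "error", "condition"),
      list(message = "no features retained by the ICC/NZV filter",
           call = sys.call(-1), report = report))
    stop(cond)
  }
  keep <- c("patient_id", "lesion_id", "volume_cm3",
            "is_largest", "is_biopsied")
  keep <- intersect(keep, names(table))
  list(table = table[, c(keep, feats[retained]), drop = FALSE],
       report = report)
}

#' Yeo-Johnson transformation
#'
#' Power transformation defined for any real input:
#' \deqn{\psi(x,\lambda) = ((x+1)^\lambda - 1)/\lambda} for \eqn{x \ge 0,
#' \lambda \ne 0}; \eqn{\log(x+1)} for \eqn{x \ge 0, \lambda = 0};
#' \eqn{-((-x+1)^{2-\lambda} - 1)/(2-\lambda)} for \eqn{x < 0,
#' \lambda \ne 2}; \eqn{-\log(-x+1)} for \eqn{x < 0, \lambda = 2}.
#'
#' @param values Finite numeric vector.
#' @param lambda Transformation parameter.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(values, lambda) {
  if (any(!is.finite(values))) stop("non-finite inputs")
  out <- numeric(length(values))
  pos <- values >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(values[pos])
  } else {
    out[pos] <- ((values[pos] + 1)^lambda - 1) / lambda
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -log1p(-values[!pos])
  } else {
    out[!pos] <- -((-values[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

#' Fit the Yeo-Johnson parameter by profile maximum likelihood
#'
#' Maximizes the Gaussian profile log-likelihood of the transformed sample,
#' including the Jacobian term
#' \eqn{(\lambda - 1)\sum \mathrm{sign}(x)\log(|x|+1)}, over
#' \eqn{\lambda \in [-5, 5]} by bounded one-dimensional optimization
#' (golden-section search with successive parabolic interpolation,
#' tolerance `1e-6`).
#'
#' @param values Finite numeric vector.
#' @param lower,upper Search bounds for `lambda`.
#' @return The fitted `lambda`.
#' @export
fit_yj_lambda <- function(values, lower = -5, upper = 5) {
  if (any(!is.finite(values))) stop("non-finite inputs")
  opt <- stats::optimize(function(l) yj_loglik(values, l),
                         interval = c(lower, upper),
                         maximum = TRUE, tol = 1e-6)
  opt$maximum
}

#' Profile log-likelihood of the Yeo-Johnson transformation
#'
#' @param values Finite numeric vector.
#' @param lambda Transformation parameter.
#' @return The Gaussian profile log-likelihood (Jacobian included).
#' @export
yj_loglik <- function(values, lambda) {
  z <- yeo_johnson(values, lambda)
  n <- length(z)
  s2 <- sum((z - mean(z))^2) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(values) * log1p(abs(values)))
}

#' Center-scale then Yeo-Johnson normalize a feature table
#'
#' Per feature: subtract the mean and divide by the standard deviation
#' computed over the pooled lesion population, then apply the Yeo-Johnson
#' transformation with the profile-ML `lambda`. The fitted constants are
#' stored so the identical transform can be replayed on new lesions with
#' [apply_feature_transform()] (no re-fitting).
#'
#' @param table Filtered lesion feature table.
#' @return List with `table` (transformed) and `transform`, a
#'   `feature_transform` object holding `center`, `scale` and `lambda` per
#'   feature.
#' @export
transform_features <- function(table) {
  feats <- feature_cols(table)
  center <- scale_ <- lambda <- stats::setNames(numeric(length(feats)), feats)
  for (f in feats) {
    center[f] <- mean(table[[f]])
    scale_[f] <- stats::sd(table[[f]])
    if (!is.finite(scale_[f]) || scale_[f] == 0)
      stop("zero standard deviation for feature ", f,
           " (should have been removed by the near-zero-variance filter)")
    z <- (table[[f]] - center[f]) / scale_[f]
    lambda[f] <- fit_yj_lambda(z)
  }
  tr <- structure(list(center = center, scale = scale_, lambda = lambda),
                  class = "feature_transform")
  list(table = apply_feature_transform(table, tr), transform = tr)
}

#' Replay a stored feature transform on a lesion table
#'
#' Applies the stored center/scale constants and Yeo-Johnson `lambda` of a
#' fitted [transform_features()] to (possibly new) lesions.
#'
#' @param table Lesion feature table containing the transform's features.
#' @param transform A `feature_transform` object.
#' @return The transformed table.
#' @export
apply_feature_transform <- function(table, transform) {
  stopifnot(inherits(transform, "feature_transform"))
  for (f in names(transform$center)) {
    if (!f %in% names(table)) stop("feature ", f, " missing from table")
    z <- (table[[f]] - transform$center[f]) / transform$scale[f]
    table[[f]] <- yeo_johnson(z, transform$lambda[f])
  }
  table
}
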