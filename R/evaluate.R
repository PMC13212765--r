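#' Area under the ROC curve (rank statistic)
#'
#' Rank-based AUROC with midrank tie handling, equal to the normalized
#' Mann-Whitney U statistic: the probability that a random positive scores
#' above a random negative, counting ties as 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Monte Carlo cross-validated AUROC of nested feature sets
#'
#' Repeated random train/test splitting: in each of `n_splits` iterations
#' a stratified `1 - test_fraction` / `test_fraction` partition is drawn,
#' an unpenalized logistic model is fitted on the training part for each
#' feature set, and the AUROC is evaluated on the held-out (out-of-bag)
#' part. The identical split sequence is shared across feature sets so the
#' per-split AUROCs are paired. Splits in which a class would be absent
#' from either part are redrawn (logged); the procedure is deterministic
#' given the seed.
#'
#' @param data Patient-level data frame.
#' @param outcome Binary (0/1) outcome column name.
#' @param feature_sets Named list of character vectors of predictor
#'   columns.
#' @param n_splits Number of Monte Carlo splits (default 1000).
#' @param test_fraction Held-out fraction per split (default 0.3).
#' @param seed Integer seed.
#' @return Named list of `mccv_result` objects, each with `feature_set`,
#'   `aurocs` (length `n_splits`), `mean_auroc`, `ci_low`/`ci_high`
#'   (2.5/97.5 percentiles across splits), `n_splits`, `test_fraction`,
#'   `seed` and a `split_id` shared by results from the same call.
#' @export
mccv <- function(data, outcome, feature_sets, n_splits = 1000,
                 test_fraction = 0.3, seed = 1L) {
  stopifnot(is.list(feature_sets), length(names(feature_sets)) > 0)
  allvars <- unique(unlist(feature_sets))
  missing_cols <- setdiff(c(outcome, allvars), names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[, c(outcome, allvars), drop = FALSE])
  dat <- data[cc, , drop = FALSE]
  y <- dat[[outcome]]
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
  pos <- which(y == 1); neg <- which(y == 0)
  n_test_pos <- max(1L, round(test_fraction * length(pos)))
  n_test_neg <- max(1L, round(test_fraction * length(neg)))
  if (n_test_pos >= length(pos) || n_test_neg >= length(neg))
    stop("too few observations in a class for the requested test fraction")

  set.seed(seed)
  splits <- vector("list", n_splits)
  redraws <- 0L
  for (s in seq_len(n_splits)) {
    repeat {
      test <- c(sample(pos, n_test_pos), sample(neg, n_test_neg))
      train <- setdiff(seq_len(nrow(dat)), test)
      if (length(unique(y[train])) == 2 && length(unique(y[test])) == 2)
        break
      redraws <- redraws + 1L
    }
    splits[[s]] <- test
  }
  if (redraws > 0) message(redraws, " splits redrawn (missing class)")
  split_id <- sum(vapply(splits, sum, numeric(1)))  # checksum for pairing

  # one model matrix per feature set, rows subset per split
  mm <- lapply(feature_sets, function(vars)
    stats::model.matrix(stats::as.formula(
      paste("~", paste(sprintf("`%s`", vars), collapse = " + "))), dat))

  results <- lapply(names(feature_sets), function(nm) {
    X <- mm[[nm]]
    aucs <- vapply(splits, function(test) {
      train <- setdiff(seq_len(nrow(dat)), test)
      fit <- suppressWarnings(
        stats::glm.fit(X[train, , drop = FALSE], y[train],
                       family = stats::binomial()))
      eta <- X[test, , drop = FALSE] %*% ifelse(is.na(fit$coefficients),
                                                0, fit$coefficients)
      auroc(as.numeric(eta), y[test])
    }, numeric(1))
    out <- list(feature_set = nm,
                aurocs = aucs,
                mean_auroc = mean(aucs),
                ci_low = unname(stats::quantile(aucs, 0.025)),
                ci_high = unname(stats::quantile(aucs, 0.975)),
                n_splits = n_splits,
                test_fraction = test_fraction,
                seed = seed,
                split_id = split_id)
    class(out) <- "mccv_result"
    out
  })
  names(results) <- names(feature_sets)
  results
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("MCCV AUROC [%s]: %.3f (95%% CI %.3f-%.3f) over %d splits\n",
              x$feature_set, x$mean_auroc, x$ci_low, x$ci_high,
              x$n_splits))
  invisible(x)
}

#' Compare Monte Carlo cross-validated feature sets
#'
#' Tabulates the mean AUROC and percentile confidence interval of each
#' feature set, and the paired per-split AUROC differences (with a
#' percentile interval of the difference) for every pair. All results must
#' come from the same call, i.e. share the split sequence.
#'
#' @param results List of `mccv_result` objects from one [mccv()] call.
#' @return List with `summary` (per feature set) and `differences`
#'   (per ordered pair).
#' @export
compare_feature_sets <- function(results) {
  if (inherits(results, "mccv_result")) results <- list(results)
  ids <- vapply(results, function(r) r$split_id, numeric(1))
  if (length(unique(ids)) != 1)
    stop("results do not share the split sequence")
  summary_ <- do.call(rbind, lapply(results, function(r)
    data.frame(feature_set = r$feature_set, mean_auroc = r$mean_auroc,
               ci_low = r$ci_low, ci_high = r$ci_high,
               n_splits = r$n_splits, stringsAsFactors = FALSE)))
  rownames(summary_) <- NULL
  diffs <- list()
  nm <- vapply(results, function(r) r$feature_set, character(1))
  for (i in seq_along(results)) for (j in seq_along(results)) {
    if (i >= j) next
    d <- results[[j]]$aurocs - results[[i]]$aurocs
    diffs[[length(diffs) + 1]] <- data.frame(
      better = nm[j], reference = nm[i],
      mean_diff = mean(d),
      ci_low = unname(stats::quantile(d, 0.025)),
      ci_high = unname(stats::quantile(d, 0.975)),
      stringsAsFactors = FALSE)
  }
  list(summary = summary_,
       differences = if (length(diffs)) do.call(rbind, diffs) else NULL)
}
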