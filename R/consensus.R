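#' Hierarchical consensus clustering
#'
#' Resampling-based consensus clustering of a patient-by-feature matrix.
#' For each candidate number of clusters `k`, `n_resamples` random subsets
#' of `ceiling(item_fraction * n)` patients are drawn without replacement
#' and clustered by agglomerative hierarchical clustering (Ward linkage on
#' Euclidean distance) cut at `k`. The consensus matrix entry for a pair of
#' patients is the fraction of subsamples containing both in which they
#' fell in the same cluster. The final partition at each `k` clusters the
#' dissimilarity `1 - consensus` by average-linkage agglomeration. The
#' number of clusters is chosen by [select_k()] (maximal relative increase
#' of the area under the consensus CDF, with the proportion of ambiguous
#' clustering as tie-breaker).
#'
#' @param X Numeric matrix, patients in rows; no missing values.
#' @param k_range Candidate cluster numbers (default 2:8).
#' @param n_resamples Number of subsamples per `k` (default 500).
#' @param item_fraction Fraction of patients per subsample (default 0.8).
#' @param seed Integer seed; the full path is deterministic given the seed.
#' @param inner_linkage Linkage of the per-subsample clustering
#'   (default `"ward.D2"`).
#' @param final_linkage Linkage of the consensus-matrix clustering
#'   (default `"average"`).
#' @return Object of class `consensus_result`: `consensus` (list of
#'   matrices per `k`), `area` (area under the consensus CDF), `delta_area`,
#'   `pac`, `chosen_k`, `assignments` (list of per-`k` partitions, named by
#'   patient), plus the call parameters.
#' @export
consensus_cluster <- function(X, k_range = 2:8, n_resamples = 500,
                              item_fraction = 0.8, seed = 1L,
                              inner_linkage = "ward.D2",
                              final_linkage = "average") {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  n <- nrow(X)
  if (n <= max(k_range)) stop("need more patients than max(k_range)")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  set.seed(seed)
  m <- ceiling(item_fraction * n)
  idx <- replicate(n_resamples, sample.int(n, m), simplify = FALSE)

  cnt <- matrix(0, n, n)
  for (ii in idx) cnt[ii, ii] <- cnt[ii, ii] + 1
  offdiag <- cnt[upper.tri(cnt)]
  if (any(offdiag == 0))
    stop("some patient pairs were never co-sampled; increase n_resamples")

  # distance computations are shared across k by caching per-subsample trees
  trees <- lapply(idx, function(ii)
    stats::hclust(stats::dist(X[ii, , drop = FALSE]), inner_linkage))

  consensus <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    for (b in seq_along(idx)) {
      ii <- idx[[b]]
      cl <- stats::cutree(trees[[b]], k)
      ind <- outer(cl, cl, "==")
      co[ii, ii] <- co[ii, ii] + ind
    }
    M <- co / pmax(cnt, 1)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    consensus[[as.character(k)]] <- M
  }

  assignments <- stats::setNames(vector("list", length(k_range)),
                                 as.character(k_range))
  for (k in k_range) {
    M <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - M), final_linkage)
    assignments[[as.character(k)]] <-
      stats::setNames(stats::cutree(hc, k), ids)
  }

  res <- structure(list(consensus = consensus,
                        assignments = assignments,
                        k_range = k_range,
                        n_resamples = n_resamples,
                        item_fraction = item_fraction,
                        seed = seed,
                        inner_linkage = inner_linkage,
                        final_linkage = final_linkage),
                   class = "consensus_result")
  sel <- select_k(res)
  res$area <- attr(sel, "area")
  res$delta_area <- attr(sel, "delta_area")
  res$pac <- attr(sel, "pac")
  res$chosen_k <- as.integer(sel)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =",
      paste(range(x$k_range), collapse = "-"),
      "(", x$n_resamples, "resamples, item fraction",
      x$item_fraction, ")\n")
  tab <- data.frame(k = x$k_range,
                    area = round(x$area, 4),
                    delta_area = round(x$delta_area, 4),
                    pac = round(x$pac, 4))
  print(tab, row.names = FALSE)
  cat("chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Choose the number of clusters from a consensus result
#'
#' Computes, for each `k`, the area under the empirical CDF of the
#' off-diagonal consensus entries (equal to `1 - mean(consensus)`), the
#' relative area increase `delta_area` (the area itself at the smallest
#' `k`), and the proportion of ambiguous clustering PAC (fraction of
#' entries in `(0.1, 0.9)`). The chosen `k` maximizes `delta_area`; exact
#' ties are broken by the lower PAC. If the consensus matrices are
#' degenerate (all areas ~ 0, e.g. identical rows), the smallest `k` is
#' returned with a warning.
#'
#' @param result A `consensus_result`.
#' @param pac_bounds Bounds of the ambiguity interval (default
#'   `c(0.1, 0.9)`).
#' @return The chosen `k`, with `area`, `delta_area` and `pac` attached as
#'   attributes.
#' @export
select_k <- function(result, pac_bounds = c(0.1, 0.9)) {
  Ms <- result$consensus
  kr <- result$k_range
  upper <- lapply(Ms, function(M) M[upper.tri(M)])
  area <- vapply(upper, function(u) 1 - mean(u), numeric(1))
  pac <- vapply(upper, function(u)
    mean(u > pac_bounds[1] & u < pac_bounds[2]), numeric(1))
  if (all(area < 1e-12)) {
    warning("degenerate consensus (all items always co-clustered); ",
            "returning k_min")
    out <- kr[1]
    attr(out, "area") <- area
    attr(out, "delta_area") <- rep(0, length(kr))
    attr(out, "pac") <- pac
    return(out)
  }
  delta <- c(area[1], diff(area) / pmax(utils::head(area, -1), 1e-12))
  best <- which(delta >= max(delta) - 1e-12)
  if (length(best) > 1) best <- best[which.min(pac[best])]
  out <- kr[best]
  attr(out, "area") <- area
  attr(out, "delta_area") <- delta
  attr(out, "pac") <- pac
  out
}

#' Merge small consensus clusters into balanced categories
#'
#' Reproduces the post-hoc grouping of sparsely populated consensus
#' clusters. With `manual_map` given (named vector `old label -> new
#' label`, covering every label), the map is applied verbatim. Otherwise
#' every cluster holding fewer than `min_frac` of the patients is merged
#' into the cluster with the highest mean pairwise consensus to it, until
#' none remains below threshold.
#'
#' @param assignments Named vector of cluster labels per patient.
#' @param min_frac Minimum cluster size as a fraction of the cohort
#'   (default 0.05).
#' @param consensus Consensus matrix (required for the automatic rule).
#' @param manual_map Optional named vector mapping every original label to
#'   a merged label.
#' @return Object of class `cluster_assignment`: list with `assignments`
#'   (merged labels, named by patient) and `merge_map` (original label ->
#'   merged label).
#' @export
merge_small_clusters <- function(assignments, min_frac = 0.05,
                                 consensus = NULL, manual_map = NULL) {
  labs <- sort(unique(as.character(assignments)))
  if (!is.null(manual_map)) {
    if (!setequal(names(manual_map), labs))
      stop("manual_map must map every original label exactly once ",
           "(not a partition)")
    merged <- unname(manual_map[as.character(assignments)])
    names(merged) <- names(assignments)
    out <- list(assignments = merged,
                merge_map = manual_map[labs])
    class(out) <- "cluster_assignment"
    return(out)
  }
  n <- length(assignments)
  cur <- as.character(assignments)
  map <- stats::setNames(labs, labs)
  repeat {
    sizes <- table(cur)
    small <- names(sizes)[sizes < min_frac * n]
    if (length(small) == 0 || length(sizes) == 1) break
    s <- small[which.min(sizes[small])]
    if (is.null(consensus))
      stop("consensus matrix required to merge small clusters")
    others <- setdiff(names(sizes), s)
    mean_cons <- vapply(others, function(o) {
      mean(consensus[names(assignments)[cur == s],
                     names(assignments)[cur == o], drop = FALSE])
    }, numeric(1))
    target <- others[which.max(mean_cons)]
    cur[cur == s] <- target
    map[map == s] <- target
  }
  names(cur) <- names(assignments)
  out <- list(assignments = cur, merge_map = map)
  class(out) <- "cluster_assignment"
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same items:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
#'   {\tfrac12\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E},
#'   \quad E = \frac{\sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}}{\binom{n}{2}}}
#' where \eqn{n_{ij}} are the contingency counts and \eqn{a_i, b_j} the
#' marginals. Equals 1 for identical partitions (up to label permutation)
#' and is ~ 0 for independent random partitions.
#'
#' @param a,b Partitions (vectors of labels) over the same items. If both
#'   are named, items are matched by name.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("mismatched item sets")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("mismatched item sets")
  if (anyNA(a) || anyNA(b)) stop("partitions must not contain NA")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  E <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - E
  if (denom == 0) return(1)  # both partitions trivial in the same way
  (sum_ij - E) / denom
}
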