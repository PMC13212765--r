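# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity by a different route than the
# implementation under test.

# ICC(2,1) via an explicit two-way ANOVA fit (aov mean squares)
oracle_icc_aov <- function(y1, y2) {
  n <- length(y1)
  d <- data.frame(y = c(y1, y2),
                  lesion = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ lesion + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Yeo-Johnson transform written straight from the piecewise definition
oracle_yj <- function(x, l) {
  sapply(x, function(xi) {
    if (xi >= 0) {
      if (l != 0) ((xi + 1)^l - 1) / l else log(xi + 1)
    } else {
      if (l != 2) -((-xi + 1)^(2 - l) - 1) / (2 - l) else -log(-xi + 1)
    }
  })
}

# grid-search profile-likelihood oracle for the Yeo-Johnson lambda
oracle_yj_lambda_grid <- function(x, step = 0.001) {
  grid <- seq(-5, 5, by = step)
  ll <- vapply(grid, function(l) {
    z <- oracle_yj(x, l)
    s2 <- mean((z - mean(z))^2)
    if (s2 <= 0) return(-Inf)
    -length(x) / 2 * log(s2) + (l - 1) * sum(sign(x) * log(abs(x) + 1))
  }, numeric(1))
  grid[which.max(ll)]
}

# adjusted Rand index by explicit pair classification over all item pairs
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- n11 + n10 + n01 + n00
  sum_a <- n11 + n10; sum_b <- n11 + n01
  E <- sum_a * sum_b / tot
  denom <- (sum_a + sum_b) / 2 - E
  if (denom == 0) return(1)
  (n11 - E) / denom
}

# two-group log-rank statistic by explicit risk-set enumeration
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  times <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# AUROC by exhaustive positive-negative pair comparison
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# build a patient-level data frame from 2x2 (or 2xL) contingency counts
expand_counts <- function(levels_, case_counts, ref_counts) {
  data.frame(
    exposure = factor(rep(rep(levels_, 2), c(case_counts, ref_counts)),
                      levels = levels_),
    case = rep(c(1L, 0L), c(sum(case_counts), sum(ref_counts))))
}

# blob matrix used by clustering recovery checks: Gaussian blobs of given
# sizes with centers on the first coordinate axis, unit within-cluster SD
make_blobs <- function(sizes, centers, p = 2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(sizes), function(g) {
    m <- matrix(rnorm(sizes[g] * p), sizes[g], p)
    m[, 1] <- m[, 1] + centers[g]
    m
  }))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  X
}
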