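test_that("adjusted Rand index matches formula examples and oracles", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # identical and label-permuted partitions
  a <- c(1, 1, 2, 3, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(7, 7, 5, 9, 9, 9)), 1)
  # exhaustive pair-counting oracle on random partitions, n <= 12
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari_pairs(a, b),
                 tolerance = 1e-12)
  }
  # cross-check against mclust on larger partitions
  set.seed(32)
  a <- sample(1:5, 200, replace = TRUE)
  b <- sample(1:4, 200, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:3, 1:4), "mismatched")
})

test_that("ARI of independent random partitions is centred at zero", {
  set.seed(33)
  aris <- replicate(100, {
    a <- sample(1:3, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("named partitions are matched by item name", {
  a <- c(x = 1, y = 1, z = 2)
  b <- c(z = 5, x = 7, y = 7)  # same partition, shuffled names
  expect_equal(adjusted_rand_index(a, b), 1)
})

test_that("consensus matrices satisfy their structural invariants and the
           path is seed-deterministic", {
  X <- make_blobs(c(12, 12), c(0, 4), seed = 41)
  res <- consensus_cluster(X, k_range = 2:4, n_resamples = 50, seed = 8)
  for (M in res$consensus) {
    expect_true(isSymmetric(M))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1))
  }
  res2 <- consensus_cluster(X, k_range = 2:4, n_resamples = 50, seed = 8)
  expect_identical(res$consensus, res2$consensus)
  expect_identical(res$assignments, res2$assignments)
  res3 <- consensus_cluster(X, k_range = 2:4, n_resamples = 50, seed = 9)
  expect_false(identical(res$consensus, res3$consensus))
})

test_that("pairs always clustered together reach consensus exactly 1", {
  X <- make_blobs(c(10, 10), c(0, 20), seed = 42)
  res <- consensus_cluster(X, k_range = 2, n_resamples = 80, seed = 3)
  M <- res$consensus[["2"]]
  within <- M[1:10, 1:10]
  expect_true(all(within == 1))
})

test_that("three well-separated blobs give chosen k = 3 and perfect
           recovery; two blobs give k = 2", {
  X <- make_blobs(c(20, 20, 20), c(0, 6, 13), seed = 51)
  truth <- rep(1:3, each = 20)
  res <- consensus_cluster(X, k_range = 2:6, n_resamples = 100, seed = 51)
  expect_equal(res$chosen_k, 3, ignore_attr = TRUE)
  ari <- adjusted_rand_index(
    unname(res$assignments[["3"]]), truth)
  expect_equal(ari, 1)
  X2 <- make_blobs(c(30, 30), c(0, 6), seed = 52)
  res2 <- consensus_cluster(X2, k_range = 2:6, n_resamples = 100,
                            seed = 52)
  expect_equal(res2$chosen_k, 2, ignore_attr = TRUE)
})

test_that("a single Gaussian blob is unstable at every k", {
  X1 <- make_blobs(60, 0, seed = 53)
  res1 <- consensus_cluster(X1, k_range = 2:6, n_resamples = 100,
                            seed = 53)
  X3 <- make_blobs(c(20, 20, 20), c(0, 6, 13), seed = 54)
  res3 <- consensus_cluster(X3, k_range = 2:6, n_resamples = 100,
                            seed = 54)
  pac3 <- res3$pac[which(res3$k_range == 3)]
  expect_true(all(res1$pac > pac3))
})

test_that("a degenerate all-ones consensus returns k_min with a warning", {
  M <- matrix(1, 20, 20)
  res <- structure(list(consensus = list(`2` = M, `3` = M, `4` = M),
                        k_range = 2:4),
                   class = "consensus_result")
  expect_warning(k <- select_k(res), "degenerate")
  expect_equal(as.integer(k), 2L)
})

test_that("cluster recovery improves monotonically with separation", {
  aris <- vapply(c(1, 3, 6), function(sep) {
    cfg <- synth_config(n_patients = 90, n_features = 5,
                        cluster_separation = sep, patient_sd = 1,
                        seed = 61)
    co <- generate_cohort(cfg)
    rep_ <- integrate_patients(co$lesions)
    M <- representation_matrix(rep_, "centroid")
    res <- consensus_cluster(M, k_range = 2:4, n_resamples = 60, seed = 61)
    truth <- co$truth$true_cluster[match(rownames(M),
                                         co$truth$patient_id)]
    adjusted_rand_index(unname(res$assignments[["3"]]), truth)
  }, numeric(1))
  expect_true(all(diff(aris) >= 0))
  expect_gt(aris[3], 0.9)
})

test_that("small clusters merge into their highest-consensus neighbour", {
  # fixture: 303 patients in clusters of 200/100/3; consensus of the tiny
  # cluster is higher with cluster 2
  sizes <- c(200, 100, 3)
  lab <- rep(1:3, sizes)
  names(lab) <- sprintf("P%03d", seq_along(lab))
  n <- length(lab)
  M <- matrix(0.05, n, n, dimnames = list(names(lab), names(lab)))
  for (g in 1:3) M[lab == g, lab == g] <- 0.95
  M[lab == 3, lab == 2] <- 0.6
  M[lab == 2, lab == 3] <- 0.6
  diag(M) <- 1
  merged <- merge_small_clusters(lab, min_frac = 0.05, consensus = M)
  expect_equal(unname(merged$merge_map["3"]), "2")
  expect_equal(sort(unique(merged$assignments)), c("1", "2"))
  expect_equal(sum(merged$assignments == "2"), 103)
  # no cluster below threshold: identity map
  big <- rep(1:2, c(60, 40)); names(big) <- sprintf("Q%03d", 1:100)
  id <- merge_small_clusters(big, min_frac = 0.05, consensus = NULL)
  expect_equal(unname(id$merge_map), c("1", "2"))
})

test_that("manual merge maps reproduce the published grouping pattern", {
  lab <- rep(c("M1", "M2", "M3", "M4", "M5"), c(100, 80, 120, 2, 6))
  names(lab) <- sprintf("P%03d", seq_along(lab))
  map <- c(M1 = "M1", M2 = "M2+M5", M5 = "M2+M5",
           M3 = "M3+M4", M4 = "M3+M4")
  merged <- merge_small_clusters(lab, manual_map = map)
  tab <- table(merged$assignments)
  expect_equal(unname(tab[c("M1", "M2+M5", "M3+M4")]),
               c(100, 86, 122), ignore_attr = TRUE)
  # a map that is not a partition of the labels is rejected
  expect_error(merge_small_clusters(lab, manual_map = map[-1]),
               "partition")
})
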