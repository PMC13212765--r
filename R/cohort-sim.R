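#' Configuration for the synthetic multi-lesion cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' emulate the published cohort structure of a 361-patient metastatic lung
#' adenocarcinoma series: every patient contributes at least two segmented
#' lesions (2 + Poisson(`lesion_lambda`), giving a sample median of 4
#' lesions per patient), molecular groups (wild-type, smoker-related
#' oncogenic alteration `sOA`, non-smoker-related `nsOA`) are drawn with
#' cluster-dependent probabilities, the per-patient lesion scatter is scaled
#' by a group-dependent multiplier (lower in nsOA), and binary response and
#' overall-survival outcomes are generated from declared logit and
#' proportional-hazards models on the dispersion range and latent cluster.
#'
#' @param n_patients Number of patients.
#' @param n_features Number of radiomic features per lesion.
#' @param n_clusters Number of latent radiophenotype clusters. Cluster means
#'   are placed as an equilateral simplex in feature space so that every
#'   pair of means is `cluster_separation` apart.
#' @param cluster_separation Distance between cluster means, in units of the
#'   within-cluster standard deviation.
#' @param cluster_probs Probability of each latent cluster (length
#'   `n_clusters`, sums to 1).
#' @param lesion_lambda Poisson mean of the lesion-count law
#'   `2 + Poisson(lesion_lambda)`.
#' @param patient_sd Standard deviation of the per-patient offset from the
#'   cluster mean (isotropic Gaussian).
#' @param lesion_sd Baseline standard deviation of lesion-level noise around
#'   the patient mean, before the group multiplier.
#' @param dispersion_by_group Named multipliers (`WT`, `sOA`, `nsOA`) applied
#'   to `lesion_sd` per molecular group.
#' @param label_probs `n_clusters x 3` matrix of molecular-group
#'   probabilities (columns `WT`, `sOA`, `nsOA`); each row sums to 1.
#' @param biopsy_fraction Fraction of patients with an identified biopsied
#'   lesion.
#' @param biopsy_largest_prob Probability that the biopsied lesion is the
#'   largest one (0.611 in the published series), otherwise uniform among
#'   the remaining lesions.
#' @param orr_intercept,orr_beta_range,orr_beta_cluster Logit model for
#'   objective response: intercept, coefficient on the dispersion range, and
#'   per-cluster additive effects (length `n_clusters`).
#' @param os_base_hazard Baseline exponential hazard of death, per month.
#' @param os_loghr_range,os_loghr_cluster Log hazard ratios on the
#'   dispersion range and per cluster for overall survival. The default
#'   0.5 per unit of range corresponds to roughly 0.17 per standard
#'   deviation of the generated dispersion ranges, matching the
#'   standardized size of the published dispersion-survival association
#'   (whose per-unit hazard ratio of 1.07 refers to ranges spanning
#'   0-14).
#' @param censor_max Upper bound of the independent uniform censoring window
#'   (months).
#' @param duplicate_icc Target intraclass correlation for duplicate
#'   segmentations, in (0, 1].
#' @param seed Integer root seed; all randomness in [generate_cohort()]
#'   flows from a single `set.seed(seed)` call followed by sequential draws.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 361L,
                         n_features = 20L,
                         n_clusters = 3L,
                         cluster_separation = 3,
                         cluster_probs = NULL,
                         lesion_lambda = 2.5,
                         patient_sd = 1,
                         lesion_sd = 1,
                         dispersion_by_group = c(WT = 1, sOA = 1, nsOA = 0.6),
                         label_probs = NULL,
                         biopsy_fraction = 0.5,
                         biopsy_largest_prob = 0.611,
                         orr_intercept = -0.2,
                         orr_beta_range = -0.4,
                         orr_beta_cluster = NULL,
                         os_base_hazard = 0.02,
                         os_loghr_range = 0.5,
                         os_loghr_cluster = NULL,
                         censor_max = 72,
                         duplicate_icc = 0.9,
                         seed = 1L) {
  if (n_patients < 1 || n_features < 1 || n_clusters < 1)
    stop("counts must be positive")
  if (n_features < n_clusters)
    stop("n_features must be >= n_clusters to place the cluster simplex")
  if (cluster_separation < 0) stop("cluster_separation must be nonnegative")
  if (is.null(cluster_probs)) cluster_probs <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_probs) != n_clusters ||
      abs(sum(cluster_probs) - 1) > 1e-8)
    stop("cluster_probs must have length n_clusters and sum to 1")
  if (is.null(label_probs)) {
    base <- rbind(c(0.15, 0.70, 0.15),
                  c(0.25, 0.50, 0.25),
                  c(0.50, 0.40, 0.10))
    label_probs <- base[rep_len(seq_len(3), n_clusters), , drop = FALSE]
  }
  label_probs <- as.matrix(label_probs)
  colnames(label_probs) <- c("WT", "sOA", "nsOA")
  if (nrow(label_probs) != n_clusters)
    stop("label_probs must have one row per cluster")
  if (any(abs(rowSums(label_probs) - 1) > 1e-8))
    stop("each row of label_probs must sum to 1")
  if (any(label_probs < 0)) stop("label_probs must be nonnegative")
  stopifnot(all(c("WT", "sOA", "nsOA") %in% names(dispersion_by_group)))
  if (is.null(orr_beta_cluster)) {
    orr_beta_cluster <- rep(0, n_clusters)
    if (n_clusters >= 2) orr_beta_cluster[2] <- 0.8
  }
  if (is.null(os_loghr_cluster)) {
    os_loghr_cluster <- rep(0, n_clusters)
    if (n_clusters >= 2) os_loghr_cluster[2] <- -0.3
  }
  if (length(orr_beta_cluster) != n_clusters ||
      length(os_loghr_cluster) != n_clusters)
    stop("per-cluster outcome coefficients must have length n_clusters")
  if (duplicate_icc <= 0 || duplicate_icc > 1)
    stop("duplicate_icc must be in (0, 1]")
  cfg <- list(n_patients = as.integer(n_patients),
              n_features = as.integer(n_features),
              n_clusters = as.integer(n_clusters),
              cluster_separation = cluster_separation,
              cluster_probs = cluster_probs,
              lesion_lambda = lesion_lambda,
              patient_sd = patient_sd,
              lesion_sd = lesion_sd,
              dispersion_by_group = dispersion_by_group,
              label_probs = label_probs,
              biopsy_fraction = biopsy_fraction,
              biopsy_largest_prob = biopsy_largest_prob,
              orr_intercept = orr_intercept,
              orr_beta_range = orr_beta_range,
              orr_beta_cluster = orr_beta_cluster,
              os_base_hazard = os_base_hazard,
              os_loghr_range = os_loghr_range,
              os_loghr_cluster = os_loghr_cluster,
              censor_max = censor_max,
              duplicate_icc = duplicate_icc,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# Covariate frequencies by molecular group, mirroring the published
# descriptive table (independent sampling of site flags is a declared
# simplification).
.covariate_freqs <- list(
  sex_female = c(WT = 0.315, sOA = 0.391, nsOA = 0.660),
  smoking    = list(WT   = c(never = 0.078, active = 0.467, former = 0.456),
                    sOA  = c(never = 0.035, active = 0.529, former = 0.436),
                    nsOA = c(never = 0.532, active = 0.191, former = 0.277)),
  who_ps     = list(WT   = c(ps0 = 0.239, ps1 = 0.489, ps2 = 0.272),
                    sOA  = c(ps0 = 0.253, ps1 = 0.517, ps2 = 0.230),
                    nsOA = c(ps0 = 0.362, ps1 = 0.553, ps2 = 0.085)),
  stage_ivb  = c(WT = 0.772, sOA = 0.770, nsOA = 0.851),
  met_brain  = c(WT = 0.283, sOA = 0.270, nsOA = 0.489),
  met_pleural = c(WT = 0.120, sOA = 0.230, nsOA = 0.234),
  met_bone   = c(WT = 0.457, sOA = 0.448, nsOA = 0.681),
  met_peritoneal = c(WT = 0.098, sOA = 0.121, nsOA = 0.000),
  met_liver  = c(WT = 0.185, sOA = 0.241, nsOA = 0.234))

#' Generate a synthetic multi-lesion radiomics cohort
#'
#' Draws a cohort under the declared generative model: each patient belongs
#' to a latent radiophenotype cluster; lesion feature vectors are
#' `cluster mean + patient offset + lesion noise`, with lesion noise scaled
#' by the patient's molecular-group dispersion multiplier; each patient has
#' `2 + Poisson(lambda)` lesions, exactly one largest-lesion flag (maximum
#' volume) and, for about half the cohort, one biopsied-lesion flag;
#' objective response is Bernoulli under a logit model on the dispersion
#' range and cluster, and overall survival is exponential with uniform
#' censoring. Identical `config` (including its seed) yields identical
#' tables.
#'
#' @param config A [synth_config()] object.
#' @return A list with class `synthetic_cohort`:
#' \describe{
#'   \item{lesions}{lesion-level feature table: `patient_id`, `lesion_id`,
#'     `volume_cm3`, `is_largest`, `is_biopsied`, feature columns `rf_*`.}
#'   \item{patients}{patient table: molecular group and flags, covariates,
#'     objective response `orr`, survival `os_months`/`os_event`.}
#'   \item{truth}{per-patient ground truth (`true_cluster`,
#'     `true_dispersion_scale`) with the generating config as attribute.}
#' }
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  p <- config$n_features
  K <- config$n_clusters

  # cluster means: equilateral simplex with pairwise distance = separation
  mu <- matrix(0, K, p)
  if (K > 1)
    mu[, seq_len(K)] <- diag(K) * config$cluster_separation / sqrt(2)

  cluster <- sample.int(K, n, replace = TRUE, prob = config$cluster_probs)
  groups <- c("WT", "sOA", "nsOA")
  group <- vapply(cluster, function(k)
    sample(groups, 1L, prob = config$label_probs[k, ]), character(1))
  disp_mult <- unname(config$dispersion_by_group[group])

  n_lesions <- 2L + stats::rpois(n, config$lesion_lambda)
  patient_id <- sprintf("P%04d", seq_len(n))

  lesion_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_lesions[i]
    offset <- stats::rnorm(p, 0, config$patient_sd)
    center <- mu[cluster[i], ] + offset
    noise <- matrix(stats::rnorm(m * p, 0, config$lesion_sd * disp_mult[i]),
                    m, p)
    feats <- sweep(noise, 2, center, "+")
    colnames(feats) <- sprintf("rf_%02d", seq_len(p))
    vol <- 1 + stats::rlnorm(m, meanlog = 1, sdlog = 1)
    is_largest <- seq_len(m) == which.max(vol)
    lesion_rows[[i]] <- data.frame(
      patient_id = patient_id[i],
      lesion_id = sprintf("%s_L%02d", patient_id[i], seq_len(m)),
      volume_cm3 = vol,
      is_largest = is_largest,
      is_biopsied = FALSE,
      feats,
      stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, lesion_rows)
  rownames(lesions) <- NULL

  # biopsied flag: identified for ~biopsy_fraction of patients; the largest
  # lesion with probability biopsy_largest_prob, else uniform among others
  has_biopsy <- stats::runif(n) < config$biopsy_fraction
  for (i in which(has_biopsy)) {
    rows <- which(lesions$patient_id == patient_id[i])
    largest <- rows[lesions$is_largest[rows]]
    if (length(rows) > 1 &&
        stats::runif(1) >= config$biopsy_largest_prob) {
      pick <- setdiff(rows, largest)
      pick <- if (length(pick) == 1) pick else sample(pick, 1L)
    } else {
      pick <- largest
    }
    lesions$is_biopsied[pick] <- TRUE
  }

  # true per-patient dispersion statistics on the raw feature scale
  disp_range <- vapply(seq_len(n), function(i) {
    rows <- lesions$patient_id == patient_id[i]
    X <- as.matrix(lesions[rows, grep("^rf_", names(lesions)), drop = FALSE])
    d <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
    max(d) - min(d)
  }, numeric(1))

  # covariates with group-dependent marginal frequencies
  fr <- .covariate_freqs
  sex <- ifelse(stats::runif(n) < fr$sex_female[group], "female", "male")
  smoking <- vapply(group, function(g)
    sample(names(fr$smoking[[g]]), 1L, prob = fr$smoking[[g]]), character(1))
  who_ps <- vapply(group, function(g)
    sample(c("0", "1", ">=2"), 1L, prob = fr$who_ps[[g]]), character(1))
  stage <- ifelse(stats::runif(n) < fr$stage_ivb[group], "IVb", "III-IVa")
  site <- function(nm) stats::runif(n) < fr[[nm]][group]

  eta <- config$orr_intercept + config$orr_beta_range * disp_range +
    config$orr_beta_cluster[cluster]
  orr <- stats::rbinom(n, 1L, stats::plogis(eta))

  haz <- config$os_base_hazard *
    exp(config$os_loghr_range * disp_range +
          config$os_loghr_cluster[cluster])
  t_event <- stats::rexp(n, haz)
  t_cens <- stats::runif(n, 0, config$censor_max)
  os_months <- pmax(pmin(t_event, t_cens), 1e-3)
  os_event <- as.integer(t_event <= t_cens)

  patients <- data.frame(
    patient_id = patient_id,
    molecular_group = group,
    any_oa = as.integer(group != "WT"),
    sex = sex,
    smoking = smoking,
    who_ps = who_ps,
    stage = stage,
    met_brain = site("met_brain"),
    met_pleural = site("met_pleural"),
    met_bone = site("met_bone"),
    met_peritoneal = site("met_peritoneal"),
    met_liver = site("met_liver"),
    orr = orr,
    os_months = os_months,
    os_event = os_event,
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = patient_id,
                      true_cluster = cluster,
                      true_dispersion_scale = disp_mult,
                      true_dispersion_range = disp_range,
                      stringsAsFactors = FALSE)
  attr(truth, "config") <- config

  out <- list(lesions = lesions, patients = patients, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-lesion cohort:",
      nrow(x$patients), "patients,",
      nrow(x$lesions), "lesions,",
      length(grep("^rf_", names(x$lesions))), "features\n")
  print(table(x$patients$molecular_group))
  invisible(x)
}

#' Simulate a duplicate segmentation of a lesion table
#'
#' Emulates a second manual segmentation of the same lesions by adding
#' independent Gaussian noise to each feature, calibrated so that the
#' two-way random-effects single-measurement ICC between the original and
#' the duplicate converges to `duplicate_icc`. Because the original table
#' carries no measurement error of its own, the noise variance placed on
#' the single duplicate copy is `2 * sigma_b^2 * (1 - icc) / icc`, where
#' `sigma_b^2` is the observed between-lesion variance of the feature; this
#' makes `duplicate_icc` the exact ICC(2,1) estimand of the generated pair.
#'
#' @param lesions A lesion feature table (as from [generate_cohort()]).
#' @param duplicate_icc Target ICC in (0, 1]. `1` returns an exact copy.
#' @param seed Integer seed.
#' @return A lesion table with the same keys and perturbed feature values.
#' @export
generate_duplicate_segmentations <- function(lesions, duplicate_icc,
                                             seed = 1L) {
  if (duplicate_icc <= 0 || duplicate_icc > 1)
    stop("duplicate_icc must be in (0, 1]")
  set.seed(seed)
  dup <- lesions
  for (f in feature_cols(lesions)) {
    if (duplicate_icc == 1) next
    s2 <- stats::var(lesions[[f]])
    sd_e <- sqrt(2 * s2 * (1 - duplicate_icc) / duplicate_icc)
    dup[[f]] <- lesions[[f]] + stats::rnorm(nrow(lesions), 0, sd_e)
  }
  dup
}

#' Names of the radiomic feature columns of a lesion table
#'
#' Feature columns are all columns other than the key/metadata columns
#' (`patient_id`, `lesion_id`, `volume_cm3`, `is_largest`, `is_biopsied`).
#'
#' @param table A lesion feature table.
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table),
          c("patient_id", "lesion_id", "volume_cm3",
            "is_largest", "is_biopsied"))
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Writes `lesions.csv`, `patients.csv` and a `truth.json` sidecar (ground
#' truth plus the generating configuration) into `dir`.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$lesions, file.path(dir, "lesions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  cfg <- attr(cohort$truth, "config")
  side <- list(truth = cohort$truth,
               config = unclass(cfg))
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param check.names Passed to `read.csv`; keys are kept verbatim.
#' @export
read_cohort <- function(dir, check.names = FALSE) {
  lesions <- utils::read.csv(file.path(dir, "lesions.csv"),
                             check.names = check.names,
                             stringsAsFactors = FALSE)
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              check.names = check.names,
                              stringsAsFactors = FALSE)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    side <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- side$truth
  }
  out <- list(lesions = lesions, patients = patients, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}
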