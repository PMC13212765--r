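#' Per-patient centroid of lesion feature vectors
#'
#' Coordinate-wise arithmetic mean of a patient's lesion feature vectors in
#' the transformed radiomic-feature space; the basis of the centroid
#' patient representation.
#'
#' @param X Numeric matrix, one row per lesion (>= 2 rows).
#' @return Named numeric centroid vector.
#' @export
patient_centroid <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("a patient must have at least 2 lesions")
  colMeans(X)
}

#' Lesion-to-centroid dispersion statistics
#'
#' Euclidean distance of each lesion to the patient centroid,
#' \eqn{d_j = \lVert x_j - c \rVert_2}, with their mean and range
#' (max - min). Mean and range are quantitative proxies for the
#' radiophenotypic dispersion of a patient's lesions; with exactly two
#' lesions both distances are equal and the range is 0.
#'
#' @param X Numeric matrix of lesion feature vectors (rows = lesions).
#' @param centroid Centroid vector in the same feature space.
#' @return List with `lesion_distances`, `dispersion_mean`,
#'   `dispersion_range`.
#' @export
dispersion_stats <- function(X, centroid) {
  X <- as.matrix(X)
  if (ncol(X) != length(centroid)) stop("dimension mismatch")
  if (nrow(X) == 2) {
    # both lesions are equidistant from their midpoint by construction;
    # computing half the inter-lesion distance keeps the range exactly 0
    d <- rep(sqrt(sum((X[1, ] - X[2, ])^2)) / 2, 2)
  } else {
    d <- sqrt(rowSums(sweep(X, 2, centroid)^2))
  }
  list(lesion_distances = d,
       dispersion_mean = mean(d),
       dispersion_range = max(d) - min(d))
}

#' Select the largest lesion of a patient
#'
#' The lesion with maximal segmented volume; ties are broken by the
#' lexicographically smallest `lesion_id` and reported with a message.
#'
#' @param lesions Data frame of one patient's lesions with `volume_cm3`
#'   and `lesion_id`.
#' @return The selected row (single-row data frame).
#' @export
select_largest <- function(lesions) {
  if (is.null(lesions$volume_cm3) || anyNA(lesions$volume_cm3))
    stop("missing volumes")
  vmax <- max(lesions$volume_cm3)
  cand <- which(lesions$volume_cm3 == vmax)
  if (length(cand) > 1) {
    cand <- cand[order(lesions$lesion_id[cand])][1]
    message("volume tie for patient ", lesions$patient_id[1],
            "; selected lesion ", lesions$lesion_id[cand])
  }
  lesions[cand, , drop = FALSE]
}

#' Select the biopsied lesion of a patient
#'
#' Returns the lesion flagged `is_biopsied`, or `NULL` when no lesion is
#' flagged (the patient is then excluded from biopsied-lesion analyses).
#' More than one flagged lesion violates the table invariant and is an
#' error.
#'
#' @param lesions Data frame of one patient's lesions.
#' @return Single-row data frame or `NULL`.
#' @export
select_biopsied <- function(lesions) {
  idx <- which(lesions$is_biopsied)
  if (length(idx) == 0) return(NULL)
  if (length(idx) > 1)
    stop("multiple biopsied flags for patient ", lesions$patient_id[1])
  lesions[idx, , drop = FALSE]
}

#' Build the patient-level representations of a lesion table
#'
#' For every patient: the centroid feature vector, the lesion-to-centroid
#' distances summarized as dispersion mean and range, the largest-lesion
#' feature vector, and the biopsied-lesion feature vector when a biopsied
#' lesion is identified (otherwise `NA`, excluding the patient from
#' biopsied-lesion analyses).
#'
#' @param table Transformed, filtered lesion feature table.
#' @return A data frame of class `patient_representation`: `patient_id`,
#'   `n_lesions`, `dispersion_mean`, `dispersion_range`, then feature
#'   columns prefixed `centroid_`, `largest_`, `biopsied_`. The feature
#'   names are kept in the `features` attribute.
#' @export
integrate_patients <- function(table) {
  feats <- feature_cols(table)
  ids <- unique(table$patient_id)
  rows <- lapply(ids, function(pid) {
    les <- table[table$patient_id == pid, , drop = FALSE]
    X <- as.matrix(les[, feats, drop = FALSE])
    ctr <- patient_centroid(X)
    disp <- dispersion_stats(X, ctr)
    big <- select_largest(les)
    bio <- select_biopsied(les)
    bio_f <- if (is.null(bio)) rep(NA_real_, length(feats))
             else as.numeric(bio[1, feats])
    out <- data.frame(patient_id = pid,
                      n_lesions = nrow(les),
                      dispersion_mean = disp$dispersion_mean,
                      dispersion_range = disp$dispersion_range,
                      stringsAsFactors = FALSE)
    out[paste0("centroid_", feats)] <- as.list(ctr)
    out[paste0("largest_", feats)] <- as.list(as.numeric(big[1, feats]))
    out[paste0("biopsied_", feats)] <- as.list(bio_f)
    out
  })
  rep_ <- do.call(rbind, rows)
  rownames(rep_) <- NULL
  attr(rep_, "features") <- feats
  class(rep_) <- c("patient_representation", "data.frame")
  rep_
}

#' Extract one representation as a patient x feature matrix
#'
#' @param rep_ A `patient_representation` data frame.
#' @param which One of `"centroid"`, `"largest"`, `"biopsied"`.
#' @param drop_missing Drop patients with missing vectors (biopsied
#'   representation only exists for patients with an identified biopsied
#'   lesion).
#' @return Numeric matrix with `patient_id` row names.
#' @export
representation_matrix <- function(rep_,
                                  which = c("centroid", "largest",
                                            "biopsied"),
                                  drop_missing = TRUE) {
  which <- match.arg(which)
  feats <- attr(rep_, "features")
  M <- as.matrix(rep_[, paste0(which, "_", feats), drop = FALSE])
  colnames(M) <- feats
  rownames(M) <- rep_$patient_id
  if (drop_missing) M <- M[stats::complete.cases(M), , drop = FALSE]
  M
}
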