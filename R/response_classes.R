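# Ordinal response categories and effect-size trend classification.
#
# Agility percent changes are baseline-adjusted, participants are
# partitioned into moderate / intermediate / max performance categories by
# Gaussian-mixture modelling (diagonal covariances, BIC-selected k), and
# each marker's category-wise mean effect profile is classified as a linear
# trend, a plateau, or neither.

#' Baseline-adjusted agility percent changes
#'
#' Raw percent change is `100 * (AT - BT) / BT` per metric. The adjusted
#' value is the residual of regressing the raw change on the BT baseline
#' (per metric), re-centered at the cohort mean change, removing the
#' regression-to-the-mean component. With no baseline variation the raw
#' change is returned unchanged.
#'
#' @param participants a `participant_sheet`.
#' @param metrics agility metric names (default flexion/extension/rotation).
#' @return Matrix, participants x metrics, of adjusted percent changes.
#' @export
baseline_adjust <- function(participants,
                            metrics = c("flexion", "extension", "rotation")) {
  df <- as.data.frame(participants)
  out <- matrix(NA_real_, nrow(df), length(metrics),
                dimnames = list(df$participant_id, metrics))
  for (m in metrics) {
    bt <- df[[paste0(m, "_bt")]]
    at <- df[[paste0(m, "_at")]]
    .assert(all(bt > 0), paste("non-positive BT baseline for", m))
    pct <- 100 * (at - bt) / bt
    if (stats::sd(bt) == 0) {
      out[, m] <- pct
    } else {
      fit <- stats::lm(pct ~ bt)
      out[, m] <- stats::residuals(fit) + mean(pct)
    }
  }
  out
}

#' Gaussian-mixture performance categories
#'
#' Fits diagonal-covariance Gaussian mixtures for `k = 1..k_max` to the
#' adjusted percent-change matrix, selects `k` by BIC, and orders components
#' by their mean overall change: the lowest becomes `moderate`, then
#' `intermediate`, then `max` (for `k = 3`; other `k` are labelled
#' `cat1 < cat2 < ...`).
#'
#' @param adjusted participants-by-metrics matrix (see [baseline_adjust()]).
#' @param k_max maximum component count (default 4).
#' @param seed integer seed.
#' @return list with `fit` (the `Mclust` object: means, diagonal
#'   covariances, weights, responsibilities, BIC trace over k), `k`, and
#'   `labels` — an ordered factor per participant.
#' @export
gmm_categories <- function(adjusted, k_max = 4, seed = 1) {
  .assert(nrow(adjusted) >= k_max + 2, "too few participants for k_max components")
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this by name in the caller
  # diagonal varying-volume model; the conjugate prior floors the variances,
  # preventing degenerate tiny-variance components at cohort size ~12
  fit <- mclust::Mclust(adjusted, G = 1:k_max, modelNames = "VVI",
                        prior = mclust::priorControl(), verbose = FALSE)
  .assert(!is.null(fit), "mixture estimation failed")
  k <- fit$G
  overall <- if (k == 1) mean(colMeans(fit$parameters$mean)) else
    colMeans(as.matrix(fit$parameters$mean))
  ord <- order(overall)  # component index -> rank by mean overall change
  lev <- if (k == 3) c("moderate", "intermediate", "max") else
    paste0("cat", seq_len(k))
  rank_of <- match(fit$classification, ord)
  labels <- factor(lev[rank_of], levels = lev, ordered = TRUE)
  names(labels) <- rownames(adjusted)
  list(fit = fit, k = k, labels = labels)
}

#' Category-wise mean effect profile per marker
#'
#' Averages each marker's per-participant effect within each ordinal
#' category. For self-assessment profiles, `exclude` removes the
#' "unimpaired" participants (no/minor back pain) before averaging.
#'
#' @param effects participants-by-markers matrix of per-participant effects
#'   (e.g. a [participant_change_matrix()] restricted to markers).
#' @param labels ordinal factor per participant (names matching rows).
#' @param exclude category labels to drop before profiling (default none).
#' @return Matrix, markers x categories (ordered levels); a category left
#'   empty yields `NA` means.
#' @export
category_effect_profile <- function(effects, labels, exclude = character(0)) {
  .assert(!is.null(names(labels)) || length(labels) == nrow(effects),
          "labels must align with effect rows")
  if (!is.null(names(labels))) {
    .assert(all(rownames(effects) %in% names(labels)),
            "every participant needs a label")
    labels <- labels[rownames(effects)]
  }
  keep <- !(as.character(labels) %in% exclude)
  effects <- effects[keep, , drop = FALSE]
  labels <- droplevels(factor(labels[keep],
                              levels = setdiff(levels(factor(labels)), exclude),
                              ordered = TRUE))
  lev <- levels(labels)
  prof <- matrix(NA_real_, ncol(effects), length(lev),
                 dimnames = list(colnames(effects), lev))
  for (l in lev) {
    rows <- which(labels == l)
    if (length(rows) > 0) prof[, l] <- colMeans(effects[rows, , drop = FALSE])
  }
  prof  # markers x categories
}

#' Classify a 3-category effect profile as trend or plateau
#'
#' With means `(m1, m2, m3)` and `range = max - min`:
#' * `increasing_linear` if `m1 < m2 < m3` and the two steps differ by at
#'   most `tol * range`;
#' * `decreasing_linear` symmetrically;
#' * `plateau_first_two` if `|m1 - m2| <= tol * range` and
#'   `|m3 - m2| > tol * range`;
#' * `plateau_last_two` symmetrically;
#' * otherwise `none`. A flat profile (`range = 0`) is `none`.
#'
#' @param profile numeric vector of 3 category means (or a markers x 3
#'   matrix; then a vector of labels is returned).
#' @param tol tolerance as a fraction of the profile range (default 0.25).
#' @return Character label(s) in
#'   `{increasing_linear, decreasing_linear, plateau_first_two,
#'   plateau_last_two, none}`.
#' @export
trend_classify <- function(profile, tol = 0.25) {
  if (is.matrix(profile)) {
    .assert(ncol(profile) == 3, "profiles must have 3 categories")
    return(apply(profile, 1, trend_classify, tol = tol))
  }
  .assert(length(profile) == 3, "profile must have 3 category means")
  if (anyNA(profile)) return("none")
  m1 <- profile[1]; m2 <- profile[2]; m3 <- profile[3]
  rng <- max(profile) - min(profile)
  if (rng == 0) return("none")
  band <- tol * rng
  s1 <- m2 - m1; s2 <- m3 - m2
  if (m1 < m2 && m2 < m3 && abs(s1 - s2) <= band) return("increasing_linear")
  if (m1 > m2 && m2 > m3 && abs(s1 - s2) <= band) return("decreasing_linear")
  if (abs(s1) <= band && abs(s2) > band) return("plateau_first_two")
  if (abs(s2) <= band && abs(s1) > band) return("plateau_last_two")
  "none"
}
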