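# Health-awareness scoring: lifestyle PLS-DA maps on BT profiles, AT
# projection, the therapy-effect distance d(BT, AT) in the variate plane,
# rank concordance across sample types (Kendall's W), VIP-gated indicators
# with jackknifed healthy ranges, weighted similarity scores, BT-vs-AT
# paired tests, and robust regression against the healthy centroid.

#' Fit a lifestyle health map on BT profiles
#'
#' Two-component PLS-DA on the before-therapy samples with lifestyle
#' categories as outcome. The model's centering/scaling is stored so the AT
#' profiles can be projected without refitting.
#'
#' @param bt_profiles samples-by-features matrix of BT profiles (row names =
#'   participant ids).
#' @param lifestyle named vector of category labels per participant.
#' @param healthy_category label of the healthy reference category.
#' @param n_components PLS components (default 2).
#' @return list of class `health_map`: `model` (a `plsda`), `bt_scores`,
#'   `lifestyle`, `healthy_category`, `healthy_centroid` (gravity center of
#'   the healthy category's BT coordinates).
#' @export
fit_health_map <- function(bt_profiles, lifestyle, healthy_category,
                           n_components = 2) {
  .assert(!is.null(rownames(bt_profiles)), "bt_profiles needs participant row names")
  lifestyle <- lifestyle[rownames(bt_profiles)]
  .assert(!anyNA(lifestyle), "every BT profile needs a lifestyle label")
  tab <- table(lifestyle)
  .assert(length(tab) >= 2, "need at least 2 lifestyle categories at BT")
  if (any(tab == 1)) {
    warning("lifestyle category with a single member: ",
            paste(names(tab)[tab == 1], collapse = ", "))
  }
  .assert(healthy_category %in% names(tab), "healthy category absent at BT")
  model <- plsda_fit(bt_profiles, lifestyle, n_components = n_components)
  bt_scores <- model$scores
  rownames(bt_scores) <- rownames(bt_profiles)
  healthy <- rownames(bt_profiles)[lifestyle == healthy_category]
  centroid <- colMeans(bt_scores[healthy, , drop = FALSE])
  structure(list(model = model, bt_scores = bt_scores,
                 lifestyle = lifestyle, healthy_category = healthy_category,
                 healthy_centroid = centroid),
            class = "health_map")
}

#' Project AT profiles into a fitted health map
#'
#' @param map a `health_map`.
#' @param at_profiles samples-by-features matrix of AT profiles covering the
#'   map's feature set (row names = participant ids).
#' @return Matrix of AT coordinates (participants x components).
#' @export
project_at <- function(map, at_profiles) {
  .assert(inherits(map, "health_map"), "map must be a health_map")
  scores <- predict(map$model, at_profiles, type = "scores")
  rownames(scores) <- rownames(at_profiles)
  scores
}

#' Per-participant therapy-effect distance d(BT, AT)
#'
#' Euclidean distance between each participant's BT coordinates and his
#' projected AT coordinates in the variate plane.
#'
#' @param map a `health_map`.
#' @param at_scores output of [project_at()].
#' @return Named nonnegative numeric vector over the participants present
#'   in both coordinate sets.
#' @export
therapy_effect_distance <- function(map, at_scores) {
  common <- intersect(rownames(map$bt_scores), rownames(at_scores))
  .assert(length(common) > 0, "no participant with both BT and AT coordinates")
  d <- sqrt(rowSums((map$bt_scores[common, , drop = FALSE] -
                       at_scores[common, , drop = FALSE])^2))
  stats::setNames(d, common)
}

#' Kendall's coefficient of concordance (tie-corrected)
#'
#' Items (participants) are ranked within each rater (sample type), mean
#' ranks for ties. With `m` raters, `n` items, rank sums `R_i`,
#' `S = sum (R_i - mean R)^2` and per-rater tie term
#' `T_j = sum (t^3 - t)`: `W = 12 S / (m^2 (n^3 - n) - m sum T_j)`, and the
#' chi-square test uses `chi2 = m (n - 1) W` with `df = n - 1`.
#'
#' @param ratings items-by-raters numeric matrix (larger value = higher
#'   rank).
#' @return list `W`, `chi2`, `df`, `p`.
#' @export
kendalls_w <- function(ratings) {
  .assert(is.matrix(ratings) && ncol(ratings) >= 2 && nrow(ratings) >= 3,
          "need >= 2 raters and >= 3 items")
  n <- nrow(ratings); m <- ncol(ratings)
  Rk <- apply(ratings, 2, rank)
  Tj <- apply(Rk, 2, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  .assert(denom > 0, "all raters constant: W undefined")
  Ri <- rowSums(Rk)
  S <- sum((Ri - mean(Ri))^2)
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  df <- n - 1
  list(W = W, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Healthy ranges of VIP-gated indicators
#'
#' Indicators are the map features with aggregate VIP >= `vip_threshold`.
#' Each indicator's values are min-max normalized to `[0, 1]` using the
#' cohort's AT values as the reference scale (values outside are clipped).
#' The healthy range is the delete-1 jackknife mean of the healthy members'
#' normalized values +/- `t_{n-1, (1+level)/2} * SE`, clipped to `[0, 1]`.
#'
#' @param map a `health_map`.
#' @param bt_profiles,at_profiles participants-by-features matrices (the AT
#'   matrix defines the normalization reference; the BT healthy members
#'   define the range).
#' @param level confidence level (default 0.95).
#' @param vip_threshold indicator gate (default 1).
#' @return data.frame `feature_id`, `weight` (VIP), `lo`, `hi`, with the
#'   normalization reference (`ref_min`, `ref_max`) attached as columns.
#' @export
healthy_range <- function(map, bt_profiles, at_profiles, level = 0.95,
                          vip_threshold = 1.0) {
  vips <- vip_scores(map$model)
  ind <- names(vips)[vips >= vip_threshold]
  .assert(length(ind) > 0, "no indicator passes the VIP gate")
  healthy <- names(map$lifestyle)[map$lifestyle == map$healthy_category]
  healthy <- intersect(healthy, rownames(bt_profiles))
  .assert(length(healthy) >= 3, "need at least 3 healthy members")
  ref_min <- apply(at_profiles[, ind, drop = FALSE], 2, min)
  ref_max <- apply(at_profiles[, ind, drop = FALSE], 2, max)
  out <- data.frame(feature_id = ind, weight = unname(vips[ind]),
                    lo = NA_real_, hi = NA_real_,
                    ref_min = unname(ref_min), ref_max = unname(ref_max),
                    stringsAsFactors = FALSE)
  nh <- length(healthy)
  tq <- stats::qt(1 - (1 - level) / 2, df = nh - 1)
  for (k in seq_along(ind)) {
    x <- normalize_to_reference(bt_profiles[healthy, ind[k]],
                                ref_min[k], ref_max[k])
    loo <- vapply(seq_len(nh), function(i) mean(x[-i]), numeric(1))
    se <- sqrt((nh - 1) / nh * sum((loo - mean(loo))^2))
    out$lo[k] <- max(0, mean(x) - tq * se)
    out$hi[k] <- min(1, mean(x) + tq * se)
  }
  out
}

#' Min-max normalize values against a reference scale
#'
#' @param x numeric values.
#' @param ref_min,ref_max reference minimum/maximum (e.g. the cohort AT
#'   values of an indicator); output is clipped to `[0, 1]`.
#' @return Normalized values in `[0, 1]`.
#' @export
normalize_to_reference <- function(x, ref_min, ref_max) {
  if (ref_max == ref_min) return(rep(0.5, length(x)))
  pmin(1, pmax(0, (x - ref_min) / (ref_max - ref_min)))
}

#' Weighted similarity to the healthy range
#'
#' Per indicator `j` with normalized value `x_j`: `s_j = 1` when
#' `lo_j <= x_j <= hi_j` (bounds inclusive); otherwise
#' `s_j = max(0, 1 - dist_j / r_j)` with `dist_j` the distance to the
#' nearest bound and `r_j = max(hi_j - lo_j, 0.05)`. The score is the
#' VIP-weighted mean `sum(w_j s_j) / sum(w_j)`.
#'
#' @param profile participant's raw indicator values (named by feature id)
#'   on the map scale; normalized internally with the ranges' reference.
#' @param ranges output of [healthy_range()].
#' @return list `weighted_score` in `[0, 1]`, `n_in_range`, `s` (per-
#'   indicator similarities).
#' @export
similarity_score <- function(profile, ranges) {
  miss <- setdiff(ranges$feature_id, names(profile))
  .assert(length(miss) == 0,
          paste("indicator(s) missing from profile:",
                paste(utils::head(miss, 5), collapse = ", ")))
  eps <- 0.05
  s <- numeric(nrow(ranges))
  for (k in seq_len(nrow(ranges))) {
    x <- normalize_to_reference(profile[[ranges$feature_id[k]]],
                                ranges$ref_min[k], ranges$ref_max[k])
    lo <- ranges$lo[k]; hi <- ranges$hi[k]
    if (x >= lo && x <= hi) {
      s[k] <- 1
    } else {
      dist <- if (x < lo) lo - x else x - hi
      r <- max(hi - lo, eps)
      s[k] <- max(0, 1 - dist / r)
    }
  }
  list(weighted_score = sum(ranges$weight * s) / sum(ranges$weight),
       n_in_range = sum(s == 1), s = stats::setNames(s, ranges$feature_id))
}

#' Paired BT-vs-AT comparison of similarity scores
#'
#' One-sided paired t-tests (alternative: AT similarity exceeds BT) per
#' (sample type x lifestyle) cell, BH-adjusted across cells; also reports
#' per cell how many participants increased their in-range indicator count.
#' Constant differences are handled at the limit: all-zero gives `p = 0.5`,
#' constant positive gives `p = 0`, constant negative `p = 1`.
#'
#' @param scores data.frame with columns `cell` (sample type x lifestyle
#'   label), `participant_id`, `bt_score`, `at_score`, `bt_n_in`, `at_n_in`.
#' @return data.frame per cell: `n`, `t`, `p`, `q` (BH), `n_improved`.
#' @export
compare_bt_at <- function(scores) {
  need <- c("cell", "participant_id", "bt_score", "at_score")
  .assert(all(need %in% names(scores)), "scores missing required columns")
  cells <- unique(scores$cell)
  res <- lapply(cells, function(cl) {
    s <- scores[scores$cell == cl, , drop = FALSE]
    d <- s$at_score - s$bt_score
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 3) {
      t_ <- NA_real_; p <- NA_real_
    } else if (stats::sd(d) == 0) {
      t_ <- ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf)
      p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    } else {
      tt <- stats::t.test(d, alternative = "greater")
      t_ <- unname(tt$statistic); p <- tt$p.value
    }
    nimp <- if (all(c("bt_n_in", "at_n_in") %in% names(s))) {
      sum(s$at_n_in > s$bt_n_in, na.rm = TRUE)
    } else NA_integer_
    data.frame(cell = cl, n = n, t = t_, p = p, n_improved = nimp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Robust (Huber) regression with a Wald slope test
#'
#' M-estimation with Huber's psi (tuning constant 1.345) by iteratively
#' reweighted least squares; the slope's Wald p-value uses the robust
#' standard error.
#'
#' @param y response (e.g. d(BT, AT)).
#' @param x predictor (e.g. BT distance to the healthy centroid).
#' @return list `slope`, `intercept`, `se`, `p`.
#' @export
robust_regress <- function(y, x) {
  .assert(length(x) == length(y) && length(x) >= 5, "need >= 5 points")
  .assert(stats::sd(x) > 0, "zero variance in x")
  ls <- stats::lm(y ~ x)
  if (max(abs(stats::residuals(ls))) < 1e-10 * max(1, stats::sd(y))) {
    # exact linear data: the M-estimation scale degenerates, return the line
    co <- stats::coef(ls)
    return(list(slope = unname(co[2]), intercept = unname(co[1]),
                se = 0, p = 0))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                   maxit = 200, acc = 1e-8)
  sm <- summary(fit)$coefficients
  z <- sm["x", "Value"] / sm["x", "Std. Error"]
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       se = unname(sm["x", "Std. Error"]),
       p = 2 * stats::pnorm(-abs(z)))
}
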