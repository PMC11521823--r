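# Composite marker discovery: paired classical tests intersected with the
# jackknifed PLS-DA VIP gate, plus effect sizes.
#
# A feature is selected as a therapy marker only when BOTH the paired t-test
# and the paired Wilcoxon signed-rank test stay significant after BH
# correction AND the jackknife 95% lower bound of its VIP reaches 1.

# cached sign-pattern matrices for the exact signed-rank null
.sign_cache <- new.env(parent = emptyenv())
.sign_matrix <- function(n) {
  key <- as.character(n)
  if (is.null(.sign_cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    storage.mode(m) <- "double"
    .sign_cache[[key]] <- m
  }
  .sign_cache[[key]]
}

# Two-sided paired signed-rank p-value. Zero differences are dropped
# (signed-rank convention). For n <= 14 the null is enumerated over all 2^n
# sign patterns, which stays exact under tied absolute differences; for
# larger n the exact distribution is used when ranks are untied, otherwise
# the tie-corrected normal approximation.
signed_rank_p <- function(d) {
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 14) {
    null_v <- as.vector(.sign_matrix(n) %*% r)
    p <- 2 * min(mean(null_v <= v + 1e-9), mean(null_v >= v - 1e-9))
  } else if (!any(duplicated(r))) {
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - n * (n + 1) / 4) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(p, 1)
}

#' Paired t- and Wilcoxon signed-rank tests per feature
#'
#' Two-sided tests on the per-pair differences AT - BT, with BH adjustment
#' within the block. Wilcoxon uses the exact null for small cohorts (zero
#' differences dropped). A feature whose differences are all zero yields
#' `p = 1` for both tests.
#'
#' @param block an `omics_block`.
#' @param design a `paired_design`.
#' @param type sample type of the block.
#' @param min_pairs minimum complete pairs per feature (default 3).
#' @return data.frame with columns `feature_id`, `n_pairs`, `p_t`,
#'   `p_wilcoxon`, `q_t`, `q_wilcoxon`.
#' @export
paired_tests <- function(block, design, type, min_pairs = 3) {
  pr <- design_pairs(design, type, block)
  .assert(nrow(pr) >= min_pairs, "not enough paired participants")
  bt <- block$values[, pr$bt, drop = FALSE]
  at <- block$values[, pr$at, drop = FALSE]
  res <- t(vapply(seq_len(nrow(bt)), function(i) {
    d <- at[i, ] - bt[i, ]
    d <- d[!is.na(d)]
    if (length(d) < min_pairs) return(c(length(d), NA_real_, NA_real_))
    if (all(d == 0)) return(c(length(d), 1, 1))
    pt <- if (stats::sd(d) == 0) 0 else stats::t.test(d)$p.value
    c(length(d), pt, signed_rank_p(d))
  }, numeric(3)))
  out <- data.frame(feature_id = rownames(block$values),
                    n_pairs = as.integer(res[, 1]),
                    p_t = res[, 2], p_wilcoxon = res[, 3], row.names = NULL)
  out$q_t <- stats::p.adjust(out$p_t, method = "BH")
  out$q_wilcoxon <- stats::p.adjust(out$p_wilcoxon, method = "BH")
  out
}

#' Jackknife confidence bounds for PLS-DA VIP scores
#'
#' Fits the full BT/AT PLS-DA on all paired samples, then refits leaving one
#' participant out at a time (both his BT and AT samples removed). The
#' delete-1 jackknife SE gives `CI = VIP_full +/- t_{n-1, (1+level)/2} * SE`.
#'
#' @param block an `omics_block`.
#' @param design a `paired_design`.
#' @param type sample type of the block.
#' @param n_components PLS components (default 2).
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `feature_id`, `vip`, `vip_lb`, `vip_ub`.
#' @export
vip_jackknife <- function(block, design, type, n_components = 2, level = 0.95) {
  pr <- design_pairs(design, type, block)
  n <- nrow(pr)
  .assert(n >= 5, "jackknife needs at least 5 paired participants")
  cols <- c(pr$bt, pr$at)
  cls <- rep(c("BT", "AT"), each = n)
  X <- t(block$values[, cols, drop = FALSE])
  feats <- rownames(block$values)
  full <- plsda_fit(X, cls, n_components)
  vip_of <- function(model) {
    v <- stats::setNames(rep(0, length(feats)), feats)
    v[model$features] <- vip_scores(model)
    v
  }
  vip_full <- vip_of(full)
  reps <- matrix(NA_real_, length(feats), n, dimnames = list(feats, NULL))
  ok <- logical(n)
  for (i in seq_len(n)) {
    drop <- c(i, n + i)
    fit <- tryCatch(suppressWarnings(
      plsda_fit(X[-drop, , drop = FALSE], cls[-drop], n_components)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("jackknife refit failed for participant %s; skipped",
                      pr$participant_id[i]))
      next
    }
    reps[, i] <- vip_of(fit)
    ok[i] <- TRUE
  }
  m <- sum(ok)
  .assert(m >= 3, "fewer than 3 successful jackknife replicates")
  reps <- reps[, ok, drop = FALSE]
  center <- rowMeans(reps)
  se <- sqrt((m - 1) / m * rowSums((reps - center)^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = m - 1)
  data.frame(feature_id = feats, vip = unname(vip_full),
             vip_lb = unname(vip_full - tq * se),
             vip_ub = unname(vip_full + tq * se), row.names = NULL)
}

#' Average effect size per feature
#'
#' `lfc`: mean over complete pairs of (log2 AT - log2 BT). `delta_pp`: the
#' same mean computed on relative-abundance percentages, i.e. the average
#' change in percentage points. Features without a complete pair get `NA`.
#'
#' @param block an `omics_block` (log2 intensities for `lfc`, percentages
#'   for `delta_pp`).
#' @param design a `paired_design`.
#' @param type sample type of the block.
#' @param mode `"lfc"` (plasma) or `"delta_pp"` (PTM relative abundances).
#' @return Named numeric vector of per-feature effects.
#' @export
effect_size <- function(block, design, type, mode = c("lfc", "delta_pp")) {
  mode <- match.arg(mode)
  pr <- design_pairs(design, type, block)
  bt <- block$values[, pr$bt, drop = FALSE]
  at <- block$values[, pr$at, drop = FALSE]
  eff <- rowMeans(at - bt, na.rm = TRUE)
  eff[rowSums(!is.na(at - bt)) == 0] <- NA_real_
  stats::setNames(eff, rownames(block$values))
}

#' Apply the composite marker selection rule
#'
#' `selected <=> q_t <= alpha AND q_wilcoxon <= alpha AND vip_lb >=
#' vip_threshold`.
#'
#' @param tests output of [paired_tests()].
#' @param vips output of [vip_jackknife()].
#' @param effects output of [effect_size()].
#' @param alpha significance level after BH correction (default 0.05).
#' @param vip_threshold VIP lower-bound gate (default 1).
#' @return data.frame of marker records (one row per feature) with the test
#'   columns, VIP bounds, `effect` and logical `selected`.
#' @export
select_markers <- function(tests, vips, effects = NULL, alpha = 0.05,
                           vip_threshold = 1.0) {
  .assert(setequal(tests$feature_id, vips$feature_id),
          "tests and vips must cover the same features")
  out <- merge(tests, vips, by = "feature_id", sort = FALSE)
  out <- out[match(tests$feature_id, out$feature_id), , drop = FALSE]
  out$effect <- if (is.null(effects)) NA_real_ else unname(effects[out$feature_id])
  out$selected <- !is.na(out$q_t) & out$q_t <= alpha &
    !is.na(out$q_wilcoxon) & out$q_wilcoxon <= alpha &
    out$vip_lb >= vip_threshold
  rownames(out) <- NULL
  out
}

#' Discover therapy markers in one block
#'
#' Runs [paired_tests()], [vip_jackknife()], [effect_size()] and
#' [select_markers()] in one call.
#'
#' @inheritParams paired_tests
#' @inheritParams select_markers
#' @param n_components PLS components.
#' @param mode effect-size mode, see [effect_size()].
#' @return The marker-record data.frame of [select_markers()].
#' @export
discover_markers <- function(block, design, type, alpha = 0.05,
                             vip_threshold = 1.0, n_components = 2,
                             mode = if (type == "plasma") "lfc" else "delta_pp") {
  tests <- paired_tests(block, design, type)
  vips <- vip_jackknife(block, design, type, n_components = n_components)
  eff <- effect_size(block, design, type, mode = mode)
  select_markers(tests, vips, eff, alpha = alpha, vip_threshold = vip_threshold)
}
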