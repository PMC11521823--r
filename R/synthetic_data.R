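# Synthetic paired BT/AT cohorts with known ground truth.
#
# The generator emulates the statistical structure of a 12-participant
# pre/post exercise-therapy study: two histone-PTM blocks (buccal swabs,
# PBMCs) measured in one batch, and a plasma protein block acquired in three
# batches (8/16/6 samples) that also contains before-only samples from
# enrolment dropouts. Planted therapy markers, participant clusters, ordinal
# response categories with effect-size trends, and both left-censored and
# random missingness give every downstream stage an exact oracle.

TREND_SHAPES <- c("increasing_linear", "decreasing_linear",
                  "plateau_first_two", "plateau_last_two")

# Per-category effect multipliers (moderate, intermediate, max) per shape.
.trend_multipliers <- list(
  increasing_linear = c(0.5, 1.0, 1.5),
  decreasing_linear = c(1.5, 1.0, 0.5),
  plateau_first_two = c(0.5, 0.5, 1.5),
  plateau_last_two  = c(0.5, 1.5, 1.5))

#' Configuration of the synthetic cohort
#'
#' Defaults mirror the emulated study: 12 paired participants, block sizes of
#' order 10^2 (PTMs) and ~340 (plasma protein groups), three plasma batches
#' of 8/16/6 samples (the extra before-therapy samples come from enrolment
#' dropouts, so the plasma block has 11 complete pairs), additive and
#' multiplicative batch effects, intensity-dependent left-censoring plus
#' random missingness, and planted BT-to-AT effects whose size follows the
#' participant's ordinal performance category through a trend shape.
#'
#' @param n_participants paired participants (default 12).
#' @param n_features named vector of per-block feature counts.
#' @param n_planted named vector of planted therapy markers per block.
#' @param effect_size planted BT-to-AT shift in log2 units at the
#'   intermediate category (other categories scale it by the trend shape).
#' @param noise_sd residual Gaussian noise SD on the log2 scale.
#' @param mean_range range of per-feature baseline means (log2 units).
#' @param batch_sizes plasma batch sample counts; must sum to the plasma
#'   sample count implied by `n_participants`, `n_dropout_bt`, `n_at_missing`.
#' @param n_dropout_bt dropout participants contributing a BT-only plasma
#'   sample.
#' @param n_at_missing completers without an AT plasma sample.
#' @param batch_shift additive batch offset magnitude (log2 units).
#' @param batch_scale multiplicative batch dispersion factor.
#' @param mnar_censor_quantile block-wide quantile below which values are
#'   censored (masked with probability `censor_prob`).
#' @param censor_prob masking probability for sub-quantile values.
#' @param mcar_rate independent random masking rate for remaining cells.
#' @param n_clusters planted participant clusters (correlated AT shifts).
#' @param cluster_effect SD of the cluster-specific shift (log2 units).
#' @param trend_shapes character vector recycled over planted markers.
#' @param healthy_fraction fraction of participants assigned to the healthy
#'   category of each lifestyle component.
#' @param perf_change_means mean agility percent change per performance
#'   category (moderate, intermediate, max).
#' @param perf_change_sd SD of the agility percent change.
#' @param seed integer seed; the whole cohort is reproducible given it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 12,
                         n_features = c(buccal = 60, pbmc = 60, plasma = 340),
                         n_planted = c(buccal = 10, pbmc = 10, plasma = 30),
                         effect_size = 1.5,
                         noise_sd = 0.5,
                         mean_range = c(16, 30),
                         batch_sizes = c(8, 16, 6),
                         n_dropout_bt = 7,
                         n_at_missing = 1,
                         batch_shift = 1.0,
                         batch_scale = 1.25,
                         mnar_censor_quantile = 0.15,
                         censor_prob = 0.95,
                         mcar_rate = 0.02,
                         n_clusters = 3,
                         cluster_effect = 0.8,
                         trend_shapes = TREND_SHAPES,
                         healthy_fraction = 0.5,
                         perf_change_means = c(5, 25, 60),
                         perf_change_sd = 2,
                         seed = 1) {
  cfg <- as.list(environment())
  rates <- c(mnar_censor_quantile, censor_prob, mcar_rate, healthy_fraction)
  .assert(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  .assert(all(names(n_planted) %in% names(n_features)) &&
            all(n_planted <= n_features[names(n_planted)]),
          "n_planted must not exceed n_features")
  .assert(n_clusters <= n_participants, "more clusters than participants")
  n_plasma <- (n_participants + n_dropout_bt) + (n_participants - n_at_missing)
  .assert(sum(batch_sizes) == n_plasma,
          sprintf("batch_sizes must sum to the plasma sample count (%d)", n_plasma))
  .assert(all(trend_shapes %in% TREND_SHAPES), "unknown trend shape")
  structure(cfg, class = "synth_config")
}

# Balanced assignment of n items to k labels, shuffled.
.balanced_labels <- function(n, labels) {
  sample(rep(labels, length.out = n))
}

.make_ptm_meta <- function(n, prefix) {
  sites <- c("K4", "K9", "K14", "K18", "K23", "K27", "K36", "K56", "K79")
  mods <- c("un", "me1", "me2", "me3", "ac")  # unmodified form included
  variants <- c("H3.1", "H3.3", "H3", "H4")
  # precursor groups of 2-5 co-measured modified forms, partitioning n
  group_sizes <- integer(0)
  remaining <- n
  while (remaining > 0) {
    k <- sample(2:5, 1)
    if (k > remaining) k <- remaining
    if (remaining - k == 1) k <- if (k < 5) k + 1 else k - 1  # no singleton tail
    group_sizes <- c(group_sizes, k)
    remaining <- remaining - k
  }
  gid <- rep(seq_along(group_sizes), group_sizes)
  variant <- rep(sample(variants, length(group_sizes), replace = TRUE), group_sizes)
  site <- rep(sample(sites, length(group_sizes), replace = TRUE), group_sizes)
  mod <- unlist(lapply(group_sizes, function(k) sample(mods, k)))
  data.frame(
    feature_id = sprintf("%s_%s_%s_%s_g%02d", prefix, variant, site, mod, gid),
    histone = sub("\\..*", "", variant), variant = variant, site = site,
    modification = mod, precursor_group = sprintf("%s_g%02d", prefix, gid),
    stringsAsFactors = FALSE)
}

.make_protein_meta <- function(n) {
  data.frame(
    feature_id = sprintf("PG%04d", seq_len(n)),
    protein = sprintf("PROT%04d_HUMAN", seq_len(n)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic paired multi-omics cohort
#'
#' @param config a [synth_config()].
#' @return A list with elements `blocks` (named list of `omics_block`:
#'   buccal, pbmc, plasma), `sheet` (`sample_sheet`), `participants`
#'   (`participant_sheet`), and `truth` — the ground-truth table holding
#'   planted marker ids per block, per-participant cluster labels, per-marker
#'   trend shapes, per-cell missingness mechanisms and the true batch
#'   parameters.
#' @export
generate_cohort <- function(config = synth_config()) {
  .assert(inherits(config, "synth_config"), "config must be a synth_config")
  set.seed(config$seed)
  n <- config$n_participants
  pid <- sprintf("P%02d", seq_len(n))
  drop_id <- if (config$n_dropout_bt > 0) sprintf("D%02d", seq_len(config$n_dropout_bt)) else character(0)

  performance <- .balanced_labels(n, c("moderate", "intermediate", "max"))
  self_assess <- .balanced_labels(n, c("improving", "improving", "unimpaired",
                                       "stagnating", "stagnating", "worsening"))
  # latent response clusters: with the default 3 clusters they coincide with
  # the ordinal performance groups (marker response amplitude is scaled per
  # category, so the clusters are expressed in the marker changes, matching
  # a cohort whose fused epigenetic clusters track therapy response);
  # other cluster counts get independent balanced labels
  clusters <- if (config$n_clusters == 3) {
    match(performance, c("moderate", "intermediate", "max"))
  } else {
    .balanced_labels(n, seq_len(config$n_clusters))
  }
  n_healthy <- max(1L, round(config$healthy_fraction * n))
  pick_healthy <- function(healthy, others) {
    lab <- c(rep(healthy, n_healthy),
             sample(others, n - n_healthy, replace = TRUE))
    sample(lab)
  }
  exercise <- pick_healthy("sportive", c("moderate", "sedentary"))
  diet <- pick_healthy("balanced", c("mixed", "unhealthy"))
  bmi <- pick_healthy("normal", "overweight")

  # agility: baseline strength plus a category-dependent percent improvement
  cat_idx <- match(performance, c("moderate", "intermediate", "max"))
  metrics <- c("flexion", "extension", "rotation")
  agility <- list()
  for (m in metrics) {
    bt <- stats::runif(n, 100, 300)
    pct <- stats::rnorm(n, config$perf_change_means[cat_idx], config$perf_change_sd)
    agility[[paste0(m, "_bt")]] <- bt
    agility[[paste0(m, "_at")]] <- bt * (1 + pct / 100)
  }
  participants <- as_participant_sheet(data.frame(
    participant_id = pid, exercise_class = exercise, diet_class = diet,
    bmi_class = bmi, performance = performance, self_assessment = self_assess,
    agility, stringsAsFactors = FALSE))

  truth <- list(clusters = stats::setNames(clusters, pid),
                planted = list(), trend = list(), mechanism = list(),
                batch_params = list(),
                healthy = list(exercise = "sportive", diet = "balanced",
                               bmi = "normal"))

  sheet_rows <- list()
  blocks <- list()
  for (ty in c("buccal", "pbmc", "plasma")) {
    p_bt <- if (ty == "plasma") c(pid, drop_id) else pid
    p_at <- if (ty == "plasma") pid[seq_len(n - config$n_at_missing)] else pid
    ids_bt <- paste0(ty, "_", p_bt, "_BT")
    ids_at <- paste0(ty, "_", p_at, "_AT")
    samp <- data.frame(
      sample_id = c(ids_bt, ids_at),
      participant_id = c(p_bt, p_at),
      timepoint = rep(c("BT", "AT"), c(length(p_bt), length(p_at))),
      sample_type = ty, stringsAsFactors = FALSE)
    if (ty == "plasma") {
      samp$batch <- sample(rep(sprintf("B%d", seq_along(config$batch_sizes)),
                               config$batch_sizes))
    } else samp$batch <- "B1"

    nf <- config$n_features[[ty]]
    meta <- if (ty == "plasma") .make_protein_meta(nf) else .make_ptm_meta(nf, ty)
    nf <- nrow(meta)
    np <- min(config$n_planted[[ty]], nf)
    planted <- sort(sample(nf, np))
    shapes <- rep(config$trend_shapes, length.out = np)
    signs <- rep(c(1, -1), length.out = np)

    mu <- stats::runif(nf, config$mean_range[1], config$mean_range[2])
    vals <- matrix(stats::rnorm(nf * nrow(samp), mean = mu, sd = config$noise_sd),
                   nrow = nf)
    rownames(vals) <- meta$feature_id
    colnames(vals) <- samp$sample_id

    # correlated within-cluster AT shifts on a random third of the
    # non-marker features (markers carry the cluster signal through their
    # category-scaled amplitudes instead, keeping them detectable)
    cl_feats <- sample(setdiff(seq_len(nf), planted),
                       max(1L, round(nf / 3)))
    cl_shift <- matrix(stats::rnorm(length(cl_feats) * config$n_clusters,
                                    0, config$cluster_effect),
                       nrow = length(cl_feats))
    at_cols <- which(samp$timepoint == "AT")
    for (j in at_cols) {
      p <- samp$participant_id[j]
      if (p %in% pid) {
        vals[cl_feats, j] <- vals[cl_feats, j] + cl_shift[, truth$clusters[[p]]]
      }
    }
    # planted therapy effects, scaled per participant by his category's
    # multiplier under the marker's trend shape
    for (k in seq_len(np)) {
      f <- planted[k]
      mult <- .trend_multipliers[[shapes[k]]]
      for (j in at_cols) {
        p <- samp$participant_id[j]
        if (p %in% pid) {
          ci <- cat_idx[match(p, pid)]
          vals[f, j] <- vals[f, j] + signs[k] * config$effect_size * mult[ci]
        }
      }
    }
    block <- omics_block(vals, feature_meta = meta)
    if (ty == "plasma" && length(config$batch_sizes) > 1) {
      be <- inject_batch_effects(block, as_sample_sheet(samp),
                                 shift = config$batch_shift,
                                 scale = config$batch_scale,
                                 seed = derive_seed(config$seed, paste0("batch_", ty)))
      block <- be$block
      truth$batch_params[[ty]] <- be$params
    }
    mi <- inject_missingness(block, config$mnar_censor_quantile,
                             config$mcar_rate,
                             seed = derive_seed(config$seed, paste0("miss_", ty)),
                             censor_prob = config$censor_prob)
    blocks[[ty]] <- mi$block
    truth$mechanism[[ty]] <- mi$mechanism
    truth$planted[[ty]] <- meta$feature_id[planted]
    # expected mean-effect profile shape over categories after the sign flip
    eff_shape <- ifelse(signs > 0, shapes,
                        c(increasing_linear = "decreasing_linear",
                          decreasing_linear = "increasing_linear",
                          plateau_first_two = "plateau_first_two",
                          plateau_last_two = "plateau_last_two")[shapes])
    truth$trend[[ty]] <- data.frame(feature_id = meta$feature_id[planted],
                                    shape = shapes, sign = signs,
                                    effect_shape = unname(eff_shape),
                                    stringsAsFactors = FALSE)
    sheet_rows[[ty]] <- samp
  }
  sheet <- as_sample_sheet(do.call(rbind, sheet_rows))
  list(blocks = blocks, sheet = sheet, participants = participants,
       truth = truth)
}

#' Inject additive and multiplicative batch effects
#'
#' Per batch `b`, each value becomes
#' `scale_b * (value - feature_mean) + feature_mean + shift_b`.
#' Batch offsets are spread symmetrically around zero with spacing `shift`
#' (so two equal batches differ by `shift` in mean) and scales spread around
#' 1 by factor `scale`, each with a small random jitter.
#'
#' @param block an `omics_block`.
#' @param sheet a `sample_sheet` covering every block sample with a batch.
#' @param shift additive offset magnitude (log2 units).
#' @param scale multiplicative factor (>1 spreads variances across batches).
#' @param seed integer seed.
#' @return list(block = modified block, params = per-batch data.frame of the
#'   true shift/scale used).
#' @export
inject_batch_effects <- function(block, sheet, shift, scale, seed = 1) {
  sheet <- as.data.frame(sheet)
  batch <- sheet$batch[match(block$sample_ids, sheet$sample_id)]
  .assert(!anyNA(batch), "every sample needs a batch label in the sheet")
  ub <- sort(unique(batch))
  if (length(ub) < 2) {
    warning("single batch: returning block unchanged")
    return(list(block = block,
                params = data.frame(batch = ub, shift = 0, scale = 1)))
  }
  set.seed(seed)
  B <- length(ub)
  centers <- (seq_len(B) - (B + 1) / 2) * 2 / (B - 1)  # -1 .. 1
  # jitter scales with the configured magnitude, so zero-magnitude effects
  # degenerate to the exact identity
  shifts <- shift * centers / 2 * (B - 1) +
    stats::rnorm(B, 0, 0.02 * abs(shift))
  scales <- scale^centers * exp(stats::rnorm(B, 0, 0.02 * abs(log(scale))))
  v <- block$values
  fm <- rowMeans(v, na.rm = TRUE)
  for (bi in seq_len(B)) {
    cols <- which(batch == ub[bi])
    v[, cols] <- scales[bi] * (v[, cols] - fm) + fm + shifts[bi]
  }
  list(block = omics_block(v, feature_meta = block$feature_meta),
       params = data.frame(batch = ub, shift = shifts, scale = scales))
}

#' Inject left-censored (NMAR) and random (MCAR) missingness
#'
#' Left-censoring is abundance-driven, as in label-free proteomics where
#' detection failure tracks a peptide's abundance class: every cell of a
#' feature whose mean intensity lies below the block-wide `censor_quantile`
#' is masked with probability `censor_prob` (the not-missing-at-random
#' regime). Each remaining cell is then masked independently with
#' probability `mcar_rate`.
#'
#' @param block an `omics_block`.
#' @param censor_quantile fraction in `[0, 1]`.
#' @param mcar_rate fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param censor_prob masking probability for sub-quantile values.
#' @return list(block = masked block, mechanism = character matrix with
#'   entries `"OBSERVED"`, `"NMAR"`, `"MCAR"` recording the true mechanism).
#' @export
inject_missingness <- function(block, censor_quantile, mcar_rate, seed = 1,
                               censor_prob = 0.95) {
  .assert(censor_quantile >= 0 && censor_quantile <= 1 &&
            mcar_rate >= 0 && mcar_rate <= 1, "rates must lie in [0, 1]")
  set.seed(seed)
  v <- block$values
  mech <- matrix("OBSERVED", nrow(v), ncol(v), dimnames = dimnames(v))
  if (censor_quantile > 0) {
    thr <- stats::quantile(v, censor_quantile, na.rm = TRUE, names = FALSE)
    low_feat <- which(rowMeans(v, na.rm = TRUE) < thr)
    cand <- which(!is.na(v) & row(v) %in% low_feat)
    hit <- cand[stats::runif(length(cand)) < censor_prob]
    v[hit] <- NA_real_
    mech[hit] <- "NMAR"
  }
  if (mcar_rate > 0) {
    cand <- which(!is.na(v))
    hit <- cand[stats::runif(length(cand)) < mcar_rate]
    v[hit] <- NA_real_
    mech[hit] <- "MCAR"
  }
  list(block = omics_block(v, feature_meta = block$feature_meta),
       mechanism = mech)
}
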