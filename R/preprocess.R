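# Preprocessing: feature filters, quantile normalization, NMAR/MAR
# imputation, empirical-Bayes batch adjustment, and precursor-group relative
# abundances.
#
# Stage order is fixed: filter -> quantile normalize -> classify missingness
# -> impute -> batch adjust -> (PTM blocks) relative abundance.

#' Imputation parameters
#'
#' @param nmar_threshold per-condition missing fraction above which a
#'   (feature, condition) is treated as not-missing-at-random (default 0.75;
#'   equality resolves to MAR).
#' @param nmar_percentile block-wide low-intensity percentile defining the
#'   censored mean (default 0.01).
#' @param mar_sd SD of the MAR imputation draw, log2 units (default 0.5).
#' @param seed integer seed for the imputation draws.
#' @return list of class `imputation_params`.
#' @export
imputation_params <- function(nmar_threshold = 0.75, nmar_percentile = 0.01,
                              mar_sd = 0.5, seed = 1) {
  .assert(nmar_threshold > 0 && nmar_threshold < 1, "nmar_threshold must lie in (0,1)")
  .assert(nmar_percentile > 0 && nmar_percentile < 1, "nmar_percentile must lie in (0,1)")
  .assert(mar_sd > 0, "mar_sd must be positive")
  structure(list(nmar_threshold = nmar_threshold,
                 nmar_percentile = nmar_percentile,
                 mar_sd = mar_sd, seed = seed),
            class = "imputation_params")
}

# Columns of the block belonging to paired samples of a type.
.paired_columns <- function(block, design, type) {
  p <- design_pairs(design, type, block)
  list(bt = p$bt, at = p$at, pairs = p)
}

#' Filter PTM features by missingness over paired samples
#'
#' Drops modifications with `max_missing` or more missing values over the
#' paired samples (both timepoints pooled).
#'
#' @param block a PTM `omics_block`.
#' @param design a `paired_design`.
#' @param type sample type of the block (`"buccal"` or `"pbmc"`).
#' @param max_missing drop threshold: missing count `>= max_missing` drops
#'   the feature (default 10).
#' @return The retained block, with a `drop_report` attribute (data.frame of
#'   dropped feature ids and their missing counts).
#' @export
filter_ptm_features <- function(block, design, type = "buccal", max_missing = 10) {
  pc <- .paired_columns(block, design, type)
  cols <- c(pc$bt, pc$at)
  nmiss <- rowSums(is.na(block$values[, cols, drop = FALSE]))
  drop <- nmiss >= max_missing
  report <- data.frame(feature_id = rownames(block$values)[drop],
                       n_missing_paired = nmiss[drop], row.names = NULL)
  out <- omics_block(block$values[!drop, , drop = FALSE],
                     feature_meta = block$feature_meta[!drop, , drop = FALSE])
  attr(out, "drop_report") <- report
  out
}

#' Filter protein groups by paired-participant coverage
#'
#' Retains protein groups observed (any intensity) in at least `min_paired`
#' paired participants at BT and, independently, at least `min_paired` at AT
#' (AND rule).
#'
#' @param block the plasma `omics_block`.
#' @param design a `paired_design`.
#' @param min_paired minimum paired participants per timepoint (default 9,
#'   i.e. 80% of 11 paired participants).
#' @return The retained block with a `drop_report` attribute.
#' @export
filter_protein_groups <- function(block, design, min_paired = 9) {
  pc <- .paired_columns(block, design, "plasma")
  obs_bt <- rowSums(!is.na(block$values[, pc$bt, drop = FALSE]))
  obs_at <- rowSums(!is.na(block$values[, pc$at, drop = FALSE]))
  keep <- obs_bt >= min_paired & obs_at >= min_paired
  report <- data.frame(feature_id = rownames(block$values)[!keep],
                       n_bt = obs_bt[!keep], n_at = obs_at[!keep],
                       row.names = NULL)
  out <- omics_block(block$values[keep, , drop = FALSE],
                     feature_meta = block$feature_meta[keep, , drop = FALSE])
  attr(out, "drop_report") <- report
  out
}

#' Quantile-normalize an intensity block
#'
#' Maps every sample's observed values onto the cross-sample mean quantile
#' vector. Ranks ignore missing cells: each sample's empirical quantiles are
#' interpolated at its own observed count, so complete samples end up with
#' identical sorted vectors and the operation is idempotent on complete
#' matrices. Tied values receive the mean of their target quantiles.
#'
#' @param block an `omics_block` with at least 2 samples.
#' @return The normalized `omics_block` (mask unchanged).
#' @export
quantile_normalize <- function(block) {
  v <- block$values
  .assert(ncol(v) >= 2, "quantile normalization needs at least 2 samples")
  nobs <- colSums(!is.na(v))
  low <- which(nobs < 2)
  .assert(length(low) == 0,
          paste("sample(s) with fewer than 2 observed values:",
                paste(colnames(v)[low], collapse = ", ")))
  grid <- seq(0, 1, length.out = nrow(v))
  # reference: mean across samples of each sample's quantile function
  qmat <- vapply(seq_len(ncol(v)), function(j) {
    x <- sort(v[, j])
    stats::approx(seq(0, 1, length.out = length(x)), x, xout = grid,
                  rule = 2)$y
  }, numeric(length(grid)))
  ref <- rowMeans(qmat)
  out <- v
  for (j in seq_len(ncol(v))) {
    idx <- which(!is.na(v[, j]))
    r <- rank(v[idx, j], ties.method = "average")
    p <- (r - 1) / (length(idx) - 1)
    out[idx, j] <- stats::approx(grid, ref, xout = p, rule = 2)$y
  }
  omics_block(out, feature_meta = block$feature_meta)
}

#' Classify missing cells as NMAR or MAR per condition
#'
#' Per (feature, condition BT/AT): `NMAR` when the missing fraction exceeds
#' `nmar_threshold`, `MAR` when some but at most that fraction are missing,
#' `OBSERVED` when none are.
#'
#' @param block an `omics_block`.
#' @param sheet a `sample_sheet` giving each sample's timepoint.
#' @param params an [imputation_params()].
#' @return data.frame with columns `feature_id`, `condition`, `label`,
#'   `n_missing`, `n_total`.
#' @export
classify_missingness <- function(block, sheet, params = imputation_params()) {
  sheet <- as.data.frame(sheet)
  tp <- sheet$timepoint[match(block$sample_ids, sheet$sample_id)]
  .assert(!anyNA(tp), "every block sample needs a timepoint in the sheet")
  out <- list()
  for (cond in c("BT", "AT")) {
    cols <- which(tp == cond)
    if (length(cols) == 0) next
    nm <- rowSums(is.na(block$values[, cols, drop = FALSE]))
    frac <- nm / length(cols)
    label <- ifelse(nm == 0, "OBSERVED",
                    ifelse(frac > params$nmar_threshold, "NMAR", "MAR"))
    out[[cond]] <- data.frame(feature_id = rownames(block$values),
                              condition = cond, label = label,
                              n_missing = nm, n_total = length(cols),
                              row.names = NULL)
  }
  do.call(rbind, out)
}

#' Impute missing intensities by missingness mechanism
#'
#' NMAR cells are drawn from `Normal(mu_low, sigma_med^2)` where `mu_low` is
#' the mean of all observed values below the block-wide `nmar_percentile`
#' quantile and `sigma_med` the median over features of the per-feature SD.
#' MAR cells are drawn from `Normal(condition mean of the feature's observed
#' values, mar_sd^2)`. Observed cells are untouched. A MAR
#' (feature, condition) with no observed value falls back to the NMAR rule
#' with a warning.
#'
#' @param block an `omics_block`.
#' @param labels output of [classify_missingness()] covering every missing
#'   cell.
#' @param sheet the `sample_sheet` (timepoints).
#' @param params an [imputation_params()]; draws are reproducible given its
#'   seed.
#' @return A complete `omics_block`.
#' @export
impute_block <- function(block, labels, sheet, params = imputation_params()) {
  sheet <- as.data.frame(sheet)
  v <- block$values
  tp <- sheet$timepoint[match(block$sample_ids, sheet$sample_id)]
  obs <- v[!is.na(v)]
  q1 <- stats::quantile(obs, params$nmar_percentile, names = FALSE)
  low <- obs[obs < q1]
  mu_low <- if (length(low) > 0) mean(low) else q1
  sds <- apply(v, 1, stats::sd, na.rm = TRUE)
  sigma_med <- stats::median(sds, na.rm = TRUE)
  set.seed(params$seed)
  key <- paste(labels$feature_id, labels$condition)
  lab <- stats::setNames(labels$label, key)
  for (cond in c("BT", "AT")) {
    cols <- which(tp == cond)
    if (length(cols) == 0) next
    for (i in seq_len(nrow(v))) {
      miss <- cols[is.na(v[i, cols])]
      if (length(miss) == 0) next
      li <- lab[[paste(rownames(v)[i], cond)]]
      .assert(!is.null(li) && li != "OBSERVED",
              paste("no missingness label for", rownames(v)[i], cond))
      if (li == "MAR") {
        m <- mean(v[i, cols], na.rm = TRUE)
        if (is.nan(m)) {
          warning(sprintf("feature %s condition %s: MAR with no observed value, using NMAR rule",
                          rownames(v)[i], cond))
          v[i, miss] <- stats::rnorm(length(miss), mu_low, sigma_med)
        } else {
          v[i, miss] <- stats::rnorm(length(miss), m, params$mar_sd)
        }
      } else {
        v[i, miss] <- stats::rnorm(length(miss), mu_low, sigma_med)
      }
    }
  }
  omics_block(v, feature_meta = block$feature_meta)
}

#' Empirical-Bayes batch adjustment
#'
#' Adjusts intensities for batch effects with the parametric empirical-Bayes
#' location/scale model (ComBat): feature-wise standardization, shrinkage of
#' per-batch additive and multiplicative effects, back-transformation. Runs
#' after imputation (no missing values) and uses no covariates.
#'
#' @param block a complete `omics_block`.
#' @param sheet a `sample_sheet` with batch labels.
#' @return The adjusted `omics_block`.
#' @export
combat_adjust <- function(block, sheet) {
  sheet <- as.data.frame(sheet)
  .assert(!anyNA(block$values), "combat_adjust requires a complete block (impute first)")
  batch <- sheet$batch[match(block$sample_ids, sheet$sample_id)]
  .assert(!anyNA(batch), "every sample needs a batch label")
  tab <- table(batch)
  .assert(length(tab) >= 2, "need at least 2 batches")
  small <- names(tab)[tab < 2]
  .assert(length(small) == 0,
          paste("batch(es) with a single sample:", paste(small, collapse = ", ")))
  adj <- sva::ComBat(dat = block$values, batch = factor(batch),
                     par.prior = TRUE, prior.plots = FALSE)
  omics_block(adj, feature_meta = block$feature_meta)
}

#' Relative abundance within precursor groups
#'
#' Converts log2 intensities to the linear scale and expresses each modified
#' peptide form as a percentage of its precursor group's total, per sample:
#' `p_i = 100 * 2^x_i / sum_j 2^x_j`. Groups with all members missing in a
#' sample yield missing percentages; a partially observed group is normalized
#' over its observed members.
#'
#' @param block a PTM `omics_block` whose `feature_meta` has
#'   `precursor_group`.
#' @return An `omics_block` of percentages (class also
#'   `relative_abundance_block`).
#' @export
relative_abundance <- function(block) {
  .assert("precursor_group" %in% names(block$feature_meta),
          "feature_meta must contain precursor_group")
  lin <- 2^block$values
  out <- lin
  for (g in unique(block$feature_meta$precursor_group)) {
    rows <- which(block$feature_meta$precursor_group == g)
    tot <- colSums(lin[rows, , drop = FALSE], na.rm = TRUE)
    tot[tot == 0] <- NA_real_
    out[rows, ] <- 100 * sweep(lin[rows, , drop = FALSE], 2, tot, "/")
  }
  rb <- omics_block(out, feature_meta = block$feature_meta)
  class(rb) <- c("relative_abundance_block", class(rb))
  rb
}

#' Run the full preprocessing chain on one block
#'
#' filter -> quantile normalize -> classify -> impute -> batch adjust (when
#' >1 batch) -> relative abundance (PTM blocks).
#'
#' @param block an `omics_block`.
#' @param sheet a `sample_sheet`.
#' @param design a `paired_design`.
#' @param type `"buccal"`, `"pbmc"` or `"plasma"`.
#' @param params an [imputation_params()].
#' @param max_missing PTM filter threshold.
#' @param min_paired protein-group filter threshold.
#' @return list with the preprocessed `block`, the `labels` table and the
#'   filter `drop_report`.
#' @export
preprocess_block <- function(block, sheet, design, type,
                             params = imputation_params(),
                             max_missing = 10, min_paired = 9) {
  filt <- if (type == "plasma") {
    filter_protein_groups(block, design, min_paired = min_paired)
  } else {
    filter_ptm_features(block, design, type = type, max_missing = max_missing)
  }
  report <- attr(filt, "drop_report")
  norm <- quantile_normalize(filt)
  labels <- classify_missingness(norm, sheet, params)
  imp <- impute_block(norm, labels, sheet, params)
  batches <- unique(as.data.frame(sheet)$batch[match(imp$sample_ids,
                                                     sheet$sample_id)])
  if (length(batches) > 1) imp <- combat_adjust(imp, sheet)
  if (type != "plasma") imp <- relative_abundance(imp)
  list(block = imp, labels = labels, drop_report = report)
}
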