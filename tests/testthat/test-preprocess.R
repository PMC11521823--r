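test_that("PTM filter drops features at the missing-count boundary", {
  x <- make_paired_block(3, 12, seed = 1)   # 24 paired samples
  v <- x$block$values
  v[1, 1:10] <- NA                           # 10 missing -> dropped
  v[2, 1:9] <- NA                            # 9 missing -> retained
  blk <- omics_block(v)
  out <- filter_ptm_features(blk, x$design, "buccal", max_missing = 10)
  expect_setequal(rownames(out$values), c("f002", "f003"))
  expect_equal(attr(out, "drop_report")$feature_id, "f001")
  expect_equal(attr(out, "drop_report")$n_missing_paired, 10)
})

test_that("protein-group filter applies the AND rule over BT and AT coverage", {
  x <- make_paired_block(3, 12, type = "plasma", seed = 2)
  v <- x$block$values
  # f001: 9 BT and 9 AT participants -> retained
  v[1, 1:3] <- NA; v[1, 13:15] <- NA
  # f002: 11 BT but 8 AT -> dropped
  v[2, 1] <- NA; v[2, 13:16] <- NA
  # f003: never observed -> dropped
  v[3, ] <- NA
  blk <- omics_block(v)
  out <- filter_protein_groups(blk, x$design, min_paired = 9)
  expect_equal(rownames(out$values), "f001")
  expect_setequal(attr(out, "drop_report")$feature_id, c("f002", "f003"))
})

test_that("quantile normalization maps samples onto the mean quantile vector", {
  v <- matrix(c(1, 3, 2, 4), nrow = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  qn <- quantile_normalize(omics_block(v))
  expect_equal(unname(qn$values[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(qn$values[, "s2"]), c(1.5, 3.5))

  x <- make_paired_block(50, 6, seed = 7)
  qn1 <- quantile_normalize(x$block)
  # complete samples share identical sorted vectors
  sorted <- apply(qn1$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotent on complete matrices
  qn2 <- quantile_normalize(qn1)
  expect_equal(qn2$values, qn1$values)
  # missing cells stay missing, observed ranks are preserved
  v2 <- x$block$values; v2[3, 2] <- NA
  qn3 <- quantile_normalize(omics_block(v2))
  expect_true(is.na(qn3$values[3, 2]))
  expect_equal(order(qn3$values[, 1]), order(v2[, 1]))
})

test_that("missingness classification applies the 75% per-condition rule", {
  x <- make_paired_block(3, 12, seed = 3)
  v <- x$block$values
  v[1, 1:10] <- NA   # 10/12 BT missing (83%) -> NMAR
  v[2, 13:18] <- NA  # 6/12 AT missing (50%) -> MAR
  labs <- classify_missingness(omics_block(v), x$sheet)
  get <- function(f, cond) labs$label[labs$feature_id == f & labs$condition == cond]
  expect_equal(get("f001", "BT"), "NMAR")
  expect_equal(get("f002", "AT"), "MAR")
  expect_equal(get("f003", "BT"), "OBSERVED")
  expect_equal(get("f003", "AT"), "OBSERVED")
  # exactly 75% resolves to MAR (9 of 12)
  v[3, 1:9] <- NA
  labs2 <- classify_missingness(omics_block(v), x$sheet)
  expect_equal(labs2$label[labs2$feature_id == "f003" & labs2$condition == "BT"],
               "MAR")
})

test_that("MAR imputation draws from Normal(condition mean, 0.5) and leaves observed cells", {
  n <- 3000; nmiss <- 1000
  sid <- sprintf("S%04d", 1:n)
  sheet <- as_sample_sheet(data.frame(
    sample_id = sid, participant_id = sprintf("P%04d", 1:n),
    timepoint = "BT", sample_type = "plasma", batch = "B1"))
  set.seed(21)
  v <- rbind(f1 = stats::rnorm(n, 18.4, 1),
             matrix(stats::rnorm(5 * n, 20, 1), 5,
                    dimnames = list(sprintf("g%d", 1:5), NULL)))
  colnames(v) <- sid
  v[1, 1:nmiss] <- NA
  blk <- omics_block(v)
  cond_mean <- mean(v[1, ], na.rm = TRUE)
  labs <- classify_missingness(blk, sheet)
  imp <- impute_block(blk, labs, sheet, imputation_params(seed = 42))
  draws <- imp$values[1, 1:nmiss]
  expect_equal(mean(draws), cond_mean, tolerance = 0.05)
  expect_equal(stats::sd(draws), 0.5, tolerance = 0.03)
  obs <- !is.na(v)
  expect_identical(imp$values[obs], v[obs])
  expect_equal(sum(is.na(imp$values)), 0L)
})

test_that("NMAR imputation centers below the first percentile of the block", {
  x <- make_paired_block(200, 12, seed = 9)
  mi <- inject_missingness(x$block, 0.15, 0, seed = 2)
  labs <- classify_missingness(mi$block, x$sheet)
  imp <- impute_block(mi$block, labs, x$sheet, imputation_params(seed = 7))
  lab_of <- stats::setNames(labs$label, paste(labs$feature_id, labs$condition))
  tp <- as.data.frame(x$sheet)$timepoint[match(mi$block$sample_ids,
                                               x$sheet$sample_id)]
  idx <- which(is.na(mi$block$values))
  nr <- nrow(mi$block$values)
  cond <- tp[(idx - 1) %/% nr + 1]
  fid <- rownames(mi$block$values)[(idx - 1) %% nr + 1]
  nmar_cells <- idx[lab_of[paste(fid, cond)] == "NMAR"]
  expect_gt(length(nmar_cells), 100)
  frac_below <- mean(imp$values[nmar_cells] <
                       stats::median(mi$block$values, na.rm = TRUE))
  expect_gte(frac_below, 0.99)
})

test_that("whole-condition missingness routes to the censored (NMAR) model", {
  x <- make_paired_block(4, 6, seed = 10)
  v <- x$block$values
  v[1, 1:6] <- NA  # whole BT condition missing -> NMAR by the 75% rule
  v[2, 1:5] <- NA  # 5/6 BT missing (83%) -> NMAR
  blk <- omics_block(v)
  labs <- classify_missingness(blk, x$sheet)
  expect_equal(labs$label[labs$feature_id == "f001" & labs$condition == "BT"],
               "NMAR")
  imp <- impute_block(blk, labs, x$sheet, imputation_params(seed = 1))
  expect_false(anyNA(imp$values))
})

test_that("ComBat adjustment removes planted batch shifts and keeps condition effects", {
  set.seed(11)
  nf <- 200; np <- 15
  x <- make_paired_block(nf, np, planted = 1:50, eff = 1.2, sd = 0.5,
                         type = "plasma", seed = 11)
  sheet <- as.data.frame(x$sheet)
  sheet$batch <- rep(rep(c("B1", "B2"), c(8, 7)), 2)  # constant per participant
  sheet <- as_sample_sheet(sheet)
  inj <- inject_batch_effects(x$block, sheet, shift = 2, scale = 1, seed = 3)
  adj <- combat_adjust(inj$block, sheet)
  b <- sheet$batch[match(adj$sample_ids, sheet$sample_id)]
  md <- rowMeans(adj$values[, b == "B1"]) - rowMeans(adj$values[, b == "B2"])
  expect_lt(abs(mean(md)), 0.1)
  expect_gte(stats::cor(effect_size(x$block, x$design, "plasma"),
                        effect_size(adj, x$design, "plasma")), 0.95)
})

test_that("ComBat preconditions: single batch and singleton batches error", {
  x <- make_paired_block(20, 4, seed = 12)
  expect_error(combat_adjust(x$block, x$sheet), "at least 2 batches")
  sheet <- as.data.frame(x$sheet)
  sheet$batch <- c("B1", rep("B2", 7))
  expect_error(combat_adjust(x$block, as_sample_sheet(sheet)), "B1")
})

test_that("ComBat barely perturbs data without true batch structure", {
  x <- make_paired_block(150, 10, seed = 14, sd = 0.5)
  sheet <- as.data.frame(x$sheet)
  sheet$batch <- rep(rep(c("B1", "B2"), 5), 2)
  adj <- combat_adjust(x$block, as_sample_sheet(sheet))
  rms <- sqrt(mean((adj$values - x$block$values)^2))
  expect_lt(rms, 0.5)  # below the noise SD
})

test_that("relative abundance converts to linear percentages within groups", {
  v <- matrix(c(1, 1, 2, 3, 3, 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(feature_id = c("a", "b", "c"), precursor_group = "g1")
  ra <- relative_abundance(omics_block(v, meta))
  expect_equal(unname(ra$values[, "s1"]), c(25, 25, 50))  # linear (2,2,4)
  expect_equal(unname(ra$values[, "s2"]), rep(100 / 3, 3))
  expect_equal(unname(colSums(ra$values)), c(100, 100))
  # two equal members -> 50/50
  v2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  ra2 <- relative_abundance(omics_block(v2, data.frame(feature_id = c("a", "b"),
                                                       precursor_group = "g")))
  expect_equal(unname(ra2$values[, 1]), c(50, 50))
  # all-missing sample in a group -> missing percentages
  v3 <- matrix(c(NA, NA, 1, 2), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  ra3 <- relative_abundance(omics_block(v3, data.frame(feature_id = c("a", "b"),
                                                       precursor_group = "g")))
  expect_true(all(is.na(ra3$values[, "s1"])))
  expect_false(anyNA(ra3$values[, "s2"]))
})

test_that("missingness mechanisms are recovered from the 75% rule on synthetic cohorts", {
  agree <- vapply(1:3, function(s) {
    co <- generate_cohort(synth_config(seed = s))
    mean(vapply(c("buccal", "pbmc", "plasma"), function(ty) {
      blk <- co$blocks[[ty]]
      labs <- classify_missingness(blk, co$sheet)
      lb <- stats::setNames(labs$label, paste(labs$feature_id, labs$condition))
      tp <- as.data.frame(co$sheet)$timepoint[match(blk$sample_ids,
                                                    co$sheet$sample_id)]
      idx <- which(is.na(blk$values))
      nr <- nrow(blk$values)
      pred <- lb[paste(rownames(blk$values)[(idx - 1) %% nr + 1],
                       tp[(idx - 1) %/% nr + 1])]
      truthm <- co$truth$mechanism[[ty]][idx]
      mean((truthm == "NMAR" & pred == "NMAR") |
             (truthm == "MCAR" & pred == "MAR"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(agree >= 0.9))
})
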