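# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Minimal paired single-type cohort: npairs participants, nf features,
# optional planted AT shift on `planted` rows (in units of the per-pair
# difference SD when `eff_unit = "diff_sd"`).
make_paired_block <- function(nf, npairs, planted = integer(0), eff = 0,
                              sd = 1, type = "buccal", seed = 1,
                              mu_range = c(16, 30)) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(npairs))
  sid <- c(paste0(type, "_", pid, "_BT"), paste0(type, "_", pid, "_AT"))
  mu <- stats::runif(nf, mu_range[1], mu_range[2])
  v <- matrix(stats::rnorm(nf * 2 * npairs, mu, sd), nf)
  rownames(v) <- sprintf("f%03d", seq_len(nf))
  colnames(v) <- sid
  if (length(planted) > 0) {
    v[planted, npairs + seq_len(npairs)] <-
      v[planted, npairs + seq_len(npairs)] + eff
  }
  sheet <- as_sample_sheet(data.frame(
    sample_id = sid, participant_id = rep(pid, 2),
    timepoint = rep(c("BT", "AT"), each = npairs),
    sample_type = type, batch = "B1", stringsAsFactors = FALSE))
  list(block = omics_block(v), sheet = sheet,
       design = build_paired_design(sheet))
}

# Small sample sheet data.frame for IO tests.
mini_sheet <- function(ids = c("S1", "S2", "S3", "S4")) {
  as_sample_sheet(data.frame(
    sample_id = ids,
    participant_id = rep(c("P1", "P2"), length.out = length(ids)),
    timepoint = rep(c("BT", "AT"), each = ceiling(length(ids) / 2))[seq_along(ids)],
    sample_type = "buccal", batch = "B1", stringsAsFactors = FALSE))
}

# Participant sheet with constant percent change per performance category.
mini_participants <- function(n = 12, pct = c(moderate = 5, intermediate = 25,
                                              max = 60), seed = 1) {
  set.seed(seed)
  perf <- rep(names(pct), length.out = n)
  bt <- stats::runif(n, 100, 300)
  mk <- function() bt * (1 + pct[perf] / 100)
  as_participant_sheet(data.frame(
    participant_id = sprintf("P%02d", 1:n),
    exercise_class = rep(c("sportive", "sedentary"), length.out = n),
    diet_class = rep(c("balanced", "mixed"), length.out = n),
    bmi_class = rep(c("normal", "overweight"), length.out = n),
    performance = perf,
    self_assessment = rep(c("improving", "stagnating", "worsening", "unimpaired"),
                          length.out = n),
    flexion_bt = bt, flexion_at = mk(),
    extension_bt = bt, extension_at = mk(),
    rotation_bt = bt, rotation_at = mk(),
    stringsAsFactors = FALSE))
}
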