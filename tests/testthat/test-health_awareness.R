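# Builders for the health-map tests: 12 participants, half in the healthy
# lifestyle category, indicator features separated by category.
make_health_cohort <- function(seed = 1, unhealthy_mean = 0, noise = 0.3,
                               shift_frac = 0, nf = 20) {
  set.seed(seed)
  n <- 12
  pid <- sprintf("P%02d", 1:n)
  lifestyle <- stats::setNames(rep(c("sportive", "sedentary"), each = 6), pid)
  cent <- rbind(sportive = c(rep(1, 10), rep(0, nf - 10)),
                sedentary = c(rep(unhealthy_mean, 10), rep(0, nf - 10)))
  bt <- cent[lifestyle, ] + matrix(rnorm(n * nf, 0, noise), n)
  rownames(bt) <- pid
  colnames(bt) <- sprintf("f%02d", seq_len(nf))
  hm <- colMeans(bt[lifestyle == "sportive", , drop = FALSE])
  at <- bt + shift_frac * (matrix(hm, n, nf, byrow = TRUE) - bt) +
    matrix(rnorm(n * nf, 0, 0.05), n)
  dimnames(at) <- dimnames(bt)
  list(bt = bt, at = at, lifestyle = lifestyle, pid = pid)
}

test_that("health maps separate lifestyle categories and refit deterministically", {
  hc <- make_health_cohort(seed = 2)
  m1 <- fit_health_map(hc$bt, hc$lifestyle, "sportive")
  m2 <- fit_health_map(hc$bt, hc$lifestyle, "sportive")
  expect_identical(m1, m2)
  c1 <- m1$bt_scores[hc$lifestyle == "sportive", 1]
  c2 <- m1$bt_scores[hc$lifestyle == "sedentary", 1]
  expect_true(all(range(c1) < min(c2)) || all(range(c1) > max(c2)))
  # permuted labels collapse the separation statistic toward the null
  sep <- function(map, lab) {
    s <- map$bt_scores[, 1]
    abs(mean(s[lab == "sportive"]) - mean(s[lab == "sedentary"])) / stats::sd(s)
  }
  set.seed(9)
  perm_gap <- replicate(20, {
    lab <- stats::setNames(sample(hc$lifestyle), names(hc$lifestyle))
    sep(fit_health_map(hc$bt, lab, "sportive"), lab)
  })
  expect_gt(sep(m1, hc$lifestyle), max(perm_gap) * 0.8)
  expect_gt(sep(m1, hc$lifestyle), mean(perm_gap))
})

test_that("AT projection uses the frozen BT transform", {
  hc <- make_health_cohort(seed = 3)
  map <- fit_health_map(hc$bt, hc$lifestyle, "sportive")
  # identical profiles land on identical coordinates, d = 0
  same <- project_at(map, hc$bt)
  expect_equal(unname(same), unname(map$bt_scores), tolerance = 1e-10)
  d0 <- therapy_effect_distance(map, same)
  expect_equal(unname(d0), rep(0, 12), tolerance = 1e-10)
  # linear-algebra oracle: projected coordinates equal the frozen
  # centering/scaling followed by the stored rotation, computed by hand
  Xs <- sweep(sweep(hc$at[, map$model$features], 2, map$model$means),
              2, map$model$scales, "/")
  manual <- Xs %*% map$model$rotation
  expect_equal(unname(project_at(map, hc$at)), unname(manual),
               tolerance = 1e-12)
})

test_that("therapy-effect distance is Euclidean and rotation-invariant", {
  hc <- make_health_cohort(seed = 4)
  map <- fit_health_map(hc$bt, hc$lifestyle, "sportive")
  at <- map$bt_scores
  at[1, ] <- map$bt_scores[1, ] + c(3, 4)
  d <- sqrt(rowSums((map$bt_scores - at)^2))
  expect_equal(unname(d[1]), 5)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  d_rot <- sqrt(rowSums(((map$bt_scores %*% R) - (at %*% R))^2))
  expect_equal(d_rot, d, tolerance = 1e-10)
})

test_that("Kendall's W matches its closed-form and brute-force evaluation", {
  # identical rankings across 3 raters
  r <- cbind(a = 1:12, b = 1:12, c = 1:12)
  expect_equal(kendalls_w(r)$W, 1)
  # two exactly reversed raters
  r2 <- cbind(a = 1:10, b = 10:1)
  expect_equal(kendalls_w(r2)$W, 0)
  # 3 x 4 toy table against an independent brute-force computation
  toy <- cbind(r1 = c(3, 1, 4, 2), r2 = c(3, 2, 4, 1), r3 = c(2, 1, 4, 3))
  out <- kendalls_w(toy)
  Rk <- apply(toy, 2, rank)
  Ri <- rowSums(Rk)
  S <- sum((Ri - mean(Ri))^2)
  W_brute <- 12 * S / (3^2 * (4^3 - 4))  # no ties
  expect_equal(out$W, W_brute, tolerance = 1e-12)
  expect_equal(out$chi2, 3 * (4 - 1) * W_brute, tolerance = 1e-12)
  expect_equal(out$df, 3)
  # tie-corrected W agrees with vegan on tied data
  tied <- cbind(r1 = c(1, 1, 2, 3, 4), r2 = c(2, 1, 3, 3, 5), r3 = c(1, 2, 2, 4, 5))
  ours <- kendalls_w(tied)$W
  ref <- suppressWarnings(vegan::kendall.global(tied))$Concordance_analysis["W", 1]
  expect_equal(ours, unname(ref), tolerance = 1e-10)
  expect_error(kendalls_w(cbind(rep(1, 5), rep(2, 5))), "constant")
})

test_that("rank concordance reflects shared versus independent latent effects", {
  w_shared <- w_indep <- numeric(25)
  for (s in 1:25) {
    set.seed(s)
    lat <- runif(12)
    w_shared[s] <- kendalls_w(sapply(1:3, function(j) lat + rnorm(12, 0, 0.08)))$W
    w_indep[s] <- kendalls_w(sapply(1:3, function(j) runif(12)))$W
  }
  expect_gte(mean(w_shared), 0.8)
  expect_equal(mean(w_indep), 1 / 3, tolerance = 0.12)
})

test_that("healthy ranges gate on VIP and collapse for constant healthy members", {
  hc <- make_health_cohort(seed = 5)
  map <- fit_health_map(hc$bt, hc$lifestyle, "sportive")
  rng <- healthy_range(map, hc$bt, hc$at)
  vips <- vip_scores(map$model)
  expect_equal(nrow(rng), sum(vips >= 1))
  expect_true(all(rng$lo <= rng$hi))
  expect_true(all(rng$weight >= 1))
  # identical healthy members give a zero-width range
  bt2 <- hc$bt
  bt2[1:6, ] <- matrix(bt2[1, ], 6, ncol(bt2), byrow = TRUE)
  map2 <- suppressWarnings(fit_health_map(bt2, hc$lifestyle, "sportive"))
  rng2 <- healthy_range(map2, bt2, hc$at)
  expect_equal(rng2$lo, rng2$hi, tolerance = 1e-10)
})

test_that("similarity scores implement the inclusive-bound weighted decay", {
  ranges <- data.frame(feature_id = c("f1", "f2", "f3"),
                       weight = c(2, 1, 1),
                       lo = c(0.4, 0.2, 0.5), hi = c(0.6, 0.4, 0.7),
                       ref_min = 0, ref_max = 1)
  inside <- c(f1 = 0.5, f2 = 0.3, f3 = 0.6)
  s1 <- similarity_score(inside, ranges)
  expect_equal(s1$weighted_score, 1)
  expect_equal(s1$n_in_range, 3L)
  # a value exactly on a bound counts as inside
  on_bound <- c(f1 = 0.6, f2 = 0.2, f3 = 0.7)
  expect_equal(similarity_score(on_bound, ranges)$n_in_range, 3L)
  # one indicator far outside loses exactly its weight share
  far <- c(f1 = 0.5, f2 = 0.3, f3 = 0)   # f3 dist 0.5 >> r 0.2 -> s = 0
  s3 <- similarity_score(far, ranges)
  expect_equal(s3$weighted_score, (2 + 1) / 4)
  # linear decay over one range-width
  near <- c(f1 = 0.5, f2 = 0.3, f3 = 0.8)  # dist 0.1, r 0.2 -> s = 0.5
  expect_equal(similarity_score(near, ranges)$s[["f3"]], 0.5)
  # monotonicity: moving an indicator toward its range never lowers the score
  path <- seq(0, 0.5, by = 0.05)
  scores <- vapply(path, function(x) {
    similarity_score(c(f1 = 0.5, f2 = 0.3, f3 = x), ranges)$weighted_score
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("paired BT/AT score comparison handles degenerate differences", {
  sc <- data.frame(cell = "x", participant_id = sprintf("P%02d", 1:12),
                   bt_score = rep(0.5, 12), at_score = rep(0.5, 12),
                   bt_n_in = 1L, at_n_in = 1L)
  out <- compare_bt_at(sc)
  expect_equal(out$t, 0)
  expect_equal(out$p, 0.5)
  sc$at_score <- sc$bt_score + 0.2
  out2 <- compare_bt_at(sc)
  expect_lt(out2$p, 1e-4)
  expect_equal(out2$n_improved, 0L)
  # BH-adjusted values never fall below the raw p
  sc2 <- rbind(sc, transform(sc, cell = "y", at_score = bt_score + rnorm(12, 0, 0.1)))
  out3 <- compare_bt_at(sc2)
  expect_true(all(out3$q >= out3$p - 1e-12))
})

test_that("Huber regression recovers exact lines and resists gross outliers", {
  x <- seq(1, 5, length.out = 10)
  fit <- robust_regress(2 * x + 1, x)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  expect_lt(fit$p, 1e-6)
  expect_error(robust_regress(rnorm(10), rep(1, 10)), "variance")
  wins <- logical(25)
  for (s in 1:25) {
    set.seed(s)
    xs <- rnorm(20)
    ys <- 1.5 * xs + rnorm(20, 0, 0.5)
    lev <- which.max(abs(xs))       # gross outlier at the leverage point
    ys[lev] <- ys[lev] + 10 * 0.5
    hub <- robust_regress(ys, xs)$slope
    ols <- unname(stats::coef(stats::lm(ys ~ xs))[2])
    wins[s] <- abs(hub - 1.5) <= abs(ols - 1.5)
  }
  expect_gte(mean(wins), 0.95)
})

test_that("a planted shift toward the healthy centroid is detected BT vs AT", {
  detected <- logical(30)
  for (s in 1:30) {
    hc <- make_health_cohort(seed = 400 + s, shift_frac = 0.2)
    map <- suppressWarnings(fit_health_map(hc$bt, hc$lifestyle, "sportive"))
    rng <- healthy_range(map, hc$bt, hc$at)
    rows <- lapply(hc$pid, function(p) {
      sb <- similarity_score(hc$bt[p, rng$feature_id], rng)
      sa <- similarity_score(hc$at[p, rng$feature_id], rng)
      data.frame(cell = "x", participant_id = p,
                 bt_score = sb$weighted_score, at_score = sa$weighted_score,
                 bt_n_in = sb$n_in_range, at_n_in = sa$n_in_range)
    })
    tst <- compare_bt_at(do.call(rbind, rows))
    detected[s] <- !is.na(tst$p) && tst$p < 0.05
  }
  expect_gte(mean(detected), 0.9)
})
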