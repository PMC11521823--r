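test_that("participant change matrix matches effect sizes and pairing", {
  x <- make_paired_block(5, 6, planted = 1:2, eff = 1, seed = 1)
  ch <- participant_change_matrix(x$block, x$design, "buccal")
  expect_equal(dim(ch), c(6L, 5L))
  expect_equal(unname(colMeans(ch)),
               unname(effect_size(x$block, x$design, "buccal")))
  # identical BT/AT gives the zero matrix
  v <- x$block$values
  v[, 7:12] <- v[, 1:6]
  ch0 <- participant_change_matrix(omics_block(v), x$design, "buccal")
  expect_true(all(ch0 == 0))
})

test_that("affinity kernel is symmetric, order-equivariant and maximal for duplicates", {
  set.seed(2)
  ch <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("P", 1:8), NULL))
  ch[2, ] <- ch[1, ]  # exact duplicate participants
  A <- build_affinity(ch, K = 2)
  expect_true(isSymmetric(unclass(A)))
  expect_true(all(A >= 0))
  off <- A[1, -1]
  expect_equal(unname(which.max(off)), 1L)  # P2 is P1's most similar
  # permuting rows permutes the affinity consistently
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  Ap <- build_affinity(ch[perm, ], K = 2)
  expect_equal(unclass(Ap), unclass(A)[perm, perm], tolerance = 1e-12)
  expect_error(build_affinity(ch, K = 8), "K")
})

test_that("well-separated groups have higher within- than between-group affinity", {
  set.seed(3)
  ch <- matrix(rnorm(12 * 10, 0, 0.5), 12, 10) +
    matrix(rep(c(0, 6), each = 6), 12, 10)
  rownames(ch) <- paste0("P", 1:12)
  A <- build_affinity(ch)
  grp <- rep(1:2, each = 6)
  same <- outer(grp, grp, "==") & upper.tri(A)
  diff <- outer(grp, grp, "!=") & upper.tri(A)
  expect_gt(mean(A[same]), mean(A[diff]))
})

test_that("SNF output is symmetric, nonnegative, with median diagonal", {
  set.seed(4)
  mk <- function() {
    ch <- matrix(rnorm(9 * 5), 9, 5, dimnames = list(paste0("P", 1:9), NULL))
    build_affinity(ch)
  }
  fused <- snf_fuse(list(mk(), mk()), t = 10)
  expect_true(isSymmetric(unclass(fused)))
  expect_true(all(fused >= 0))
  # diagonal is set to one shared value inside the off-diagonal value range
  expect_equal(unname(diag(fused)), rep(unname(diag(fused))[1], 9))
  off <- unclass(fused)[row(fused) != col(fused)]
  expect_gte(diag(fused)[1], min(off))
  expect_lte(diag(fused)[1], max(off))
  # ids must match across views
  bad <- mk(); rownames(bad)[1] <- colnames(bad)[1] <- "QQ"
  expect_error(snf_fuse(list(mk(), bad)), "same participant ids")
})

test_that("fusing identical views preserves planted block structure", {
  set.seed(5)
  truecl <- rep(1:3, each = 4)
  ch <- matrix(rnorm(12 * 8, 0, 0.5), 12, 8) +
    matrix(rep(c(0, 4, 8), each = 4), 12, 8)
  rownames(ch) <- paste0("P", 1:12)
  A <- build_affinity(ch)
  fused <- snf_fuse(list(A, A))
  ari_single <- adjusted_rand_index(spectral_cluster(A, 3, seed = 1)$labels, truecl)
  ari_fused <- adjusted_rand_index(spectral_cluster(fused, 3, seed = 1)$labels, truecl)
  expect_gte(ari_fused, ari_single)
  expect_equal(ari_fused, 1)
})

test_that("complementary views fuse into the joint cluster structure", {
  ok <- logical(10)
  for (s in 1:10) {
    set.seed(s)
    truecl <- rep(1:3, each = 4)
    mkview <- function(informative) {
      ch <- matrix(rnorm(12 * 20, 0, 1), 12, 20)
      cent <- matrix(0, 3, 20)
      cent[informative, 1:10] <- matrix(rnorm(length(informative) * 10, 0, 2.5),
                                        length(informative))
      out <- ch + cent[truecl, ]
      rownames(out) <- paste0("P", 1:12)
      out
    }
    a1 <- build_affinity(mkview(c(1, 2)))
    a2 <- build_affinity(mkview(c(2, 3)))
    f <- snf_fuse(list(a1, a2))
    arif <- adjusted_rand_index(spectral_cluster(f, 3, seed = 1)$labels, truecl)
    ari1 <- adjusted_rand_index(spectral_cluster(a1, 3, seed = 1)$labels, truecl)
    ari2 <- adjusted_rand_index(spectral_cluster(a2, 3, seed = 1)$labels, truecl)
    ok[s] <- arif >= max(ari1, ari2)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("spectral clustering recovers planted partitions and validates k", {
  set.seed(6)
  ch <- matrix(rnorm(12 * 10, 0, 0.3), 12, 10) +
    matrix(rep(c(0, 5, 10), each = 4), 12, 10)
  rownames(ch) <- paste0("P", 1:12)
  A <- build_affinity(ch)
  sc <- spectral_cluster(A, k = "auto", seed = 1)
  expect_equal(sc$k, 3L)
  expect_equal(adjusted_rand_index(sc$labels, rep(1:3, each = 4)), 1)
  expect_error(spectral_cluster(A, k = 1), "k must be")
})

test_that("change-correlation network applies the signed absolute threshold", {
  set.seed(7)
  n <- 20
  base <- rnorm(n)
  ptm <- cbind(p_hi = base + rnorm(n, 0, 0.22),
               p_anti = -base,
               p_null = rnorm(n))
  prot <- cbind(q1 = base)
  rownames(ptm) <- rownames(prot) <- paste0("P", 1:n)
  r_hi <- stats::cor(ptm[, "p_hi"], prot[, "q1"])
  expect_gt(r_hi, 0.7)  # construction check
  edges <- change_correlation_network(ptm, prot, threshold = 0.7)
  expect_setequal(edges$from, c("p_hi", "p_anti"))
  expect_equal(edges$sign[edges$from == "p_anti"], "-")
  expect_equal(edges$r[edges$from == "p_anti"], -1)
  # r just under the threshold yields no edge
  edges99 <- change_correlation_network(ptm, prot, threshold = r_hi + 1e-6)
  expect_false("p_hi" %in% edges99$from)
  # scale invariance: multiplying a column by a positive constant changes nothing
  ptm2 <- ptm; ptm2[, 1] <- 7 * ptm2[, 1]
  edges2 <- change_correlation_network(ptm2, prot, threshold = 0.7)
  expect_equal(edges2[c("from", "to", "sign")], edges[c("from", "to", "sign")])
  # zero-variance columns are excluded with a warning
  ptm3 <- cbind(ptm, p_const = rep(1, n))
  expect_warning(change_correlation_network(ptm3, prot, 0.7), "zero-variance")
})

test_that("high-degree nodes are ranked by degree then id", {
  edges <- data.frame(from = c("a", "a", "a", "b", "c"),
                      to = paste0("q", 1:5),
                      r = 0.8, sign = "+")
  out <- high_degree_nodes(edges, min_degree = 1)
  expect_equal(out$feature_id, c("a", "b", "c"))
  expect_equal(out$degree, c(3L, 1L, 1L))
  expect_equal(nrow(high_degree_nodes(edges, min_degree = 3)), 1L)
  empty <- edges[0, ]
  expect_equal(nrow(high_degree_nodes(empty)), 0L)
})

test_that("cophenetic comparison matches a hand-worked average-linkage oracle", {
  # 4 points on a line: {0,1} merge at 1, {10,12} at 2, clusters at
  # mean(10,12,9,11) = 10.5
  a <- matrix(c(0, 1, 10, 12), 4, 1, dimnames = list(paste0("S", 1:4), NULL))
  ca <- stats::cophenetic(stats::hclust(stats::dist(a), "average"))
  expected <- c(1, 10.5, 10.5, 10.5, 10.5, 2)  # pairs (12,13,14,23,24,34)
  expect_equal(as.vector(ca), expected)
  expect_equal(cophenetic_compare(a, a), 1)
  # independent random matrices have low cophenetic correlation on average
  set.seed(8)
  vals <- replicate(50, {
    m1 <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(paste0("S", 1:20), NULL))
    m2 <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(paste0("S", 1:20), NULL))
    cophenetic_compare(m1, m2)
  })
  expect_lt(abs(mean(vals)), 0.3)
  expect_error(cophenetic_compare(a[1:2, , drop = FALSE], a[1:2, , drop = FALSE]),
               "3")
})
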