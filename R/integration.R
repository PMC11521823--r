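# Multi-omics integration: participant-level similarity network fusion with
# spectral clustering, cross-omics change-correlation networks, and
# dendrogram comparison via the cophenetic correlation.

#' Participant-by-feature change matrix
#'
#' Per paired participant, AT - BT per feature (log2 units for intensity
#' blocks, percentage points for relative-abundance blocks). Unpaired
#' participants are excluded.
#'
#' @param block an `omics_block`.
#' @param design a `paired_design`.
#' @param type sample type of the block.
#' @param features optional subset of feature ids (e.g. discovered markers).
#' @return Numeric matrix, participants x features.
#' @export
participant_change_matrix <- function(block, design, type, features = NULL) {
  pr <- design_pairs(design, type, block)
  v <- block$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    .assert(length(miss) == 0,
            paste("unknown feature(s):", paste(utils::head(miss, 5), collapse = ", ")))
    v <- v[features, , drop = FALSE]
  }
  ch <- t(v[, pr$at, drop = FALSE] - v[, pr$bt, drop = FALSE])
  rownames(ch) <- pr$participant_id
  ch
}

#' Participant affinity matrix (scaled exponential kernel)
#'
#' The similarity-network-fusion kernel: squared Euclidean distances with a
#' local bandwidth that averages each participant's K-nearest-neighbour
#' distances, `W_ij = exp(-d2_ij / (2 mu eps_ij))` with
#' `eps_ij = (eps_i + eps_j + d2_ij) / 3`.
#'
#' @param changes participants-by-features matrix (rows are compared).
#' @param K neighbour count (default `max(2, floor(n/3))`), must be `< n`.
#' @param mu kernel bandwidth factor (default 0.5).
#' @return Symmetric nonnegative affinity matrix with participant labels,
#'   class `affinity`.
#' @export
build_affinity <- function(changes, K = max(2, floor(nrow(changes) / 3)),
                           mu = 0.5) {
  n <- nrow(changes)
  .assert(n >= 3, "need at least 3 participants")
  .assert(K >= 1 && K < n, "K must satisfy 1 <= K < n")
  d2 <- as.matrix(stats::dist(changes))^2
  eps_i <- vapply(seq_len(n),
                  function(i) mean(sort(d2[i, -i])[seq_len(K)]), numeric(1))
  # guard fully duplicated rows (zero local bandwidth)
  eps_i[eps_i == 0] <- .Machine$double.eps
  EPS <- (outer(eps_i, eps_i, "+") + d2) / 3
  W <- exp(-d2 / (2 * mu * EPS))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(changes), rownames(changes))
  structure(W, class = c("affinity", "matrix"))
}

# full-kernel transition matrix: off-diagonal mass 1/2, diagonal 1/2
.snf_full_norm <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# sparse KNN-local kernel: rows renormalized over the K nearest neighbours
.snf_local <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- 0
    nn <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nn] <- w[nn] / sum(w[nn])
  }
  S
}

#' Fuse affinity matrices by similarity network fusion
#'
#' Cross-diffusion of the full and KNN-local transition matrices of each
#' view: at every iteration each view's matrix is updated with the average
#' of the other views, `P_v <- S_v %*% mean(P_-v) %*% t(S_v)`, then the
#' fused matrix is the average over views, symmetrized. The diagonal is
#' finally set to the median of the whole fused matrix for downstream
#' display and clustering.
#'
#' @param affinities list of >= 2 `affinity` matrices over the same
#'   participants in the same order.
#' @param K neighbour count for the local kernels.
#' @param t diffusion iterations (default 20).
#' @return Fused `affinity` matrix.
#' @export
snf_fuse <- function(affinities, K = max(2, floor(nrow(affinities[[1]]) / 3)),
                     t = 20) {
  .assert(is.list(affinities) && length(affinities) >= 2,
          "need at least 2 affinity matrices")
  ids <- rownames(affinities[[1]])
  for (a in affinities) {
    .assert(identical(rownames(a), ids) && identical(colnames(a), ids),
            "all affinities must share the same participant ids in order")
  }
  m <- length(affinities)
  P <- lapply(affinities, .snf_full_norm)
  S <- lapply(affinities, .snf_local, K = K)
  for (it in seq_len(t)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Pv <- S[[v]] %*% others %*% t(S[[v]])
      Pnew[[v]] <- .snf_full_norm((Pv + t(Pv)) / 2)
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  diag(fused) <- stats::median(fused)
  dimnames(fused) <- list(ids, ids)
  structure(fused, class = c("affinity", "matrix"))
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized-Laplacian spectral clustering (Ng-Jordan-Weiss): the leading
#' eigenvectors of `D^-1/2 W D^-1/2` are row-normalized and clustered by
#' k-means. When `k = "auto"` the number of clusters is chosen by the
#' largest eigengap of the normalized Laplacian in `[2, n/2]`.
#'
#' @param fused an `affinity` matrix (connected graph).
#' @param k integer >= 2, or `"auto"`.
#' @param seed seed for the k-means step.
#' @return list with `labels` (named integer vector), `k`, and `eigengap`
#'   diagnostics (Laplacian eigenvalues).
#' @export
spectral_cluster <- function(fused, k = "auto", seed = 1) {
  W <- unclass(fused)
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("disconnected affinity graph: returning connected components")
    labels <- stats::setNames(as.integer(comp$membership), rownames(W))
    return(list(labels = labels, k = comp$no, eigengap = NULL))
  }
  d <- rowSums(W)
  Dm <- 1 / sqrt(d)
  L <- diag(n) - (Dm * W) %*% diag(Dm)  # I - D^-1/2 W D^-1/2
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  vals <- rev(ev$values)            # ascending
  vecs <- ev$vectors[, rev(seq_len(n)), drop = FALSE]
  if (identical(k, "auto")) {
    kmax <- max(2L, floor(n / 2))
    gaps <- diff(vals)[seq(1, kmax)]  # gap after eigenvalue k
    k <- which.max(gaps[-1]) + 1L     # restrict to k >= 2
  }
  .assert(is.numeric(k) && k >= 2, "k must be >= 2")
  U <- vecs[, seq_len(k), drop = FALSE]
  nu <- sqrt(rowSums(U^2)); nu[nu == 0] <- 1
  U <- U / nu
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 25)
  list(labels = stats::setNames(km$cluster, rownames(W)), k = as.integer(k),
       eigengap = vals)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions up to renaming).
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "label vectors must match in length")
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab); si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Thresholded PTM-protein change-correlation network
#'
#' Pearson correlation over participants between every (PTM change, protein
#' change) pair; edges where `|r| >= threshold`, signed. Zero-variance
#' columns are excluded with a warning.
#'
#' @param ptm_changes,protein_changes participants-by-features change
#'   matrices sharing row (participant) names.
#' @param threshold absolute correlation threshold (default 0.7).
#' @return data.frame edge list (`from` PTM, `to` protein, `r`, `sign`)
#'   with a `threshold` attribute.
#' @export
change_correlation_network <- function(ptm_changes, protein_changes,
                                       threshold = 0.7) {
  common <- intersect(rownames(ptm_changes), rownames(protein_changes))
  .assert(length(common) >= 3, "matrices must share at least 3 participants")
  A <- ptm_changes[common, , drop = FALSE]
  B <- protein_changes[common, , drop = FALSE]
  drop_const <- function(M, lab) {
    s <- apply(M, 2, stats::sd)
    if (any(s == 0)) {
      warning(sprintf("excluding %d zero-variance %s column(s)", sum(s == 0), lab))
      M <- M[, s > 0, drop = FALSE]
    }
    M
  }
  A <- drop_const(A, "PTM"); B <- drop_const(B, "protein")
  R <- stats::cor(A, B)
  hit <- which(abs(R) >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = colnames(A)[hit[, 1]],
                      to = colnames(B)[hit[, 2]],
                      r = R[hit], sign = ifelse(R[hit] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "threshold") <- threshold
  edges
}

#' High-degree PTM nodes of a correlation network
#'
#' @param edges edge list from [change_correlation_network()].
#' @param min_degree minimum degree.
#' @return data.frame `feature_id`, `degree`, sorted by decreasing degree
#'   then id.
#' @export
high_degree_nodes <- function(edges, min_degree = 1) {
  if (nrow(edges) == 0) {
    return(data.frame(feature_id = character(0), degree = integer(0)))
  }
  deg <- table(edges$from)
  keep <- deg[deg >= min_degree]
  out <- data.frame(feature_id = names(keep), degree = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cophenetic correlation between two sample dendrograms
#'
#' Average-linkage hierarchical clustering of the samples of each matrix on
#' Euclidean distance; the correlation of the two cophenetic-distance
#' vectors measures how similarly the two omics cluster the samples.
#'
#' @param a,b samples-by-features matrices over the same samples (matched by
#'   row name when present).
#' @return Pearson correlation of the cophenetic distances.
#' @export
cophenetic_compare <- function(a, b) {
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    .assert(length(common) >= 3, "need at least 3 shared samples")
    a <- a[common, , drop = FALSE]
    b <- b[common, , drop = FALSE]
  }
  .assert(nrow(a) == nrow(b) && nrow(a) >= 3, "need the same >= 3 samples")
  ca <- stats::cophenetic(stats::hclust(stats::dist(a), method = "average"))
  cb <- stats::cophenetic(stats::hclust(stats::dist(b), method = "average"))
  stats::cor(as.vector(ca), as.vector(cb))
}
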