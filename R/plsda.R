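# Partial least squares discriminant analysis (NIPALS) with VIP scores.
#
# Features are autoscaled, the class is coded as a centered indicator
# matrix, and components are extracted by the iterative NIPALS algorithm
# with deflation. The model carries everything needed to project new
# samples without refitting (centering/scaling vectors and the rotation
# W (P'W)^-1), which the health-awareness maps rely on.

#' Fit a PLS-DA model
#'
#' @param x samples-by-features numeric matrix, or an `omics_block` (then
#'   transposed internally so samples are rows).
#' @param classes factor or character vector of per-sample class labels
#'   (at least two classes present).
#' @param n_components number of latent components (default 2), at most
#'   `min(n_features, n_samples - 1)`.
#' @return An object of class `plsda`: list with `means`, `scales`,
#'   `weights` (W, unit-norm columns), `loadings` (P), `y_loadings` (Q),
#'   `scores` (T), `rotation` (W (P'W)^-1), `ss_y` (response variance
#'   explained per component), `classes`, `class_levels`, `features`
#'   (features kept after the zero-variance exclusion), `excluded`.
#' @export
plsda_fit <- function(x, classes, n_components = 2) {
  if (inherits(x, "omics_block")) x <- t(x$values)
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  .assert(!anyNA(x), "PLS-DA requires complete data (impute first)")
  classes <- factor(classes)
  .assert(length(classes) == nrow(x), "one class label per sample required")
  .assert(nlevels(classes) >= 2, "both/all classes must be present")
  sds <- apply(x, 2, stats::sd)
  excluded <- colnames(x)[sds == 0]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d zero-variance feature(s)", length(excluded)))
    x <- x[, sds > 0, drop = FALSE]
  }
  n <- nrow(x); p <- ncol(x)
  a_max <- min(p, n - 1L)
  .assert(n_components >= 1, "n_components must be >= 1")
  if (n_components > a_max) n_components <- a_max
  mu <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  X <- scale(x, center = mu, scale = sc)
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  Tm <- matrix(0, n, n_components)
  ss_y <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (sum(u^2) < 1e-12) break
    t_old <- rep(Inf, n)
    for (it in seq_len(500)) {
      w <- crossprod(X, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t_ <- X %*% w
      q <- crossprod(Y, t_) / sum(t_^2)
      u <- Y %*% q / sum(q^2)
      if (sqrt(sum((t_ - t_old)^2)) < 1e-10 * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    if (sqrt(sum(t_^2)) < 1e-12) break
    p_ <- crossprod(X, t_) / sum(t_^2)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
    ss_y[a] <- sum(t_^2) * sum(q^2)
    X <- X - tcrossprod(t_, p_)
    Y <- Y - tcrossprod(t_, q)
    a_used <- a
  }
  .assert(a_used >= 1, "no PLS component could be extracted")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  ss_y <- ss_y[keep]
  R <- W %*% solve(crossprod(P, W))
  feats <- colnames(x) %||% paste0("f", seq_len(p))
  rownames(W) <- rownames(P) <- rownames(R) <- feats
  structure(list(means = stats::setNames(mu, feats),
                 scales = stats::setNames(sc, feats),
                 weights = W, loadings = P, y_loadings = Q, scores = Tm,
                 rotation = R, ss_y = ss_y, n_components = a_used,
                 classes = classes, class_levels = levels(classes),
                 features = feats, excluded = excluded),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d features, %d samples, %d component(s); classes: %s\n",
              length(x$features), nrow(x$scores), x$n_components,
              paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$rotation %*% t(object$y_loadings)

#' Project samples into a fitted PLS-DA variate space
#'
#' New profiles are transformed with the training centering/scaling and
#' rotation; no refitting. The projection is affine in the input.
#'
#' @param object a `plsda` model.
#' @param newdata samples-by-features matrix (or `omics_block`) containing
#'   every model feature; extra features are ignored.
#' @param type `"scores"` (variate coordinates) or `"class"` (nearest class
#'   centroid in score space).
#' @param ... unused.
#' @return Scores matrix (samples x components) or a factor of classes.
#' @export
predict.plsda <- function(object, newdata, type = c("scores", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "omics_block")) newdata <- t(newdata$values)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  miss <- setdiff(object$features, colnames(newdata))
  .assert(length(miss) == 0,
          paste("feature(s) missing from newdata:", paste(utils::head(miss, 5), collapse = ", ")))
  Xs <- scale(newdata[, object$features, drop = FALSE],
              center = object$means, scale = object$scales)
  scores <- Xs %*% object$rotation
  if (type == "scores") return(scores)
  cent <- apply(object$scores, 2, function(s) tapply(s, object$classes, mean))
  d2 <- apply(scores, 1, function(s) colSums((t(cent) - s)^2))
  factor(object$class_levels[apply(as.matrix(d2), 2, which.min)],
         levels = object$class_levels)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )` with `SS_a` the
#' response variance explained by component `a` and unit-norm weight
#' columns; `p` = number of (kept) features. Consequently
#' `sum_j VIP_j^2 = p` exactly.
#'
#' @param model a fitted `plsda`.
#' @return Named numeric vector of VIP scores over the model's features.
#' @export
vip_scores <- function(model) {
  .assert(inherits(model, "plsda"), "model must be a plsda fit")
  p <- nrow(model$weights)
  w2 <- model$weights^2
  num <- as.vector(w2 %*% model$ss_y)
  stats::setNames(sqrt(p * num / sum(model$ss_y)), model$features)
}
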