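#' One-hot class indicator matrix
#'
#' @param groups Factor or character vector of class labels (>= 2 classes,
#'   each non-empty).
#' @return An `n x G` 0/1 indicator matrix, one column per class; each row
#'   sums to 1 and column sums equal the class counts.
#' @export
one_hot <- function(groups) {
  y <- factor(groups)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) == 0L))
    stop("class with zero members: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "), call. = FALSE)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(names(groups), levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# keep the k largest-|a| entries, shrinking survivors by the (k+1)-th largest
# absolute value (soft threshold); ties broken by position order
.soft_threshold_keep <- function(a, k) {
  p <- length(a)
  if (k >= p) return(a)
  ord <- order(-abs(a), seq_len(p))
  lambda <- abs(a[ord[k + 1L]])
  out <- numeric(p)
  keep <- ord[seq_len(k)]
  out[keep] <- sign(a[keep]) * pmax(abs(a[keep]) - lambda, 0)
  out
}

#' Sparse Partial Least Squares Discriminant Analysis
#'
#' Fits sPLS-DA by NIPALS: the class labels are one-hot encoded into a dummy
#' matrix `Y`; per component the X-loading weight `a` is iterated as
#' `a = X' u`, soft-thresholded so that at most `keepX[h]` entries survive
#' (the threshold is the `(keepX[h]+1)`-th largest absolute entry, survivors
#' shrunk toward zero by it — the Lasso-style cardinality constraint),
#' renormalized to unit length; scores are `t = X a`, the Y-side weight comes
#' from `Y' t`, and both `X` and `Y` are deflated on `t` (regression
#' deflation). Columns of `X` (and `Y`) are centred and unit-variance scaled
#' internally. The sign convention fixes the largest-|loading| entry of each
#' component positive, so fits are deterministic.
#'
#' Explained variance of component `h` is `||t_h p_h'||_F^2 / ||X_0||_F^2`
#' with `p_h` the regression loading and `X_0` the centred/scaled input.
#'
#' @param x Numeric matrix, samples in rows, proteins in columns (complete;
#'   zero-variance columns must have been removed).
#' @param y Class labels, one per row of `x` (>= 2 classes).
#' @param ncomp Number of latent components `H`.
#' @param keepX Integer vector (length `H`, recycled if scalar): number of
#'   proteins retained per component; defaults to all (classical PLS-DA).
#' @param scale Unit-variance scale the columns of `x` (default `TRUE`).
#' @param tol,max_iter NIPALS convergence tolerance on the loading update and
#'   iteration cap.
#' @return An object of class `splsda` with components `loadings` (p x H
#'   sparse loading weights), `scores` (n x H), `x_loadings` (regression
#'   loadings used for deflation), `y_loadings` (H x G), centring/scaling
#'   parameters, `explained_variance`, `keepX`, `levels`, and the training
#'   labels.
#' @seealso [predict.splsda()], [tune_splsda()], [cv_splsda()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 30), 40, 30,
#'             dimnames = list(NULL, paste0("P", 1:30)))
#' grp <- rep(c("A", "B"), each = 20)
#' x[grp == "B", 1:3] <- x[grp == "B", 1:3] + 2
#' fit <- splsda(x, grp, ncomp = 2, keepX = c(5, 5))
#' fit
#' head(coef(fit))
splsda <- function(x, y, ncomp = 2L, keepX = ncol(x), scale = TRUE,
                   tol = 1e-9, max_iter = 5000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' must be finite and complete", call. = FALSE)
  y <- factor(y)
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)", call. = FALSE)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  n <- nrow(x); p <- ncol(x); G <- nlevels(y)
  if (n < G) stop("need at least as many samples as classes", call. = FALSE)
  ncomp <- as.integer(ncomp)
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX < 1L) || any(keepX > p))
    stop("keepX must lie in [1, ncol(x)]", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))

  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2L, stats::sd) else rep(1, p)
  if (any(scl < 1e-12))
    stop("zero-variance column(s): remove them before fitting", call. = FALSE)
  Xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  Y <- one_hot(y)
  y_ctr <- colMeans(Y)
  y_scl <- apply(Y, 2L, stats::sd)
  Ys <- sweep(sweep(Y, 2L, y_ctr), 2L, y_scl, "/")

  x0norm2 <- sum(Xs^2)
  Xd <- Xs; Yd <- Ys
  A <- matrix(0, p, ncomp, dimnames = list(colnames(x), paste0("comp", seq_len(ncomp))))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(x), colnames(A)))
  P <- matrix(0, p, ncomp, dimnames = dimnames(A))
  D <- matrix(0, ncomp, G, dimnames = list(colnames(A), levels(y)))
  ev <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    a_old <- rep(0, p)
    a_old2 <- rep(0, p)
    conv <- FALSE
    near <- function(v, w) sum((v - w)^2) < tol^2 || sum((v + w)^2) < tol^2
    for (it in seq_len(max_iter)) {
      a <- drop(crossprod(Xd, u))
      a <- .soft_threshold_keep(a, keepX[h])
      nrm <- sqrt(sum(a^2))
      if (nrm < 1e-300)
        stop("component ", h, ": loading collapsed to zero", call. = FALSE)
      a <- a / nrm
      tt <- drop(Xd %*% a)
      b <- drop(crossprod(Yd, tt))
      b <- b / sqrt(sum(b^2))
      u <- drop(Yd %*% b)
      # fixed point, or a period-2 limit cycle of the thresholded update
      # (two supports with near-equal objective, seen on signal-free data):
      # either way the iteration has stabilized
      if (near(a, a_old) || near(a, a_old2)) {
        conv <- TRUE
        break
      }
      a_old2 <- a_old
      a_old <- a
    }
    if (!conv)
      stop("NIPALS failed to converge for component ", h, call. = FALSE)
    imax <- which.max(abs(a))
    if (a[imax] < 0) { a <- -a; tt <- -tt }
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(Xd, tt)) / tt2
    d <- drop(crossprod(Yd, tt)) / tt2
    ev[h] <- tt2 * sum(pl^2) / x0norm2
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, d)
    A[, h] <- a; Tm[, h] <- tt; P[, h] <- pl; D[h, ] <- d
  }
  structure(list(loadings = A, scores = Tm, x_loadings = P, y_loadings = D,
                 center = ctr, scale = scl, y_center = y_ctr, y_scale = y_scl,
                 explained_variance = stats::setNames(ev, colnames(A)),
                 keepX = keepX, ncomp = ncomp, levels = levels(y), y = y,
                 scaled = scale, call = match.call()),
            class = "splsda")
}

#' @export
print.splsda <- function(x, ...) {
  cat(sprintf("sparse PLS-DA: %d component(s), %d classes (%s)\n",
              x$ncomp, length(x$levels), paste(x$levels, collapse = ", ")))
  cat("  keepX:", paste(x$keepX, collapse = ", "), "\n")
  cat("  explained variance (X):",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.splsda <- function(object, ...) {
  nnz <- colSums(object$loadings != 0)
  out <- data.frame(component = seq_len(object$ncomp),
                    keepX = object$keepX, n_selected = nnz,
                    explained_variance = object$explained_variance,
                    row.names = NULL)
  class(out) <- c("summary.splsda", "data.frame")
  out
}

#' @export
print.summary.splsda <- function(x, ...) {
  cat("sparse PLS-DA component summary\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Extract sparse loading weights
#'
#' @param object A fitted [splsda()] model.
#' @param comp Optional component index; default all.
#' @param ... Unused.
#' @return Matrix (or vector for a single component) of loading weights;
#'   zero entries are unselected proteins.
#' @export
coef.splsda <- function(object, comp = NULL, ...) {
  if (is.null(comp)) object$loadings else object$loadings[, comp]
}

#' Proteins selected by an sPLS-DA model
#'
#' @param object A fitted [splsda()] model.
#' @param comp Components to pool over (default all).
#' @return Character vector of proteins with a nonzero loading on any of the
#'   requested components.
#' @export
selected_proteins <- function(object, comp = seq_len(object$ncomp)) {
  stopifnot(inherits(object, "splsda"))
  rownames(object$loadings)[rowSums(abs(object$loadings[, comp, drop = FALSE])) > 0]
}

# project new data through the stored centring/scaling and the sequential
# deflation, reproducing training scores exactly on the training data
.splsda_scores <- function(object, xnew, ncomp = object$ncomp) {
  miss <- setdiff(rownames(object$loadings), colnames(xnew))
  if (length(miss))
    stop("proteins missing from new data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  xnew <- xnew[, rownames(object$loadings), drop = FALSE]
  if (!all(is.finite(xnew))) stop("new data must be complete", call. = FALSE)
  Xs <- sweep(sweep(xnew, 2L, object$center), 2L, object$scale, "/")
  Tm <- matrix(0, nrow(xnew), ncomp,
               dimnames = list(rownames(xnew), colnames(object$loadings)[seq_len(ncomp)]))
  for (h in seq_len(ncomp)) {
    tt <- drop(Xs %*% object$loadings[, h])
    Tm[, h] <- tt
    Xs <- Xs - tcrossprod(tt, object$x_loadings[, h])
  }
  Tm
}

#' Predict classes from an sPLS-DA model
#'
#' Projects new samples into the latent space and assigns classes by one of
#' three prediction distances: `max_dist` (largest back-transformed
#' dummy-regression prediction, the default), `centroid_dist` (nearest class
#' centroid of the training scores, Euclidean) or `mahalanobis_dist` (nearest
#' centroid under the pooled within-class covariance of the training scores).
#' The per-class dummy predictions are returned as decision scores for ROC
#' analysis regardless of the distance used for the class call.
#'
#' @param object A fitted [splsda()] model.
#' @param newdata Matrix of samples x proteins containing the model's
#'   proteins (complete).
#' @param distance Prediction distance (see above).
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A list of class `splsda_predict`: `class` (factor of predicted
#'   labels), `response` (n x G dummy predictions on the indicator scale),
#'   `scores` (n x ncomp latent scores), `distance`.
#' @export
predict.splsda <- function(object, newdata,
                           distance = c("max_dist", "centroid_dist",
                                        "mahalanobis_dist"),
                           ncomp = object$ncomp, ...) {
  distance <- match.arg(distance)
  newdata <- as.matrix(newdata)
  Tm <- .splsda_scores(object, newdata, ncomp)
  # back-transform dummy predictions to the 0/1 indicator scale
  resp <- Tm %*% object$y_loadings[seq_len(ncomp), , drop = FALSE]
  resp <- sweep(resp, 2L, object$y_scale, "*")
  resp <- sweep(resp, 2L, object$y_center, "+")
  cls <- switch(distance,
    max_dist = object$levels[max.col(resp, ties.method = "first")],
    centroid_dist = {
      cent <- .class_centroids(object, ncomp)
      object$levels[.nearest_centroid(Tm, cent)]
    },
    mahalanobis_dist = {
      cent <- .class_centroids(object, ncomp)
      W <- .pooled_within_cov(object, ncomp)
      object$levels[.nearest_centroid(Tm, cent, solve(W))]
    })
  structure(list(class = factor(cls, levels = object$levels),
                 response = resp, scores = Tm, distance = distance),
            class = "splsda_predict")
}

.class_centroids <- function(object, ncomp) {
  Tm <- object$scores[, seq_len(ncomp), drop = FALSE]
  do.call(rbind, lapply(object$levels, function(g)
    colMeans(Tm[object$y == g, , drop = FALSE])))
}

.pooled_within_cov <- function(object, ncomp) {
  Tm <- object$scores[, seq_len(ncomp), drop = FALSE]
  n <- nrow(Tm)
  G <- length(object$levels)
  S <- matrix(0, ncomp, ncomp)
  for (g in object$levels) {
    Tg <- Tm[object$y == g, , drop = FALSE]
    if (nrow(Tg) > 1L)
      S <- S + crossprod(sweep(Tg, 2L, colMeans(Tg)))
  }
  S / max(n - G, 1L)
}

.nearest_centroid <- function(Tm, centroids, metric = NULL) {
  G <- nrow(centroids)
  d <- sapply(seq_len(G), function(g) {
    dif <- sweep(Tm, 2L, centroids[g, ])
    if (is.null(metric)) rowSums(dif^2) else rowSums((dif %*% metric) * dif)
  })
  d <- matrix(d, nrow = nrow(Tm))
  max.col(-d, ties.method = "first")
}

#' @export
print.splsda_predict <- function(x, ...) {
  cat(sprintf("splsda_predict (%s): %d sample(s)\n", x$distance,
              length(x$class)))
  print(table(predicted = x$class))
  invisible(x)
}

#' Project samples into the latent space of a fitted model
#'
#' @param object A fitted [splsda()] model.
#' @param newdata Samples x proteins matrix; defaults to reproducing the
#'   training scores.
#' @param ncomp Number of components.
#' @return Scores matrix (n x ncomp).
#' @export
splsda_transform <- function(object, newdata = NULL, ncomp = object$ncomp) {
  stopifnot(inherits(object, "splsda"))
  if (is.null(newdata)) return(object$scores[, seq_len(ncomp), drop = FALSE])
  .splsda_scores(object, as.matrix(newdata), ncomp)
}

#' Plot sPLS-DA sample scores
#'
#' @param x A fitted [splsda()] model.
#' @param comps Two component indices to plot.
#' @param ... Passed to [graphics::plot()].
#' @return The score matrix used, invisibly.
#' @export
plot.splsda <- function(x, comps = c(1L, 2L), ...) {
  stopifnot(length(comps) == 2L, max(comps) <= x$ncomp)
  Tm <- x$scores[, comps, drop = FALSE]
  ev <- 100 * x$explained_variance[comps]
  cols <- as.integer(x$y)
  graphics::plot(Tm[, 1L], Tm[, 2L], col = cols, pch = 16,
                 xlab = sprintf("component %d (%.1f%% expl. var.)", comps[1L], ev[1L]),
                 ylab = sprintf("component %d (%.1f%% expl. var.)", comps[2L], ev[2L]),
                 ...)
  graphics::legend("topright", legend = x$levels, col = seq_along(x$levels),
                   pch = 16, bty = "n")
  invisible(Tm)
}
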