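#' Repeated stratified fold assignment
#'
#' Builds `repeats` independent stratified `folds`-fold partitions: within
#' each repeat the members of every class are shuffled and dealt to folds
#' cyclically, so every test fold contains at least one sample of each class
#' whose size is at least `folds`, and smaller classes are spread maximally.
#'
#' @param groups Class labels (names, if present, are used as sample ids;
#'   otherwise integer indices are returned).
#' @param folds Number of folds `M` (>= 2, <= n).
#' @param repeats Number of repeats.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A list of fold plans, each a list with `repeat_`, `fold`, `train`,
#'   `test` (vectors of sample ids or indices). Within a repeat the test sets
#'   partition the samples.
#' @export
stratified_folds <- function(groups, folds = 5L, repeats = 10L, seed = 1L) {
  y <- factor(groups)
  n <- length(y)
  if (folds < 2L || folds > n) stop("'folds' must be in [2, n]", call. = FALSE)
  ids <- if (!is.null(names(groups))) names(groups) else seq_len(n)
  .set_seed(seed)
  plans <- list()
  for (r in seq_len(repeats)) {
    assign <- integer(n)
    offset <- 0L
    for (g in levels(y)) {
      idx <- which(y == g)
      idx <- idx[sample.int(length(idx))]
      # rotate the fold sequence between classes so small classes do not
      # all pile into fold 1
      assign[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
    for (f in seq_len(folds)) {
      test <- ids[assign == f]
      plans[[length(plans) + 1L]] <-
        list(repeat_ = r, fold = f, train = ids[assign != f], test = test)
    }
  }
  plans
}

#' Balanced error rate from a confusion matrix
#'
#' `BER = mean over classes of (misclassified_g / n_g)`, the per-class
#' average misclassification rate; insensitive to class imbalance.
#'
#' @param confusion Square matrix, rows = true classes, columns = predicted,
#'   each true class with at least one sample.
#' @return The balanced error rate in `[0, 1]`.
#' @export
balanced_error_rate <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  ng <- rowSums(confusion)
  if (any(ng == 0))
    stop("class(es) with zero true samples: ",
         paste(rownames(confusion)[ng == 0], collapse = ", "), call. = FALSE)
  mean(1 - diag(confusion) / ng)
}

#' One-vs-rest AUROC from decision scores
#'
#' For each class `g`, the AUROC of its decision score separating class-`g`
#' samples from all others, computed by the rank (Mann-Whitney) formulation
#' with midranks for ties.
#'
#' @param scores Numeric matrix, samples x classes (column names = classes).
#' @param groups True class labels, one per row.
#' @return Named numeric vector of per-class AUROCs; `NA` when a class has
#'   no positives or no negatives.
#' @export
one_vs_rest_auroc <- function(scores, groups) {
  scores <- as.matrix(scores)
  y <- factor(groups)
  cls <- colnames(scores)
  if (is.null(cls)) stop("'scores' needs class column names", call. = FALSE)
  out <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (g in cls) {
    pos <- y == g
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(scores[, g])
    out[g] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Cross-validated performance of an sPLS-DA model
#'
#' Repeated stratified M-fold cross-validation: per fold the model is refit
#' on the training samples only (centring, scaling and the sparse support are
#' all recomputed from the fold's training data, so no test information
#' leaks), test samples are predicted, and within each repeat the pooled test
#' predictions give the overall error rate, the balanced error rate and
#' per-class one-vs-rest AUROCs from the dummy decision scores. Means and
#' SDs are taken across repeats. A fold whose training set loses a class is
#' skipped with a warning; a repeat in which some class is never trained is
#' dropped.
#'
#' @param x Complete samples x proteins matrix (preprocessed log2 data).
#' @param groups Class labels per sample.
#' @param ncomp,keepX Model size passed to [splsda()].
#' @param folds,repeats CV geometry (default 5-fold, 10 repeats).
#' @param distance Prediction distance, see [predict.splsda()].
#' @param seed Seed for the fold plan.
#' @param plans Optional precomputed [stratified_folds()] plan (overrides
#'   `folds`/`repeats`/`seed`).
#' @return An object of class `cv_splsda`: `error_rate`, `ber`, `auroc`
#'   (each with `mean` and `sd`; AUROC per class), and `per_repeat` raw
#'   values.
#' @export
cv_splsda <- function(x, groups, ncomp = 2L, keepX = ncol(x), folds = 5L,
                      repeats = 10L, distance = "max_dist", seed = 1L,
                      plans = NULL) {
  x <- as.matrix(x)
  y <- factor(groups)
  ids <- seq_len(nrow(x))
  names(ids) <- rownames(x)
  if (is.null(plans))
    plans <- stratified_folds(stats::setNames(as.character(y), ids),
                              folds = folds, repeats = repeats, seed = seed)
  reps <- unique(vapply(plans, `[[`, 0, "repeat_"))
  lv <- levels(y)
  per_rep <- list()
  for (r in reps) {
    rplans <- Filter(function(pl) pl$repeat_ == r, plans)
    pred <- factor(rep(NA_character_, nrow(x)), levels = lv)
    dscore <- matrix(NA_real_, nrow(x), length(lv),
                     dimnames = list(NULL, lv))
    trained_classes <- character(0)
    for (pl in rplans) {
      tr <- as.integer(pl$train); te <- as.integer(pl$test)
      if (length(unique(y[tr])) < length(lv)) {
        warning(sprintf("repeat %d fold %d: training set lost a class; fold skipped",
                        pl$repeat_, pl$fold), call. = FALSE)
        next
      }
      trained_classes <- lv
      fit <- splsda(x[tr, , drop = FALSE], y[tr], ncomp = ncomp, keepX = keepX)
      pr <- predict(fit, x[te, , drop = FALSE], distance = distance)
      pred[te] <- pr$class
      dscore[te, ] <- pr$response
    }
    if (length(trained_classes) < length(lv)) next  # repeat dropped
    ok <- !is.na(pred)
    conf <- table(factor(y[ok], levels = lv), factor(pred[ok], levels = lv))
    per_rep[[length(per_rep) + 1L]] <- list(
      repeat_ = r,
      error_rate = mean(pred[ok] != y[ok]),
      ber = balanced_error_rate(conf),
      auroc = one_vs_rest_auroc(dscore[ok, , drop = FALSE], y[ok]))
  }
  if (!length(per_rep)) stop("no repeat completed", call. = FALSE)
  err <- vapply(per_rep, `[[`, 0, "error_rate")
  ber <- vapply(per_rep, `[[`, 0, "ber")
  auc <- do.call(rbind, lapply(per_rep, `[[`, "auroc"))
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  structure(list(
    error_rate = c(mean = mean(err), sd = sd0(err)),
    ber = c(mean = mean(ber), sd = sd0(ber)),
    auroc = list(mean = colMeans(auc, na.rm = TRUE),
                 sd = if (nrow(auc) > 1L) apply(auc, 2L, stats::sd, na.rm = TRUE)
                      else stats::setNames(rep(0, ncol(auc)), colnames(auc))),
    per_repeat = per_rep, ncomp = ncomp, keepX = keepX,
    folds = folds, repeats = length(per_rep), distance = distance),
    class = "cv_splsda")
}

#' @export
print.cv_splsda <- function(x, ...) {
  cat(sprintf("cv_splsda: %d-fold x %d repeat(s), distance = %s\n",
              x$folds, x$repeats, x$distance))
  cat(sprintf("  error rate: %.3f +/- %.3f\n", x$error_rate["mean"],
              x$error_rate["sd"]))
  cat(sprintf("  BER:        %.3f +/- %.3f\n", x$ber["mean"], x$ber["sd"]))
  cat("  one-vs-rest AUROC:\n")
  for (g in names(x$auroc$mean))
    cat(sprintf("    %-10s %.3f +/- %.3f\n", g, x$auroc$mean[g], x$auroc$sd[g]))
  invisible(x)
}

#' Tune keepX and the number of components by cross-validated BER
#'
#' Sequential per-component tuning: the keepX of components `1..h-1` are
#' fixed at their chosen values while the grid is scanned for component `h`;
#' each candidate is scored by the mean cross-validated balanced error rate
#' of the `h`-component model over the same fold plan. The chosen selection
#' attains the minimal mean BER, with ties resolved toward the smallest
#' keepX and then the smallest number of components.
#'
#' @param x Complete samples x proteins matrix.
#' @param groups Class labels.
#' @param keepX_grid Integer vector of candidate keepX values.
#' @param ncomp_max Maximum number of components to tune.
#' @param folds,repeats,distance,seed As in [cv_splsda()]; the same fold plan
#'   is reused across the whole grid so candidates are compared on identical
#'   partitions.
#' @return An object of class `splsda_tune`: `grid` (data.frame `comp`,
#'   `keepX`, `ber_mean`, `ber_sd` -- the tuning-curve table, error against
#'   number of selected features per component count), `ncomp`, `keepX`
#'   (chosen), `best_ber`.
#' @export
tune_splsda <- function(x, groups, keepX_grid = c(5L, 10L, 20L, 50L),
                        ncomp_max = 2L, folds = 5L, repeats = 10L,
                        distance = "max_dist", seed = 1L) {
  x <- as.matrix(x)
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  if (!length(keepX_grid)) stop("empty keepX grid", call. = FALSE)
  if (any(keepX_grid > ncol(x)))
    stop("keepX grid exceeds the number of proteins", call. = FALSE)
  y <- factor(groups)
  plans <- stratified_folds(as.character(y), folds = folds, repeats = repeats,
                            seed = seed)
  chosen <- integer(0)
  grid_rows <- list()
  best_per_comp <- numeric(ncomp_max)
  for (h in seq_len(ncomp_max)) {
    bers <- matrix(NA_real_, length(keepX_grid), 2L)
    for (i in seq_along(keepX_grid)) {
      cv <- cv_splsda(x, y, ncomp = h, keepX = c(chosen, keepX_grid[i]),
                      distance = distance, plans = plans)
      bers[i, ] <- cv$ber
      grid_rows[[length(grid_rows) + 1L]] <-
        data.frame(comp = h, keepX = keepX_grid[i],
                   ber_mean = cv$ber["mean"], ber_sd = cv$ber["sd"])
    }
    best <- which(bers[, 1L] == min(bers[, 1L]))[1L]  # grid sorted: ties -> smallest keepX
    chosen <- c(chosen, keepX_grid[best])
    best_per_comp[h] <- bers[best, 1L]
  }
  ncomp <- which(best_per_comp == min(best_per_comp))[1L]  # ties -> fewest comps
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  structure(list(grid = grid, ncomp = ncomp, keepX = chosen[seq_len(ncomp)],
                 keepX_all = chosen, best_ber = best_per_comp[ncomp],
                 ber_per_comp = best_per_comp),
            class = "splsda_tune")
}

#' @export
print.splsda_tune <- function(x, ...) {
  cat("sPLS-DA tuning (balanced error rate)\n")
  cat(sprintf("  chosen: ncomp = %d, keepX = (%s), mean BER = %.3f\n",
              x$ncomp, paste(x$keepX, collapse = ", "), x$best_ber))
  invisible(x)
}

#' Plot the tuning curve (BER against number of selected features)
#'
#' @param x An object from [tune_splsda()].
#' @param ... Passed to [graphics::matplot()].
#' @return The grid table, invisibly.
#' @export
plot.splsda_tune <- function(x, ...) {
  g <- x$grid
  comps <- sort(unique(g$comp))
  kx <- sort(unique(g$keepX))
  m <- sapply(comps, function(h) g$ber_mean[g$comp == h][order(g$keepX[g$comp == h])])
  graphics::matplot(kx, m, type = "b", pch = 16, lty = 1,
                    xlab = "number of selected features",
                    ylab = "balanced error rate", ...)
  graphics::legend("topright", legend = paste("comp", comps),
                   col = seq_along(comps), lty = 1, pch = 16, bty = "n")
  invisible(g)
}
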