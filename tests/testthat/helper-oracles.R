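# Independent oracles, written as direct transcriptions of the defining
# formulas so they share no code path with the package implementation.

# Dense PLS-DA reference: per component the loading is the dominant left
# singular vector of X' Y (the NIPALS fixed point), computed by svd() rather
# than by iteration; X and Y deflated on the score (regression deflation).
ref_dense_plsda <- function(x, y, ncomp) {
  xs <- scale(x)
  ys <- scale(one_hot(y))
  p <- ncol(xs)
  n <- nrow(xs)
  loadings <- matrix(0, p, ncomp)
  scores <- matrix(0, n, ncomp)
  for (h in seq_len(ncomp)) {
    sv <- svd(crossprod(xs, ys), nu = 1L, nv = 0L)
    a <- sv$u[, 1L]
    if (a[which.max(abs(a))] < 0) a <- -a
    tt <- drop(xs %*% a)
    pl <- drop(crossprod(xs, tt)) / sum(tt^2)
    d <- drop(crossprod(ys, tt)) / sum(tt^2)
    xs <- xs - tcrossprod(tt, pl)
    ys <- ys - tcrossprod(tt, d)
    loadings[, h] <- a
    scores[, h] <- tt
  }
  list(loadings = loadings, scores = scores)
}

# Benjamini-Hochberg step-up, coded from the definition: sort ascending,
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
ref_bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exhaustive KNN imputation oracle: all pairwise distances enumerated, the
# same neighbour definition as documented (Euclidean over co-observed
# samples, normalized by co-observation count; neighbours must be observed
# in the target sample).
ref_knn_impute_cell <- function(v, target, j, k) {
  p <- nrow(v)
  d <- rep(Inf, p)
  for (q in seq_len(p)) {
    if (q == target) next
    co <- which(!is.na(v[target, ]) & !is.na(v[q, ]))
    if (!length(co)) next
    d[q] <- sqrt(sum((v[target, co] - v[q, co])^2) / length(co))
  }
  ord <- order(d, seq_len(p))
  ord <- ord[is.finite(d[ord]) & !is.na(v[ord, j])]
  if (!length(ord)) return(mean(v[target, ], na.rm = TRUE))
  mean(v[ord[seq_len(min(k, length(ord)))], j])
}

# O(N^2) enrichment running sum: the value at every position recomputed
# from scratch as the sum of all increments up to that position.
ref_es_bruteforce <- function(metric, hits, exponent) {
  N <- length(metric)
  nh <- sum(hits)
  wh <- sum(abs(metric[hits])^exponent)
  step <- function(i) {
    if (hits[i]) {
      if (wh > 0) abs(metric[i])^exponent / wh else 1 / nh
    } else -1 / (N - nh)
  }
  runs <- vapply(seq_len(N), function(i)
    sum(vapply(seq_len(i), step, numeric(1))), numeric(1))
  list(es = runs[which.max(abs(runs))], running_sum = runs)
}

# AUROC by exhaustive concordant-pair counting (ties count one half).
ref_auroc_pairs <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  conc <- 0
  for (i in pos) for (j in neg) {
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / (length(pos) * length(neg))
}

# AUROC as the trapezoidal integral of the empirical ROC curve
# (tie-free scores assumed).
ref_auroc_trapezoid <- function(score, positive) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(score[positive] >= s), numeric(1)))
  fpr <- c(0, vapply(thr, function(s) mean(score[!positive] >= s), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# small helpers used across test files --------------------------------------

# multi-group fixture with 10 planted proteins per non-reference group
make_cohort_matrix <- function(n_per = 10, p = 50, delta = 2, G = 3,
                               seed = 1) {
  set.seed(seed)
  n <- n_per * G
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("P%03d", 1:p)))
  g <- rep(LETTERS[1:G], each = n_per)
  planted <- character(0)
  if (delta > 0)
    for (k in 2:G) {
      cols <- (k - 2) * 10 + 1:10
      x[g == LETTERS[k], cols] <- x[g == LETTERS[k], cols] + delta
      planted <- c(planted, colnames(x)[cols])
    }
  list(x = x, g = g, planted = planted)
}

make_im <- function(v, scale = "log2") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("P%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  intensity_matrix(v, scale)
}

write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# mock differential table with just the columns the quadrant stage consumes
mock_diff_table <- function(protein, fc, q) {
  data.frame(protein = protein, log2_fc = fc, q_value = q,
             stringsAsFactors = FALSE)
}
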