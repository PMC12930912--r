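#' Contrast specification
#'
#' Describes which samples are compared: `two_group` (side `a` vs side `b`,
#' each one group), `one_vs_rest` (group `a` vs everything else, e.g. IBM vs
#' non-IBM), or `multi_group` (ANOVA over all groups; no fold change).
#'
#' @param type Contrast type.
#' @param a,b Group names; `b` is ignored for `one_vs_rest` and both for
#'   `multi_group`.
#' @param name Optional label; defaults to a readable composition.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(type = c("two_group", "one_vs_rest", "multi_group"),
                          a = NULL, b = NULL, name = NULL) {
  type <- match.arg(type)
  if (type == "two_group" && (is.null(a) || is.null(b)))
    stop("two_group contrast needs 'a' and 'b'", call. = FALSE)
  if (type == "one_vs_rest" && is.null(a))
    stop("one_vs_rest contrast needs 'a'", call. = FALSE)
  if (is.null(name))
    name <- switch(type,
                   two_group = paste(a, "vs", b),
                   one_vs_rest = paste(a, "vs rest"),
                   multi_group = "multi_group")
  structure(list(type = type, a = a, b = b, name = name),
            class = "contrast_spec")
}

# collapse groups to the two sides of a contrast; NA = sample not in contrast
.contrast_sides <- function(groups, contrast) {
  g <- as.character(groups)
  switch(contrast$type,
    two_group = ifelse(g == contrast$a, "A", ifelse(g == contrast$b, "B", NA)),
    one_vs_rest = ifelse(g == contrast$a, "A", "B"),
    multi_group = g)
}

#' Per-protein log2 fold change
#'
#' `FC = mean(log2 side A) - mean(log2 side B)` for a two-sided contrast.
#'
#' @param x Complete log2-scale `intensity_matrix` or proteins x samples
#'   matrix.
#' @param groups Group labels per sample.
#' @param contrast A [contrast_spec()] with two sides.
#' @return Named numeric vector of fold changes per protein.
#' @export
log2_fold_change <- function(x, groups, contrast) {
  v <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  side <- .contrast_sides(groups, contrast)
  if (contrast$type == "multi_group")
    stop("fold change needs a two-sided contrast", call. = FALSE)
  if (!any(side == "A", na.rm = TRUE) || !any(side == "B", na.rm = TRUE))
    stop("contrast side with no samples", call. = FALSE)
  rowMeans(v[, which(side == "A"), drop = FALSE]) -
    rowMeans(v[, which(side == "B"), drop = FALSE])
}

# vectorized one-way ANOVA over matrix rows: classical between/within
# mean-square F with (G-1, n-G) df
.row_anova <- function(v, y) {
  y <- factor(y)
  n <- ncol(v); G <- nlevels(y)
  stopifnot(G >= 2, all(table(y) >= 2))
  gm <- rowMeans(v)
  ssb <- rep(0, nrow(v))
  ssw <- rep(0, nrow(v))
  for (g in levels(y)) {
    idx <- which(y == g)
    mg <- rowMeans(v[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (mg - gm)^2
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - mg)^2)
  }
  f <- (ssb / (G - 1)) / (ssw / (n - G))
  p <- stats::pf(f, G - 1, n - G, lower.tail = FALSE)
  # degenerate rows: no variance anywhere -> no evidence, p = 1
  degen <- ssw < 1e-300 & ssb < 1e-300
  f[degen] <- 0
  p[degen] <- 1
  list(statistic = f, p = p, df1 = G - 1, df2 = n - G)
}

#' Per-protein one-way ANOVA
#'
#' Classical between/within mean-square F test applied to every protein row,
#' with `(G-1, n-G)` degrees of freedom. A row with zero between- and
#' within-group variance is reported with `p = 1` by convention.
#'
#' @param x Complete log2-scale `intensity_matrix` or proteins x samples
#'   matrix.
#' @param groups Group labels (>= 2 groups, each with >= 2 samples).
#' @return Data.frame `protein`, `statistic` (F), `p_value`.
#' @export
protein_anova <- function(x, groups) {
  v <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  if (anyNA(v)) stop("matrix must be complete (impute first)", call. = FALSE)
  res <- .row_anova(v, groups)
  data.frame(protein = rownames(v), statistic = res$statistic,
             p_value = res$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-protein two-group Student's t-test
#'
#' Pooled-variance Student t per protein for a two-sided contrast, with
#' optional Bonferroni (`p_adj = min(1, p * m)`) or Benjamini-Hochberg
#' adjustment across proteins.
#'
#' @param x Complete log2-scale `intensity_matrix` or matrix.
#' @param groups Group labels.
#' @param contrast A two-sided [contrast_spec()].
#' @param correction `"bonferroni"` or `"bh"`.
#' @return Data.frame `protein`, `statistic` (t), `p_value`, `p_adjusted`.
#' @export
protein_ttest <- function(x, groups, contrast,
                          correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  v <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  if (anyNA(v)) stop("matrix must be complete (impute first)", call. = FALSE)
  side <- .contrast_sides(groups, contrast)
  ia <- which(side == "A"); ib <- which(side == "B")
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2 || n2 < 2) stop("each side needs >= 2 samples", call. = FALSE)
  m1 <- rowMeans(v[, ia, drop = FALSE]); m2 <- rowMeans(v[, ib, drop = FALSE])
  ss1 <- rowSums((v[, ia, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, ib, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
  degen <- sp2 < 1e-300
  tt[degen & abs(m1 - m2) < 1e-300] <- 0
  p[degen & abs(m1 - m2) < 1e-300] <- 1
  padj <- adjust_fdr(p, method = if (correction == "bh") "bh" else "bonferroni")
  data.frame(protein = rownames(v), statistic = tt, p_value = p,
             p_adjusted = padj, row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' Step-up Benjamini-Hochberg q-values (default) or Bonferroni, via
#' [stats::p.adjust()]. `NA` p-values propagate as `NA` and are excluded
#' from the effective number of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted values in `[0, 1]`.
#' @export
adjust_fdr <- function(pvalues, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = if (method == "bh") "BH" else "bonferroni")
}

#' Differential protein table
#'
#' Per-protein group means, log2 fold change for the contrast, test
#' statistic, p, q, rank and significance flag at `q <= 0.05`. The test is
#' one-way ANOVA (default) or the pooled-variance Student t-test; both
#' routes are offered because reported analyses of this kind use either.
#' Proteins are ranked by ascending q, then descending |fold change|, then
#' identifier.
#'
#' @param x Complete log2-scale `intensity_matrix` or matrix.
#' @param groups Group labels per sample.
#' @param contrast A [contrast_spec()]; `multi_group` contrasts carry no
#'   fold change (`NA`).
#' @param test `"anova"` or `"ttest"` (t-test requires a two-sided contrast).
#' @param correction `"bh"` (q-values, default) or `"bonferroni"`.
#' @param q_threshold Significance threshold on the adjusted value.
#' @return A data.frame of class `differential_table`: `protein`, one
#'   `mean_<group>` column per group (log2), `log2_fc`, `statistic`,
#'   `p_value`, `q_value`, `rank`, `significant`; sorted by rank.
#' @export
differential_table <- function(x, groups, contrast = contrast_spec("multi_group"),
                               test = c("anova", "ttest"),
                               correction = c("bh", "bonferroni"),
                               q_threshold = 0.05) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  v <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  if (anyNA(v)) stop("matrix must be complete (impute first)", call. = FALSE)
  g <- as.character(groups)
  ug <- unique(g)
  means <- matrix(NA_real_, nrow(v), length(ug),
                  dimnames = list(NULL, paste0("mean_", ug)))
  for (i in seq_along(ug))
    means[, i] <- rowMeans(v[, g == ug[i], drop = FALSE])
  side <- .contrast_sides(groups, contrast)
  in_contrast <- !is.na(side)
  fc <- if (contrast$type == "multi_group") rep(NA_real_, nrow(v))
        else log2_fold_change(v, groups, contrast)
  if (test == "ttest") {
    if (contrast$type == "multi_group")
      stop("t-test requires a two-sided contrast", call. = FALSE)
    tst <- protein_ttest(v[, in_contrast, drop = FALSE], side[in_contrast],
                         contrast_spec("two_group", "A", "B"),
                         correction = if (correction == "bh") "bh" else "bonferroni")
    stat <- tst$statistic; p <- tst$p_value; q <- tst$p_adjusted
  } else {
    lab <- if (contrast$type == "multi_group") g[in_contrast] else side[in_contrast]
    res <- .row_anova(v[, in_contrast, drop = FALSE], lab)
    stat <- res$statistic; p <- res$p
    q <- adjust_fdr(p, method = correction)
  }
  out <- data.frame(protein = rownames(v), means, log2_fc = fc,
                    statistic = stat, p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- rank_proteins(out)
  out$significant <- out$q_value <= q_threshold
  attr(out, "contrast") <- contrast
  attr(out, "test") <- test
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Rank a differential table
#'
#' Primary key ascending q-value, secondary descending |log2 fold change|
#' (`NA` fold changes rank last within a q tie), tertiary protein id, so the
#' ordering is deterministic.
#'
#' @param table Data.frame with `protein`, `q_value` and `log2_fc` columns.
#' @return The table sorted, with a `rank` column.
#' @export
rank_proteins <- function(table) {
  afc <- abs(table$log2_fc)
  afc[is.na(afc)] <- -Inf
  ord <- order(table$q_value, -afc, table$protein)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Ranked protein list for enrichment analysis
#'
#' Builds the descending ranked list GSEA consumes. The default metric is
#' `sign(FC) * (-log10 p)`; `"log2fc"` uses the fold change directly. An
#' optional pre-filter restricts the list to proteins whose (adjusted or
#' raw) p-value is below a threshold. Zero p-values are clamped to the
#' smallest positive double. Ties are broken by protein id.
#'
#' @param table A [differential_table()].
#' @param metric `"signed_logp"` or `"log2fc"`.
#' @param filter Optional p threshold; `NULL` keeps all proteins.
#' @param filter_on `"q"` (adjusted, default) or `"p"` (raw) for the filter.
#' @return Data.frame of class `ranked_list`: `protein`, `metric`, sorted
#'   descending.
#' @export
ranked_list <- function(table, metric = c("signed_logp", "log2fc"),
                        filter = NULL, filter_on = c("q", "p")) {
  metric <- match.arg(metric)
  filter_on <- match.arg(filter_on)
  tb <- table
  if (!is.null(filter)) {
    col <- if (filter_on == "q") tb$q_value else tb$p_value
    tb <- tb[!is.na(col) & col < filter, , drop = FALSE]
  }
  p <- pmax(tb$p_value, .Machine$double.xmin)
  m <- switch(metric,
              signed_logp = sign(tb$log2_fc) * (-log10(p)),
              log2fc = tb$log2_fc)
  ord <- order(-m, tb$protein)
  out <- data.frame(protein = tb$protein[ord], metric = m[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Significance stars
#'
#' Star coding at the conventional thresholds: `p < 0.0001` `"****"`,
#' `< 0.001` `"***"`, `< 0.01` `"**"`, `< 0.05` `"*"`, otherwise `"ns"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 5e-2, "*", "ns")))))
}

#' Transcript-level validation ANOVA
#'
#' One-way ANOVA on log-scale normalized expression (log2(TMM + 1)) for a
#' list of genes of interest, without multiplicity correction, with star
#' coding of the raw p-values. Genes absent from the table are reported as
#' missing rather than erroring.
#'
#' @param expression Genes x samples matrix of log2(TMM + 1) values (or an
#'   `intensity_matrix`).
#' @param groups Group labels per sample.
#' @param genes Optional character vector of genes of interest; default all.
#' @return Data.frame `gene`, `statistic` (F), `p_value`, `stars`,
#'   `present`.
#' @export
transcript_anova <- function(expression, groups, genes = NULL) {
  v <- if (inherits(expression, "intensity_matrix")) expression$values
       else as.matrix(expression)
  if (is.null(genes)) genes <- rownames(v)
  present <- genes %in% rownames(v)
  out <- data.frame(gene = genes, statistic = NA_real_, p_value = NA_real_,
                    stars = NA_character_, present = present,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(present)) {
    res <- .row_anova(v[genes[present], , drop = FALSE], groups)
    out$statistic[present] <- res$statistic
    out$p_value[present] <- res$p
    out$stars[present] <- signif_stars(res$p)
  }
  out
}
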