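#' Dual-contrast fold-change quadrant classification
#'
#' Cross-tabulates two differential tables sharing a common reference (e.g.
#' disease A vs control on x, disease B vs control on y): proteins raised
#' beyond the fold-change threshold `tau` in both contrasts (and, by
#' default, significant in both) are `shared_up`; exceeding `tau` on one
#' axis with the other inside `[-tau, tau]` is axis-specific; opposite-sign
#' exceedances are `discordant`; everything else is `null`. The protein
#' universe is the intersection of the two tables.
#'
#' @param table_x,table_y [differential_table()]s with two-sided contrasts.
#' @param fc_threshold Fold-change threshold `tau` on the log2 scale
#'   (default 1, i.e. 2-fold).
#' @param sig_threshold q-value threshold for the significance flags.
#' @param require_significance Require both contrasts significant for
#'   `shared_*` calls (default `TRUE`).
#' @return Data.frame of class `quadrant_table`: `protein`, `fc_x`, `fc_y`,
#'   `sig_x`, `sig_y`, `quadrant`; attribute `n_universe` records the
#'   intersection size. The labels partition the universe.
#' @export
dual_contrast <- function(table_x, table_y, fc_threshold = 1,
                          sig_threshold = 0.05, require_significance = TRUE) {
  common <- intersect(table_x$protein, table_y$protein)
  if (!length(common)) stop("tables share no proteins", call. = FALSE)
  ix <- match(common, table_x$protein)
  iy <- match(common, table_y$protein)
  fx <- table_x$log2_fc[ix]; fy <- table_y$log2_fc[iy]
  sx <- table_x$q_value[ix] <= sig_threshold
  sy <- table_y$q_value[iy] <= sig_threshold
  tau <- fc_threshold
  shared_ok <- if (require_significance) sx & sy else TRUE
  quadrant <- rep("null", length(common))
  quadrant[fx > tau & fy > tau & shared_ok] <- "shared_up"
  quadrant[fx < -tau & fy < -tau & shared_ok] <- "shared_down"
  quadrant[fx > tau & abs(fy) <= tau] <- "x_specific_up"
  quadrant[fx < -tau & abs(fy) <= tau] <- "x_specific_down"
  quadrant[fy > tau & abs(fx) <= tau] <- "y_specific_up"
  quadrant[fy < -tau & abs(fx) <= tau] <- "y_specific_down"
  quadrant[(fx > tau & fy < -tau) | (fx < -tau & fy > tau)] <- "discordant"
  out <- data.frame(protein = common, fc_x = fx, fc_y = fy,
                    sig_x = sx, sig_y = sy, quadrant = quadrant,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_universe") <- length(common)
  attr(out, "fc_threshold") <- tau
  class(out) <- c("quadrant_table", "data.frame")
  out
}

#' Top proteins of a quadrant
#'
#' Ranks the members of a quadrant by combined fold-change magnitude
#' `sqrt(fc_x^2 + fc_y^2)`, ties broken by protein id.
#'
#' @param qtable A [dual_contrast()] table.
#' @param quadrant Quadrant label.
#' @param k Number of proteins (>= 1); an empty quadrant yields an empty
#'   vector, `k` beyond the quadrant size yields all members.
#' @return Character vector of protein ids.
#' @export
top_quadrant_proteins <- function(qtable, quadrant, k = 10L) {
  stopifnot(k >= 1)
  q <- qtable[qtable$quadrant == quadrant, , drop = FALSE]
  if (!nrow(q)) return(character(0))
  mag <- sqrt(q$fc_x^2 + q$fc_y^2)
  ord <- order(-mag, q$protein)
  q$protein[ord][seq_len(min(k, nrow(q)))]
}

#' Hierarchical clustering order for heatmap axes
#'
#' Agglomerative clustering (complete linkage, Euclidean distance by
#' default — the common clustered-image-map convention) of the rows or
#' columns of a matrix, via [stats::hclust()]. Merge heights of complete
#' linkage are non-decreasing, and the leaf order is a permutation of all
#' items.
#'
#' @param x Numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param linkage Linkage method for [stats::hclust()].
#' @param metric Distance for [stats::dist()].
#' @return A list: `order` (leaf order, integer), `labels`, `merge`,
#'   `height`, and the underlying `hclust` object.
#' @export
cluster_order <- function(x, axis = c("rows", "columns"),
                          linkage = "complete", metric = "euclidean") {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(x) else x
  if (nrow(m) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  d <- stats::dist(m, method = metric)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  hc <- stats::hclust(d, method = linkage)
  list(order = hc$order, labels = hc$labels, merge = hc$merge,
       height = hc$height, hclust = hc)
}

#' Scaled group-mean heatmap table
#'
#' Per-protein group means (log2) z-scored across groups per protein row,
#' with row and column orderings from hierarchical clustering. A protein
#' with identical group means (SD 0) is emitted as an all-zero row and
#' flagged rather than erroring.
#'
#' @param x Complete log2-scale `intensity_matrix` or proteins x samples
#'   matrix.
#' @param groups Group labels per sample (>= 2 groups).
#' @param linkage,metric Clustering parameters, see [cluster_order()].
#' @return A list of class `heatmap_table`: `values` (proteins x groups
#'   scaled means), `row_order`, `col_order`, `row_tree`, `col_tree`
#'   (`NULL` with fewer than 3 groups), `flat_rows` (proteins with SD 0).
#' @export
scaled_group_heatmap <- function(x, groups, linkage = "complete",
                                 metric = "euclidean") {
  v <- if (inherits(x, "intensity_matrix")) x$values else as.matrix(x)
  g <- as.character(groups)
  ug <- unique(g)
  if (length(ug) < 2L) stop("need at least 2 groups to scale", call. = FALSE)
  means <- matrix(NA_real_, nrow(v), length(ug),
                  dimnames = list(rownames(v), ug))
  for (i in seq_along(ug))
    means[, i] <- rowMeans(v[, g == ug[i], drop = FALSE])
  mu <- rowMeans(means)
  sdv <- apply(means, 1L, stats::sd)
  flat <- sdv < 1e-12
  scaled <- (means - mu) / ifelse(flat, 1, sdv)
  scaled[flat, ] <- 0
  row_order <- if (nrow(scaled) >= 2L)
    cluster_order(scaled, "rows", linkage, metric) else NULL
  col_order <- if (ncol(scaled) >= 3L)
    cluster_order(scaled, "columns", linkage, metric) else NULL
  structure(list(values = scaled,
                 row_order = if (is.null(row_order)) seq_len(nrow(scaled))
                             else row_order$order,
                 col_order = if (is.null(col_order)) seq_len(ncol(scaled))
                             else col_order$order,
                 row_tree = row_order, col_tree = col_order,
                 flat_rows = rownames(scaled)[flat]),
            class = "heatmap_table")
}

#' @export
print.heatmap_table <- function(x, ...) {
  cat(sprintf("heatmap_table: %d proteins x %d groups (row-scaled means)\n",
              nrow(x$values), ncol(x$values)))
  if (length(x$flat_rows))
    cat("  flat (zero-SD) rows:", length(x$flat_rows), "\n")
  invisible(x)
}
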