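#' Preprocessing configuration
#'
#' Parameters of the missingness-stratified two-step imputation. Proteins
#' missing in more than `drop_threshold` of samples are removed; survivors
#' with missingness strictly below `low_threshold` are KNN-imputed; the rest
#' (moderate stratum, up to and including `drop_threshold`) are imputed by
#' downshifted normal sampling, the convention for left-censored label-free
#' MS data. The downshift draws for a sample with observed log2 mean `mu_j`
#' and SD `sigma_j` come from `Normal(mu_j - shift * sigma_j,
#' (width * sigma_j)^2)`; `shift = 1.8` and `width = 0.3` are the
#' conventional per-sample defaults of that approach.
#'
#' @param drop_threshold Remove proteins with missing fraction strictly above
#'   this (default 0.70; a fraction of exactly 0.70 is retained).
#' @param low_threshold Low/moderate boundary (default 0.20): `0 < f <
#'   low_threshold` routes to KNN, `low_threshold <= f <= drop_threshold`
#'   to downshift imputation.
#' @param k Number of nearest neighbour proteins for KNN imputation.
#' @param width,shift Downshift width `w` and shift `d`, in units of the
#'   per-sample SD of observed log2 values.
#' @param seed Integer seed for the downshift draws.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(drop_threshold = 0.70, low_threshold = 0.20,
                              k = 10L, width = 0.3, shift = 1.8, seed = 1L) {
  stopifnot(low_threshold > 0, low_threshold < drop_threshold,
            drop_threshold <= 1, k >= 1, width >= 0, shift >= 0)
  structure(list(drop_threshold = drop_threshold,
                 low_threshold = low_threshold, k = as.integer(k),
                 width = width, shift = shift, seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Profile per-protein missingness
#'
#' Computes per-protein missing fractions over the samples of the analysis
#' cohort and assigns each protein a stratum: `drop` (f > drop_threshold),
#' `low` (0 < f < low_threshold), `moderate` (low_threshold <= f <=
#' drop_threshold) or `complete` (f = 0).
#'
#' @param x An `intensity_matrix`.
#' @param config A [preprocess_config()].
#' @return A data.frame `protein`, `missing_fraction`, `stratum`.
#' @export
profile_missingness <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "intensity_matrix"), ncol(x$values) > 0)
  f <- rowMeans(is.na(x$values))
  stratum <- ifelse(f > config$drop_threshold, "drop",
             ifelse(f == 0, "complete",
             ifelse(f < config$low_threshold, "low", "moderate")))
  data.frame(protein = proteins(x), missing_fraction = f, stratum = stratum,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove proteins above the missingness threshold
#'
#' @param x An `intensity_matrix`.
#' @param profile Output of [profile_missingness()] for `x`.
#' @return The matrix with `drop`-stratum proteins removed, order preserved.
#' @export
filter_high_missingness <- function(x, profile) {
  stopifnot(identical(profile$protein, proteins(x)))
  keep <- profile$stratum != "drop"
  intensity_matrix(x$values[keep, , drop = FALSE], x$scale)
}

# neighbour distances: Euclidean over co-observed samples, normalized by the
# number of co-observed samples (so sparsity does not deflate distances)
.knn_distances <- function(v, target) {
  p <- nrow(v)
  d <- rep(Inf, p)
  xt <- v[target, ]
  obs_t <- !is.na(xt)
  for (q in seq_len(p)) {
    if (q == target) next
    co <- obs_t & !is.na(v[q, ])
    nco <- sum(co)
    if (nco == 0L) next
    d[q] <- sqrt(sum((xt[co] - v[q, co])^2) / nco)
  }
  d
}

#' K-nearest-neighbour imputation for low-missingness proteins
#'
#' For each `low`-stratum protein, neighbour proteins are ranked by Euclidean
#' distance over co-observed samples (normalized by the co-observation
#' count); each missing cell is replaced by the mean value, in that sample,
#' of the `k` nearest neighbours observed in that sample. A protein with no
#' co-observed partner (or no observed neighbour in the sample) falls back to
#' its own observed mean; fallbacks are recorded in the `"fallback_proteins"`
#' attribute. Other strata are untouched.
#'
#' @param x Log2-scale `intensity_matrix`.
#' @param profile Output of [profile_missingness()] for `x`.
#' @param config A [preprocess_config()] supplying `k`.
#' @return The matrix with low-stratum cells imputed.
#' @export
knn_impute <- function(x, profile, config = preprocess_config()) {
  stopifnot(inherits(x, "intensity_matrix"), x$scale == "log2",
            identical(profile$protein, proteins(x)))
  v <- x$values
  out <- v
  targets <- which(profile$stratum == "low")
  fallback <- character(0)
  for (t in targets) {
    miss <- which(is.na(v[t, ]))
    if (!length(miss)) next
    d <- .knn_distances(v, t)
    ord <- order(d, seq_along(d))   # ties broken by protein order
    ord <- ord[is.finite(d[ord])]
    used_fallback <- FALSE
    for (j in miss) {
      cand <- ord[!is.na(v[ord, j])]
      if (length(cand)) {
        nb <- cand[seq_len(min(config$k, length(cand)))]
        out[t, j] <- mean(v[nb, j])
      } else {
        out[t, j] <- mean(v[t, ], na.rm = TRUE)
        used_fallback <- TRUE
      }
    }
    if (used_fallback) fallback <- c(fallback, proteins(x)[t])
  }
  res <- intensity_matrix(out, "log2")
  attr(res, "fallback_proteins") <- fallback
  res
}

#' Downshifted-normal imputation for moderate-missingness proteins
#'
#' Emulates values beneath the detection limit: for each sample `j` the mean
#' `mu_j` and SD `sigma_j` of its observed log2 values are computed, and
#' every missing cell of a `moderate`-stratum protein in that sample is drawn
#' from `Normal(mu_j - shift * sigma_j, (width * sigma_j)^2)`. Draws are
#' consumed column by column (samples in order, proteins in row order within
#' a column) after seeding, so results are reproducible.
#'
#' @param x Log2-scale `intensity_matrix`.
#' @param profile Output of [profile_missingness()] for `x`.
#' @param config A [preprocess_config()] supplying `width` and `shift`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return The matrix with moderate-stratum cells imputed; per-sample
#'   `(mu_j, sigma_j)` in the `"column_params"` attribute.
#' @export
downshift_impute <- function(x, profile, config = preprocess_config(),
                             seed = config$seed) {
  stopifnot(inherits(x, "intensity_matrix"), x$scale == "log2",
            identical(profile$protein, proteins(x)))
  v <- x$values
  moderate <- profile$stratum == "moderate"
  n_obs <- colSums(!is.na(v))
  if (any(moderate) && any(n_obs < 3L))
    stop("sample(s) with fewer than 3 observed values: ",
         paste(colnames(v)[n_obs < 3L], collapse = ", "), call. = FALSE)
  mu <- colMeans(v, na.rm = TRUE)
  sg <- apply(v, 2L, stats::sd, na.rm = TRUE)
  out <- v
  .set_seed(seed)
  for (j in seq_len(ncol(v))) {
    miss <- which(moderate & is.na(v[, j]))
    if (!length(miss)) next
    out[miss, j] <- stats::rnorm(length(miss),
                                 mu[j] - config$shift * sg[j],
                                 config$width * sg[j])
  }
  res <- intensity_matrix(out, "log2")
  attr(res, "column_params") <- data.frame(sample = colnames(v), mu = mu,
                                           sigma = sg, row.names = NULL)
  res
}

#' Remove zero-variance proteins
#'
#' Drops proteins whose values are identical across samples (SD below 1e-12),
#' which carry no discriminative information and break unit-variance scaling.
#'
#' @param x An `intensity_matrix` (typically fully imputed).
#' @return The filtered matrix.
#' @export
drop_zero_variance <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  sds <- apply(x$values, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 1e-12
  intensity_matrix(x$values[keep, , drop = FALSE], x$scale)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: log2 transform (raw input only) -> missingness profile
#' -> removal above the drop threshold -> KNN imputation (low stratum) ->
#' downshift imputation (moderate stratum) -> zero-variance filter. The
#' output contains no missing cells. Missing fractions are computed within
#' the cohort being modelled, so cohorts analysed separately are profiled
#' separately.
#'
#' @param x An `intensity_matrix` (raw or log2 scale).
#' @param config A [preprocess_config()].
#' @return A list of class `preprocess_result`: `matrix` (complete,
#'   log2-scale `intensity_matrix`) and `report` (counts per stage, strata,
#'   per-sample downshift parameters, seed).
#' @export
preprocess <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "intensity_matrix"))
  n_in <- nrow(x$values)
  if (x$scale == "raw") x <- log2_transform(x)
  prof <- profile_missingness(x, config)
  x <- filter_high_missingness(x, prof)
  prof2 <- profile_missingness(x, config)
  n_low_cells <- sum(is.na(x$values[prof2$stratum == "low", , drop = FALSE]))
  x <- knn_impute(x, prof2, config)
  fallback <- attr(x, "fallback_proteins")
  n_mod_cells <- sum(is.na(x$values[prof2$stratum == "moderate", , drop = FALSE]))
  if (n_mod_cells > 0) {
    x <- downshift_impute(x, prof2, config)
    col_params <- attr(x, "column_params")
  } else col_params <- NULL
  n_before_zv <- nrow(x$values)
  x <- drop_zero_variance(x)
  report <- list(
    n_proteins_in = n_in,
    n_dropped_missingness = sum(prof$stratum == "drop"),
    n_dropped_zero_variance = n_before_zv - nrow(x$values),
    n_retained = nrow(x$values),
    strata_counts = c(complete = sum(prof2$stratum == "complete"),
                      low = sum(prof2$stratum == "low"),
                      moderate = sum(prof2$stratum == "moderate")),
    n_cells_imputed_knn = n_low_cells,
    n_cells_imputed_downshift = n_mod_cells,
    knn_fallback_proteins = fallback,
    downshift_column_params = col_params,
    config = config, seed = config$seed)
  structure(list(matrix = x, report = report), class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  r <- x$report
  cat("preprocess_result\n")
  cat(sprintf("  proteins: %d in, %d dropped (missingness), %d dropped (zero variance), %d retained\n",
              r$n_proteins_in, r$n_dropped_missingness,
              r$n_dropped_zero_variance, r$n_retained))
  cat(sprintf("  imputed cells: %d KNN (low stratum), %d downshift (moderate stratum)\n",
              r$n_cells_imputed_knn, r$n_cells_imputed_downshift))
  invisible(x)
}
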