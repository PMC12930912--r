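#' Weighted running-sum enrichment score
#'
#' The classical weighted Kolmogorov-Smirnov statistic over a ranked list:
#' walking down the list, a hit (member of the set) increments the running
#' sum by `|metric|^exponent / sum of |metric|^exponent over hits` and a miss
#' decrements it by `1 / (N - n_hits)`. The enrichment score is the value of
#' the running sum at its largest absolute excursion. The sum starts and
#' ends at zero by construction.
#'
#' @param ranked A [ranked_list()] (or data.frame with `protein` and
#'   `metric`, metric descending).
#' @param set Character vector of member identifiers.
#' @param exponent Metric weight exponent (>= 0; `0` gives the unweighted
#'   KS statistic, default `1`).
#' @return A list: `es`, `running_sum` (length N), `peak` (index of the
#'   extreme excursion), `hits` (logical length N).
#' @export
enrichment_score <- function(ranked, set, exponent = 1) {
  stopifnot(exponent >= 0)
  ids <- ranked$protein
  metric <- ranked$metric
  N <- length(ids)
  hits <- ids %in% set
  nh <- sum(hits)
  if (nh == 0L) stop("set does not intersect the ranked list", call. = FALSE)
  w <- abs(metric)^exponent
  wh <- sum(w[hits])
  inc <- numeric(N)
  if (wh > 0) inc[hits] <- w[hits] / wh else inc[hits] <- 1 / nh
  if (nh < N) inc[!hits] <- -1 / (N - nh)
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  list(es = run[peak], running_sum = run, peak = peak, hits = hits)
}

# null ES for a random same-size set: positions sampled uniformly
.null_es <- function(metric, N, nh, exponent) {
  idx <- sample.int(N, nh)
  hits <- logical(N)
  hits[idx] <- TRUE
  w <- abs(metric)^exponent
  wh <- sum(w[hits])
  inc <- numeric(N)
  if (wh > 0) inc[hits] <- w[hits] / wh else inc[hits] <- 1 / nh
  if (nh < N) inc[!hits] <- -1 / (N - nh)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Gene Set Enrichment Analysis on a ranked protein list
#'
#' Preranked GSEA with a gene-permutation null: for each set the observed
#' enrichment score is compared against `nperm` scores of random same-size
#' sets drawn from the list universe. The permutation p-value is the
#' sign-matched tail frequency with +1 smoothing; the normalized enrichment
#' score is `ES / mean(|null ES of matching sign|)`; p-values are BH-adjusted
#' across the retained sets. The leading edge contains the hits at or before
#' the running-sum peak (after the peak for negative ES).
#'
#' @param ranked A [ranked_list()].
#' @param collection A `gene_set_collection` (see [read_gmt()]) or named list
#'   of character vectors.
#' @param nperm Number of permutations (>= 100; default 1000).
#' @param min_size,max_size Set-size bounds after intersection with the list;
#'   sets outside are excluded and counted.
#' @param exponent Metric weight exponent, see [enrichment_score()].
#' @param seed Integer RNG seed; results are deterministic given it.
#' @return A data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p_value`, `p_adjusted`, `direction` (`activated`/`suppressed`),
#'   `leading_edge` (semicolon-joined), sorted by p then |NES|; excluded and
#'   non-intersecting set counts in attributes `n_excluded_size`,
#'   `n_skipped_empty`.
#' @export
gsea <- function(ranked, collection, nperm = 1000L, min_size = 10L,
                 max_size = 500L, exponent = 1, seed = 1L) {
  if (nperm < 100L) stop("nperm must be >= 100", call. = FALSE)
  ids <- ranked$protein
  N <- length(ids)
  .set_seed(seed)
  rows <- list()
  n_excl <- 0L
  n_empty <- 0L
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], ids)
    sz <- length(members)
    if (sz == 0L) { n_empty <- n_empty + 1L; next }
    if (sz < min_size || sz > max_size) { n_excl <- n_excl + 1L; next }
    obs <- enrichment_score(ranked, members, exponent)
    null <- vapply(seq_len(nperm), function(b)
      .null_es(ranked$metric, N, sz, exponent), numeric(1))
    same <- null[sign(null) == sign(obs$es)]
    if (length(same)) {
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      nes <- obs$es / mean(abs(same))
    } else {
      p <- 1 / (1 + nperm)
      nes <- NA_real_
    }
    le <- if (obs$es >= 0) which(obs$hits & seq_len(N) <= obs$peak)
          else which(obs$hits & seq_len(N) >= obs$peak)
    rows[[nm]] <- data.frame(
      set = nm, size = sz, es = obs$es, nes = nes, p_value = p,
      direction = if (obs$es >= 0) "activated" else "suppressed",
      leading_edge = paste(ids[le], collapse = ";"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), size = integer(0), es = numeric(0),
               nes = numeric(0), p_value = numeric(0),
               direction = character(0), leading_edge = character(0),
               stringsAsFactors = FALSE)
  out$p_adjusted <- adjust_fdr(out$p_value, "bh")
  out <- out[order(out$p_value, -abs(out$nes), out$set), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("set", "size", "es", "nes", "p_value", "p_adjusted",
                 "direction", "leading_edge")]
  attr(out, "n_excluded_size") <- n_excl
  attr(out, "n_skipped_empty") <- n_empty
  attr(out, "nperm") <- as.integer(nperm)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
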