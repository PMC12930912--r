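# fixture: log2 matrix with a prescribed number of missing cells per row
mask_matrix <- function(n_missing_per_row, n_samples, seed = 1) {
  set.seed(seed)
  p <- length(n_missing_per_row)
  v <- matrix(rnorm(p * n_samples, 20, 2), p, n_samples)
  for (i in seq_len(p))
    if (n_missing_per_row[i] > 0)
      v[i, seq_len(n_missing_per_row[i])] <- NA
  make_im(v, "log2")
}

test_that("missingness strata follow the documented boundaries", {
  im <- mask_matrix(c(8, 7, 1, 0, 2, 3), 10)
  prof <- profile_missingness(im)
  expect_equal(prof$missing_fraction, c(.8, .7, .1, 0, .2, .3))
  expect_equal(prof$stratum,
               c("drop", "moderate", "low", "complete", "moderate", "moderate"))
})

test_that("high-missingness filter removes only the drop stratum, keeping order", {
  im <- mask_matrix(c(8, 9, 10, rep(0, 7)), 10)
  prof <- profile_missingness(im)
  out <- filter_high_missingness(im, prof)
  expect_equal(nrow(out$values), 7L)
  expect_equal(proteins(out), proteins(im)[-(1:3)])

  # complete matrix passes through untouched
  full <- mask_matrix(rep(0, 5), 10)
  expect_identical(filter_high_missingness(full, profile_missingness(full))$values,
                   full$values)

  # exactly 70% missing is retained (removal is strictly > 0.70)
  im70 <- mask_matrix(c(70, 71), 100)
  kept <- filter_high_missingness(im70, profile_missingness(im70))
  expect_equal(proteins(kept), proteins(im70)[1])
})

test_that("KNN imputation matches simple hand-checkable cases", {
  cfg <- preprocess_config(low_threshold = 0.3, k = 1L)
  # target identical to a complete neighbour on observed cells
  v <- rbind(c(1, 2, 3, NA, 5, 6, 7, 8, 9, 10),
             c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             c(50, 60, 70, 80, 90, 100, 110, 120, 130, 140))
  im <- make_im(v, "log2")
  prof <- profile_missingness(im, cfg)
  expect_equal(prof$stratum[1], "low")
  out <- knn_impute(im, prof, cfg)
  expect_equal(out$values[1, 4], 4)

  # constant protein among constant neighbours stays at that constant
  vc <- rbind(c(5, 5, 5, 5, 5, 5, 5, 5, 5, NA),
              matrix(5, 3, 10))
  imc <- make_im(vc, "log2")
  outc <- knn_impute(imc, profile_missingness(imc, cfg), preprocess_config(low_threshold = 0.3, k = 2L))
  expect_equal(outc$values[1, 10], 5)
})

test_that("KNN imputation equals the exhaustive pairwise-distance oracle", {
  cfg <- preprocess_config(low_threshold = 0.3, k = 2L)
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rnorm(20, 20, 2), 5, 4)
    v[cbind(c(1, 3), c(2, 4))] <- NA  # one missing cell in two proteins
    im <- make_im(v, "log2")
    prof <- profile_missingness(im, cfg)
    out <- knn_impute(im, prof, cfg)
    for (t in which(prof$stratum == "low"))
      for (j in which(is.na(v[t, ])))
        expect_equal(out$values[t, j], ref_knn_impute_cell(v, t, j, 2L))
    # convexity: imputed value inside the range of that sample's values
    for (t in which(prof$stratum == "low"))
      for (j in which(is.na(v[t, ]))) {
        expect_gte(out$values[t, j], min(v[-t, j], na.rm = TRUE))
        expect_lte(out$values[t, j], max(v[-t, j], na.rm = TRUE))
      }
  }
})

test_that("downshift imputation draws from the per-sample downshifted normal", {
  # w = 0: every imputed cell is exactly mu_j - d * sigma_j
  set.seed(4)
  v <- matrix(rnorm(200, 20, 2), 20, 10)
  v[1:6, 1:4] <- NA   # 40% missing -> moderate stratum
  im <- make_im(v, "log2")
  cfg0 <- preprocess_config(width = 0, shift = 1.8)
  prof <- profile_missingness(im, cfg0)
  expect_true(all(prof$stratum[1:6] == "moderate"))
  out <- downshift_impute(im, prof, cfg0, seed = 1)
  for (j in 1:4) {
    mu <- mean(v[, j], na.rm = TRUE)
    sg <- sd(v[, j], na.rm = TRUE)
    expect_equal(unname(out$values[1:6, j]), rep(mu - 1.8 * sg, 6))
  }
  # observed cells bitwise untouched
  obs <- !is.na(v)
  expect_identical(out$values[obs], v[obs])
  # determinism
  out2 <- downshift_impute(im, prof, cfg0, seed = 1)
  expect_identical(out$values, out2$values)
})

test_that("downshift centre and spread match the configured parameters", {
  # d = 0, w = 1: imputed-cell mean approaches the observed column mean
  n_draw <- 10000L
  set.seed(8)
  v <- matrix(rnorm((n_draw + 200) * 2, 20, 2), n_draw + 200, 2)
  v[seq_len(n_draw), 1] <- NA   # ~98% missing in these rows: moderate w.r.t. 2 cols? no: f=0.5
  im <- make_im(v, "log2")
  cfg <- preprocess_config(width = 1, shift = 0)
  prof <- profile_missingness(im, cfg)
  expect_true(all(prof$stratum[seq_len(n_draw)] == "moderate"))
  out <- downshift_impute(im, prof, cfg, seed = 2)
  mu1 <- mean(v[, 1], na.rm = TRUE)
  sg1 <- sd(v[, 1], na.rm = TRUE)
  imputed <- out$values[seq_len(n_draw), 1]
  expect_lt(abs(mean(imputed) - mu1), 4 * sg1 / sqrt(n_draw))

  # d > 0 shifts the imputed mean below the observed mean
  cfgd <- preprocess_config(width = 0.3, shift = 1.8)
  outd <- downshift_impute(im, prof, cfgd, seed = 2)
  expect_lt(mean(outd$values[seq_len(n_draw), 1]), mu1)

  # a sample with fewer than 3 observed values cannot be parameterized
  tiny <- make_im(rbind(c(NA, 1), c(NA, 2), c(1, 3), c(NA, 4)), "log2")
  ptiny <- profile_missingness(tiny, cfg)
  expect_error(downshift_impute(tiny, ptiny, cfg), "fewer than 3")
})

test_that("zero-variance proteins are removed and others kept", {
  v <- rbind(rep(5, 6), c(1, 1, 1, 1, 1, 1.01), rnorm(6))
  im <- make_im(v, "log2")
  out <- drop_zero_variance(im)
  expect_equal(proteins(out), proteins(im)[2:3])
  # jittered random matrix: identity
  set.seed(2)
  rnd <- make_im(matrix(rnorm(40), 8, 5), "log2")
  expect_identical(drop_zero_variance(rnd)$values, rnd$values)
})

test_that("full preprocessing pipeline routes strata and leaves no missing cells", {
  # constructed masks: 5 drop, 10 low, 15 moderate (+20 complete), 100 samples
  nmiss <- c(rep(80, 5), rep(10, 10), rep(30, 15), rep(0, 20))
  im_log <- mask_matrix(nmiss, 100, seed = 6)
  im_raw <- intensity_matrix(2^im_log$values, "raw")
  res <- preprocess(im_raw, preprocess_config(seed = 3))
  expect_equal(res$report$n_dropped_missingness, 5L)
  expect_equal(unname(res$report$strata_counts[c("low", "moderate")]),
               c(10L, 15L))
  expect_equal(res$report$n_proteins_in, 50L)
  expect_equal(n_missing(res$matrix), 0L)
  expect_equal(res$matrix$scale, "log2")

  # observed cells carry through log2 exactly
  obs_ids <- intersect(proteins(res$matrix), proteins(im_log))
  mask <- !is.na(im_log$values[obs_ids, ])
  expect_identical(res$matrix$values[obs_ids, ][mask],
                   im_log$values[obs_ids, ][mask])

  # complete input: only the log2 transform applies
  full <- intensity_matrix(2^mask_matrix(rep(0, 8), 10)$values, "raw")
  res2 <- preprocess(full)
  expect_equal(res2$report$n_dropped_missingness, 0L)
  expect_equal(res2$report$n_cells_imputed_knn, 0L)
  expect_equal(res2$report$n_cells_imputed_downshift, 0L)
  expect_equal(res2$matrix$values, log2(full$values))

  # idempotence: reapplying to the already-processed (log2, complete) matrix
  res3 <- preprocess(res2$matrix)
  expect_identical(res3$matrix$values, res2$matrix$values)
})
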