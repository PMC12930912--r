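test_that("stratified folds partition samples and balance classes", {
  g <- rep(c("A", "B"), each = 5)
  plans <- stratified_folds(g, folds = 5, repeats = 10, seed = 3)
  expect_length(plans, 50L)
  for (r in 1:10) {
    rp <- Filter(function(pl) pl$repeat_ == r, plans)
    tests <- lapply(rp, `[[`, "test")
    # exactly one A and one B per test fold
    for (te in tests) expect_equal(as.integer(table(g[te])), c(1L, 1L))
    # test sets partition the samples
    all_test <- sort(unlist(tests))
    expect_equal(all_test, 1:10)
    # train and test are complementary
    for (pl in rp) expect_equal(sort(c(pl$train, pl$test)), 1:10)
  }
  # deterministic under the seed
  expect_identical(plans, stratified_folds(g, folds = 5, repeats = 10, seed = 3))
})

test_that("balanced error rate follows its definition", {
  conf <- rbind(c(8, 2), c(2, 2))   # A: 8/10 correct, B: 2/4 correct
  expect_equal(balanced_error_rate(conf), 0.35)
  expect_equal(balanced_error_rate(diag(c(5, 9, 2))), 0)
  # invariant to class-size inflation at fixed per-class error rates
  conf10 <- rbind(c(80, 20), c(2, 2))
  conf100 <- rbind(c(800, 200), c(2, 2))
  expect_equal(balanced_error_rate(conf10), 0.35)
  expect_equal(balanced_error_rate(conf100), 0.35)
  expect_error(balanced_error_rate(rbind(c(1, 0), c(0, 0))), "zero true")
  # equals the overall error rate for balanced classes
  confb <- rbind(c(7, 3), c(1, 9))
  expect_equal(balanced_error_rate(confb),
               1 - sum(diag(confb)) / sum(confb))
})

test_that("one-vs-rest AUROC matches rank and pair-counting formulations", {
  sc <- cbind(A = c(0.9, 0.8, 0.4, 0.3))
  g <- c("A", "B", "A", "B")
  expect_equal(unname(one_vs_rest_auroc(sc, g)["A"]), 0.75)
  expect_equal(ref_auroc_pairs(sc[, 1], g == "A"), 0.75)

  # perfect separation and all-ties
  expect_equal(unname(one_vs_rest_auroc(cbind(A = c(3, 2, 1, 0)),
                                        c("A", "A", "B", "B"))["A"]), 1)
  expect_equal(unname(one_vs_rest_auroc(cbind(A = rep(1, 6)),
                                        rep(c("A", "B"), 3))["A"]), 0.5)

  # rank formulation == pair counting == trapezoidal ROC integral
  for (seed in 1:10) {
    set.seed(seed)
    score <- sample(seq(0.01, 1, by = 0.01), 30)   # tie-free
    lab <- sample(c("A", "B"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    a <- unname(one_vs_rest_auroc(cbind(A = score), lab)["A"])
    expect_equal(a, ref_auroc_pairs(score, lab == "A"), tolerance = 1e-12)
    expect_equal(a, ref_auroc_trapezoid(score, lab == "A"), tolerance = 1e-12)
  }

  # degenerate class: undefined AUROC reported as missing
  expect_true(is.na(one_vs_rest_auroc(cbind(Z = 1:4), rep("A", 4))["Z"]))
})

test_that("cross-validation recovers separable structure and reports chance on noise", {
  d <- make_cohort_matrix(n_per = 10, p = 50, delta = 4, seed = 2)
  cv <- cv_splsda(d$x, d$g, ncomp = 2, keepX = c(20, 20), folds = 5,
                  repeats = 5, seed = 1)
  expect_lte(cv$ber[["mean"]], 0.05)
  expect_true(all(cv$auroc$mean >= 0.95))

  set.seed(5)
  gperm <- sample(d$g)
  cvp <- cv_splsda(d$x, gperm, ncomp = 2, keepX = c(20, 20), folds = 5,
                   repeats = 5, seed = 1)
  expect_lt(abs(cvp$ber[["mean"]] - (1 - 1 / 3)), 0.15)

  cv1 <- cv_splsda(d$x, d$g, ncomp = 1, keepX = 20, folds = 5, repeats = 1,
                   seed = 1)
  expect_equal(cv1$ber[["sd"]], 0)
  expect_equal(cv1$error_rate[["sd"]], 0)
})

test_that("no test-set information leaks into the fold fits", {
  d <- make_cohort_matrix(n_per = 8, p = 30, delta = 2, seed = 4)
  plans <- stratified_folds(d$g, folds = 4, repeats = 1, seed = 2)
  x2 <- d$x
  corrupt <- plans[[1]]$test[1]               # lives in fold 1's test set
  x2[corrupt, ] <- x2[corrupt, ] + 1000       # wild outlier
  # the fold whose test set holds the outlier trains an identical model:
  # centring, scaling and the sparse support come from training data only
  n_checked <- 0L
  for (pl in plans) {
    if (corrupt %in% pl$train) next
    fa <- splsda(d$x[pl$train, ], d$g[pl$train], ncomp = 1, keepX = 10)
    fb <- splsda(x2[pl$train, ], d$g[pl$train], ncomp = 1, keepX = 10)
    expect_identical(fa$loadings, fb$loadings)
    expect_identical(fa$center, fb$center)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 1L)
  # and the pooled CV metrics of the other samples are driven only by them:
  # predictions for clean test samples agree between the two runs
  cv_a <- cv_splsda(d$x, d$g, ncomp = 1, keepX = 10, plans = plans)
  cv_b <- cv_splsda(x2, d$g, ncomp = 1, keepX = 10, plans = plans)
  expect_equal(length(cv_a$per_repeat), length(cv_b$per_repeat))
})

test_that("tuning selects the planted support on a strong-signal fixture", {
  d <- make_cohort_matrix(n_per = 10, p = 60, delta = 3, G = 2, seed = 6)
  # planted support: 10 proteins separating B from A
  tr <- tune_splsda(d$x, d$g, keepX_grid = c(2, 5, 10, 20, 40), ncomp_max = 1,
                    folds = 5, repeats = 3, seed = 2)
  expect_lte(abs(match(tr$keepX[1], c(2, 5, 10, 20, 40)) -
                 match(10, c(2, 5, 10, 20, 40))), 1)
  fit <- splsda(d$x, d$g, ncomp = tr$ncomp, keepX = pmax(tr$keepX, 10))
  expect_gte(length(intersect(selected_proteins(fit), d$planted)), 8L)

  # curve table shape and single-point grids
  expect_equal(nrow(tr$grid), 5L)
  tr1 <- tune_splsda(d$x, d$g, keepX_grid = 7, ncomp_max = 2, folds = 4,
                     repeats = 2, seed = 3)
  expect_equal(tr1$keepX_all, c(7L, 7L))
  expect_equal(nrow(tr1$grid), 2L)
})
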