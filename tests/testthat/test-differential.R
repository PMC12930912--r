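two_group_matrix <- function(p = 20, n_per = 5, delta = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(p * 2 * n_per, 20), p, 2 * n_per)
  g <- rep(c("A", "B"), each = n_per)
  v[, g == "B"] <- v[, g == "B"] + delta
  rownames(v) <- sprintf("P%03d", seq_len(p))
  colnames(v) <- sprintf("s%02d", seq_len(2 * n_per))
  list(v = v, g = g)
}

test_that("log2 fold change is the difference of group means and antisymmetric", {
  v <- rbind(P1 = c(2, 2, 0, 0), P2 = c(1, 1, 1, 1))
  colnames(v) <- paste0("s", 1:4)
  g <- c("A", "A", "B", "B")
  fc <- log2_fold_change(v, g, contrast_spec("two_group", "A", "B"))
  expect_equal(unname(fc), c(2, 0))
  fc_rev <- log2_fold_change(v, g, contrast_spec("two_group", "B", "A"))
  expect_equal(unname(fc_rev), -unname(fc))
  expect_error(log2_fold_change(v, g, contrast_spec("two_group", "A", "Z")),
               "no samples")
})

test_that("per-protein ANOVA matches the aov oracle and its identities", {
  # hand fixture, oracle-computed F
  v <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 1, 9)
  rownames(v) <- "P1"; colnames(v) <- paste0("s", 1:9)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  res <- protein_anova(v, g)
  oracle <- summary(stats::aov(v[1, ] ~ factor(g)))[[1]]
  expect_equal(res$statistic, oracle[["F value"]][1], tolerance = 1e-12)
  expect_equal(res$statistic, 3)
  expect_equal(res$p_value, oracle[["Pr(>F)"]][1], tolerance = 1e-12)

  # random fixtures against aov
  set.seed(2)
  v2 <- matrix(rnorm(5 * 12), 5, 12,
               dimnames = list(paste0("P", 1:5), paste0("s", 1:12)))
  g2 <- rep(c("a", "b", "c"), each = 4)
  res2 <- protein_anova(v2, g2)
  for (i in 1:5) {
    o <- summary(stats::aov(v2[i, ] ~ factor(g2)))[[1]]
    expect_equal(res2$statistic[i], o[["F value"]][1], tolerance = 1e-10)
    expect_equal(res2$p_value[i], o[["Pr(>F)"]][1], tolerance = 1e-10)
  }

  # two groups: F = t^2
  d <- two_group_matrix(p = 30, seed = 3)
  fa <- protein_anova(d$v, d$g)
  tt <- protein_ttest(d$v, d$g, contrast_spec("two_group", "A", "B"))
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(fa$p_value, tt$p_value, tolerance = 1e-10)

  # degenerate: no variance at all -> p = 1
  vc <- matrix(5, 2, 6, dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
  rc <- protein_anova(vc, rep(c("A", "B"), each = 3))
  expect_equal(rc$p_value, c(1, 1))
})

test_that("t statistics match t.test on random fixtures", {
  for (seed in 1:25) {
    d <- two_group_matrix(p = 4, n_per = 4, delta = runif(1, 0, 2),
                          seed = seed)
    res <- protein_ttest(d$v, d$g, contrast_spec("two_group", "A", "B"))
    for (i in seq_len(nrow(d$v))) {
      o <- stats::t.test(d$v[i, d$g == "A"], d$v[i, d$g == "B"],
                         var.equal = TRUE)
      expect_equal(res$statistic[i], unname(o$statistic), tolerance = 1e-10)
      expect_equal(res$p_value[i], o$p.value, tolerance = 1e-10)
    }
  }
  # equal values on both sides: t = 0, p = 1
  ve <- matrix(3, 1, 8, dimnames = list("P1", paste0("s", 1:8)))
  re <- protein_ttest(ve, rep(c("A", "B"), each = 4),
                      contrast_spec("two_group", "A", "B"))
  expect_equal(re$statistic, 0)
  expect_equal(re$p_value, 1)
})

test_that("null cohorts are calibrated: uniform p, nominal type-I error", {
  cfg <- cohort_config(n_proteins = 500L, groups = c(A = 8L, B = 8L, C = 8L),
                       n_effect_proteins = 0L, mnar_mid = -Inf, mcar = 0,
                       seed = 11L)
  coh <- generate_cohort(cfg)
  res <- protein_anova(log2_transform(coh$matrix), coh$metadata$group)
  expect_gt(stats::ks.test(res$p_value, "punif")$p.value, 0.01)
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("multiplicity adjustment matches hand and independent step-up results", {
  expect_equal(adjust_fdr(rep(0.01, 4), "bonferroni"), rep(0.04, 4))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5), "bh"), rep(1, 5))
  # NA propagation without inflating m
  q <- adjust_fdr(c(0.01, NA, 0.02), "bh")
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], adjust_fdr(c(0.01, 0.02), "bh"))

  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(3:50, 1))
    q <- adjust_fdr(p, "bh")
    expect_equal(q, ref_bh_stepup(p), tolerance = 1e-12)
    # monotone in p after sorting
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("differential tables rank by q then |fold change| then id", {
  tb <- data.frame(protein = c("P2", "P1", "P3", "P4"),
                   log2_fc = c(1, 3, -3, 2),
                   q_value = c(0.02, 0.01, 0.01, 0.02))
  r <- rank_proteins(tb)
  expect_equal(r$protein, c("P1", "P3", "P4", "P2"))
  expect_equal(r$rank, 1:4)
  # full tie: id order
  tb2 <- data.frame(protein = c("Pb", "Pa"), log2_fc = c(1, 1),
                    q_value = c(0.5, 0.5))
  expect_equal(rank_proteins(tb2)$protein, c("Pa", "Pb"))
})

test_that("differential_table integrates means, fold change, test and flags", {
  d <- two_group_matrix(p = 50, n_per = 6, delta = 0, seed = 7)
  d$v[1:5, d$g == "B"] <- d$v[1:5, d$g == "B"] + 4
  tb <- differential_table(d$v, d$g, contrast_spec("two_group", "B", "A"))
  expect_equal(nrow(tb), 50L)
  expect_equal(anyDuplicated(tb$protein), 0L)
  expect_true(all(c("mean_A", "mean_B", "log2_fc", "q_value") %in% names(tb)))
  top5 <- tb$protein[1:5]
  expect_setequal(top5, sprintf("P%03d", 1:5))
  expect_true(all(tb$significant[1:5]))
  expect_equal(tb$log2_fc, tb$mean_B - tb$mean_A)
  # q >= p everywhere and flags consistent
  expect_true(all(tb$q_value >= tb$p_value - 1e-15))
  expect_equal(tb$significant, tb$q_value <= 0.05)

  # one-vs-rest contrast pools the rest
  d3 <- make_cohort_matrix(n_per = 6, p = 30, delta = 3, seed = 8)
  tb3 <- differential_table(t(d3$x), d3$g, contrast_spec("one_vs_rest", "A"),
                            test = "ttest", correction = "bonferroni")
  expect_equal(nrow(tb3), 30L)
})

test_that("ranked lists order by the signed significance metric", {
  tb <- data.frame(protein = paste0("P", 1:4),
                   log2_fc = c(2, -2, 1, -1),
                   p_value = c(1e-4, 1e-4, 1e-2, 1e-2),
                   q_value = c(1e-3, 1e-3, 3e-2, 3e-2))
  rl <- ranked_list(tb)
  expect_equal(rl$protein, c("P1", "P3", "P4", "P2"))
  # negating fold changes reverses the order exactly
  tbn <- tb; tbn$log2_fc <- -tbn$log2_fc
  expect_equal(ranked_list(tbn)$protein, rev(rl$protein))
  # filter keeps only sub-threshold entries
  tb$q_value <- c(0.01, 0.01, 0.2, 0.2)
  expect_equal(nrow(ranked_list(tb, filter = 0.05)), 2L)
  expect_equal(nrow(ranked_list(tb, filter = 0.05, filter_on = "p")), 4L)
})

test_that("transcript ANOVA reuses the protein machinery with star coding", {
  v <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 1, 9,
              dimnames = list("GENE1", paste0("s", 1:9)))
  g <- rep(c("g1", "g2", "g3"), each = 3)
  ta <- transcript_anova(v, g, genes = c("GENE1", "ABSENT"))
  pa <- protein_anova(v, g)
  expect_equal(ta$statistic[1], pa$statistic[1])
  expect_false(ta$present[2])
  expect_true(is.na(ta$p_value[2]))

  expect_equal(signif_stars(c(0.3, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
})
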