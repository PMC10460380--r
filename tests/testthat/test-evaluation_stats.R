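test_that("lower-tailed Fisher matches closed forms and base R", {
  # identical proportions carry no evidence
  expect_equal(fisher_lower(matrix(c(0, 0, 10, 10), 2)), 1)
  # complete separation the 'wrong' way: P[X <= 0] = 1/choose(10,5)
  expect_equal(fisher_lower(matrix(c(0, 5, 5, 0), 2)), 1 / 252)
  expect_warning(p <- fisher_lower(matrix(0L, 2, 2)), "all-zero")
  expect_equal(p, 1)
  # independent route through base R's implementation
  tab <- matrix(c(3, 9, 14, 6), 2)
  expect_equal(fisher_lower(tab),
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
})

test_that("concordance accounting reproduces hand-tallied tables", {
  # all predictions as expected
  pred <- c("pre-receptive", "receptive", "post-receptive")
  expected <- c("ESE", "MSE", "LSE")
  ct <- evaluate_concordance(pred, expected)
  expect_equal(ct$concordance_pct, 100)
  expect_equal(ct$displaced_pct, 0)

  # transitionary calls at MSE are in-range, not displacement
  ct <- evaluate_concordance(
    c("early-receptive", "late-receptive", "receptive", "pre-receptive"),
    c("MSE", "MSE", "MSE", "MSE"))
  expect_equal(ct$concordant, 3L)
  expect_equal(ct$displaced, 1L)
  expect_equal(ct$in_range_shift, 2L)
  expect_equal(ct$in_range_shift_pct, 50)

  # unknown expected phases are excluded with a warning
  expect_warning(
    ct <- evaluate_concordance(c("receptive", "receptive"),
                               c("MSE", "PE")),
    "PE")
  expect_equal(ct$n, 1L)
})

test_that("cross-validation is perfect on separated clusters and folds partition", {
  fix <- make_separated_counts(seed = 61)
  cv <- crossvalidate(fix$sim$counts, housekeepers(fix$panel),
                      n_repeats = 3, seed = 5, horn_iter = 30)
  expect_equal(cv$macro_accuracy, 1.0)
  expect_equal(unname(cv$per_class_recall), rep(1, 3))
  n <- nrow(fix$sim$counts$counts)
  for (folds in cv$fold_assignments) {
    expect_equal(sort(unlist(lapply(1:5, function(f) which(folds == f)))),
                 seq_len(n))
    # stratification: every test fold holds every reference class
    cls <- beready:::PHASE_TO_CLASS[fix$sim$counts$sample_meta$phase]
    for (f in 1:5) {
      expect_true(all(beready:::REFERENCE_CLASSES %in% cls[folds == f]))
    }
  }
})

test_that("cross-validation refits per split: no leakage from the full fit", {
  fix <- make_separated_counts(seed = 62)
  full <- fit_reference(fix$sim$counts, housekeepers(fix$panel), seed = 1)
  idx <- seq_len(nrow(fix$sim$counts$counts) - 5)
  part <- count_matrix(fix$sim$counts$counts[idx, , drop = FALSE],
                       phase = fix$sim$counts$sample_meta$phase[idx])
  split_fit <- fit_reference(part, housekeepers(fix$panel), seed = 1)
  expect_false(isTRUE(all.equal(split_fit$centroids, full$centroids)))
  expect_false(isTRUE(all.equal(split_fit$scaling$center,
                                full$scaling$center)))
})

test_that("CV demands enough samples per class for stratification", {
  fix <- make_separated_counts(n_per_phase = c(PE = 3, ESE = 3, MSE = 6,
                                               LSE = 3), seed = 63)
  expect_error(crossvalidate(fix$sim$counts, housekeepers(fix$panel)),
               "lower n_folds")
})

test_that("Welch t-test handles analytic and degenerate cases", {
  m <- cbind(flat = c(1, 2, 3, 1, 2, 3),
             diff = c(0, 0.1, -0.1, 5, 5.1, 4.9),
             zero = rep(2, 6))
  g <- rep(c("a", "b"), each = 3)
  res <- de_test(m, g)
  expect_equal(res$t[res$gene == "flat"], 0)
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_equal(res$t[res$gene == "zero"], 0)
  expect_equal(res$p[res$gene == "zero"], 1)
  expect_true(res$p[res$gene == "diff"] < 0.05)

  # Bonferroni is plain multiplication, capped at one
  expect_equal(res$p_adj, pmin(1, res$p * 3))

  # agreement with stats::t.test on a non-degenerate gene
  set.seed(9)
  y <- rnorm(12)
  g2 <- rep(c("a", "b"), each = 6)
  ours <- de_test(cbind(g1 = y), g2)
  ref <- t.test(y[g2 == "a"], y[g2 == "b"])
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("Bonferroni holds the family-wise error rate on null data", {
  hits <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    m <- matrix(rnorm(20 * 72), 20, 72,
                dimnames = list(NULL, sprintf("g%02d", 1:72)))
    sum(de_test(m, rep(c("a", "b"), each = 10))$significant)
  }, numeric(1))
  # FWER <= 0.05: allow up to the binomial(40, 0.05) 99.9% quantile of
  # false-positive replicates
  expect_lte(sum(hits > 0), qbinom(0.999, 40, 0.05))
  # raw p-values behave like a uniform: about 3.6 of 72 below 0.05
  raw <- de_test(matrix(rnorm(20 * 72), 20, 72,
                        dimnames = list(NULL, sprintf("g%02d", 1:72))),
                 rep(c("a", "b"), each = 10))$p
  expect_lt(sum(raw < 0.05), 15)
})

test_that("interaction ANOVA finds planted effects and stays null otherwise", {
  set.seed(77)
  phase <- factor(rep(c("PE", "ESE", "MSE", "LSE"), each = 20))
  cond <- factor(rep(rep(c("healthy", "pcos"), each = 10), 4))
  # additive model: phase effect + condition effect, no interaction
  base <- as.numeric(phase) * 0.5 + (cond == "pcos") * 0.3
  m_null <- vapply(1:72, function(j) base + rnorm(80, sd = 1), numeric(80))
  colnames(m_null) <- sprintf("g%02d", 1:72)
  res <- anova_interaction(m_null, phase, cond)
  expect_equal(nrow(res), 72L)
  ks <- suppressWarnings(ks.test(res$p_interaction, "punif"))
  expect_gt(ks$p.value, 0.01)

  # plant a one-cell mean shift of 5 sd in one gene
  m_alt <- m_null
  cell <- phase == "MSE" & cond == "pcos"
  m_alt[cell, 1] <- m_alt[cell, 1] + 5
  res_alt <- anova_interaction(m_alt, phase, cond)
  expect_lt(res_alt$p_interaction[1], 0.001)

  # duplicating every observation strengthens the planted interaction
  res_dup <- anova_interaction(rbind(m_alt, m_alt), rep(phase, 2),
                               rep(cond, 2))
  expect_lt(res_dup$p_interaction[1], res_alt$p_interaction[1])

  # empty design cell: warned, nothing tested
  keep <- !(phase == "LSE" & cond == "pcos")
  expect_warning(
    res_empty <- anova_interaction(m_null[keep, ], phase[keep], cond[keep]),
    "LSE.*pcos|empty")
  expect_equal(nrow(res_empty), 0L)
})
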