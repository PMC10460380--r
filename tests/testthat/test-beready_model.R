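test_that("Horn's analysis keeps the floor on pure noise and finds a factor", {
  set.seed(1)
  noise <- matrix(rnorm(60 * 20), 60, 20)
  k_noise <- horn_parallel(noise, n_iter = 100, seed = 10)
  expect_equal(as.integer(k_noise), 1L)

  # planted rank-1 structure: one latent factor loading on all columns
  f <- rnorm(60)
  signal <- outer(f, rep(1, 20)) + matrix(rnorm(60 * 20, sd = 0.1), 60, 20)
  k_sig <- horn_parallel(scale(signal), n_iter = 100, seed = 10)
  expect_gte(as.integer(k_sig), 1L)
  ev <- attr(k_sig, "eigenvalues")
  expect_gt(ev[1] / ev[2], 10)
})

test_that("Horn retention is monotone in the quantile parameter", {
  set.seed(7)
  x <- matrix(rnorm(50 * 15), 50, 15)
  k_strict <- horn_parallel(x, n_iter = 100, quantile = 0.05, seed = 3)
  k_loose <- horn_parallel(x, n_iter = 100, quantile = 0.5, seed = 3)
  expect_lte(as.integer(k_strict), as.integer(k_loose))
})

test_that("Mahalanobis distance matches closed forms", {
  expect_equal(mahalanobis_sq(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(3, 4), c(0, 0), diag(2)), 25)
  # diagonal covariance (2, 0.5): d2 = 1/2 + 1/0.5
  cov_inv <- solve(diag(c(2, 0.5)))
  expect_equal(mahalanobis_sq(c(1, 1), c(0, 0), cov_inv), 2.5)
  expect_error(mahalanobis_sq(c(1, 2, 3), c(0, 0), diag(2)), "dimension")
})

test_that("Mahalanobis distance is invariant under affine maps of PC space", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    x <- rnorm(k); cen <- rnorm(k)
    a <- matrix(rnorm(k * k), k)
    covm <- crossprod(a) + diag(k) * 0.5
    d0 <- mahalanobis_sq(x, cen, solve(covm))
    # invertible map of the space, with centroid and covariance transformed
    amap <- matrix(rnorm(k * k), k) + diag(k) * 2
    d1 <- mahalanobis_sq(amap %*% x, amap %*% cen,
                         solve(amap %*% covm %*% t(amap)))
    expect_equal(d1, d0, tolerance = 1e-8)
  }
})

test_that("chi2 outlier gate matches the analytic tails", {
  # chi2(2) survival at 2 ln 2 is exactly 1/2
  r <- outlier_p(2 * log(2), k = 2)
  expect_equal(r$p, 0.5)
  expect_false(r$is_outlier)
  # 0.975 quantile of chi2(2) from published tables
  r <- outlier_p(7.3778, k = 2)
  expect_equal(r$p, 0.025, tolerance = 1e-4)
  # zero distance is never an upper-tail outlier
  r <- outlier_p(0, k = 3)
  expect_equal(r$p, 1)
  expect_false(r$is_outlier)
  # the literal lower-tail reading flags it instead
  r <- outlier_p(0, k = 3, direction = "lower")
  expect_true(r$is_outlier)
})

test_that("relative probabilities follow the Gaussian kernel, stably", {
  expect_equal(relative_probability(3, 3), c(0.5, 0.5))
  expect_equal(relative_probability(2, 4)[1], 1 / (1 + exp(-1)))
  expect_equal(sum(relative_probability(2, 4)), 1)
  big <- relative_probability(1e8, 1e8 + 2)
  expect_false(anyNA(big))
  expect_equal(sum(big), 1)
  expect_equal(relative_probability(0, 1e8)[1], 1)
})

test_that("reference fitting reproduces its own projections and centroids", {
  fix <- make_separated_counts(seed = 41)
  fit <- fit_reference(fix$sim$counts, housekeepers(fix$panel), seed = 2)

  pr <- beready:::project_counts(fix$sim$counts, fit)
  cls <- unname(beready:::PHASE_TO_CLASS[fix$sim$counts$sample_meta$phase])
  for (cl in fit$class_order) {
    expect_equal(unname(fit$centroids[cl, ]),
                 unname(colMeans(pr$scores[cls == cl, , drop = FALSE])),
                 tolerance = 1e-10)
  }

  # well-separated clusters: centroids far apart in Mahalanobis terms
  thr <- qchisq(0.99, df = fit$k)
  combs <- combn(fit$class_order, 2)
  for (j in seq_len(ncol(combs))) {
    d2 <- mahalanobis_sq(fit$centroids[combs[1, j], ],
                         fit$centroids[combs[2, j], ], fit$within_cov_inv)
    expect_gt(d2, thr)
  }
})

test_that("training requires two samples per reference class", {
  fix <- make_separated_counts(n_per_phase = c(PE = 4, ESE = 4, MSE = 4,
                                               LSE = 1), seed = 6)
  expect_error(fit_reference(fix$sim$counts, housekeepers(fix$panel)),
               ">= 2")
})

test_that("the hierarchical decision handles boundaries and outliers", {
  model <- list(k = 2L, outlier_alpha = 0.025, outlier_tail = "upper",
                boundaries = c(0.25, 0.75))

  # clear winner: distance 0 to pre-receptive
  r <- beready:::classify_scores(
    c("pre-receptive" = 0, "receptive" = 40, "post-receptive" = 90), model)
  expect_equal(r$final_class, "pre-receptive")
  expect_gt(max(r$rel_prob), 0.75)

  # exact tie between pre and receptive: the defining early-receptive case
  r <- beready:::classify_scores(
    c("pre-receptive" = 5, "receptive" = 5, "post-receptive" = 60), model)
  expect_equal(unname(r$rel_prob), c(0.5, 0.5))
  expect_equal(r$final_class, "early-receptive")
  expect_equal(r$stage2_pair, c("pre-receptive", "receptive"))

  # receptive/post tie yields late-receptive
  r <- beready:::classify_scores(
    c("pre-receptive" = 60, "receptive" = 5, "post-receptive" = 5), model)
  expect_equal(r$final_class, "late-receptive")

  # closest is receptive: the adjacent pair with smaller summed d2 is used
  r <- beready:::classify_scores(
    c("pre-receptive" = 30, "receptive" = 1, "post-receptive" = 8), model)
  expect_equal(r$stage2_pair, c("receptive", "post-receptive"))
  expect_equal(r$final_class, "receptive")

  # far from everything: still classified, flagged as outlier
  r <- beready:::classify_scores(
    c("pre-receptive" = 500, "receptive" = 520, "post-receptive" = 580),
    model)
  expect_true(r$overall_outlier)
  expect_true(r$final_class %in% beready:::RECEPTIVITY_CLASSES)

  # exactly one final class, and the stage-2 pair is always adjacent
  expect_length(r$final_class, 1L)
  expect_true(paste(r$stage2_pair, collapse = "|") %in%
                c("pre-receptive|receptive", "receptive|post-receptive"))
})

test_that("held-out samples classify to their class or its transition", {
  fix <- make_separated_counts(seed = 55)
  fit <- fit_reference(fix$sim$counts, housekeepers(fix$panel), seed = 9)
  test_cfg <- simulation_config(fix$panel,
                                n_per_phase = c(PE = 10, ESE = 10,
                                                MSE = 10, LSE = 10),
                                phase_means = fix$cfg$phase_means,
                                dispersion = 50, libsize_sigma = 0.2,
                                seed = 77)
  sim <- simulate_counts(test_cfg)
  res <- classify(sim$counts, fit)
  pred <- vapply(res, `[[`, character(1), "final_class")
  ok_sets <- list(
    "pre-receptive" = c("pre-receptive", "early-receptive"),
    "receptive" = c("early-receptive", "receptive", "late-receptive"),
    "post-receptive" = c("late-receptive", "post-receptive")
  )
  hits <- mapply(function(p, cl) p %in% ok_sets[[cl]], pred, sim$truth$class)
  expect_gte(mean(hits), 0.95)
})

test_that("classification is deterministic and reports all intermediates", {
  fix <- make_separated_counts(seed = 3)
  fit <- fit_reference(fix$sim$counts, housekeepers(fix$panel), seed = 4)
  r1 <- classify(subset_one(fix$sim$counts, 5), fit)
  r2 <- classify(subset_one(fix$sim$counts, 5), fit)
  expect_identical(r1$d2, r2$d2)
  expect_identical(r1$final_class, r2$final_class)
  expect_named(r1$rel_prob, r1$stage2_pair)
  expect_equal(sum(r1$rel_prob), 1)
  rep <- classification_report(r1)
  expect_equal(nrow(rep), 1L)
  expect_true(all(c("d2_pre", "final_class", "rel_prob_leading") %in%
                    names(rep)))
})

test_that("classifying with missing model genes is an explicit error", {
  fix <- make_separated_counts(seed = 14)
  fit <- fit_reference(fix$sim$counts, housekeepers(fix$panel), seed = 4)
  crop <- count_matrix(fix$sim$counts$counts[, -7, drop = FALSE],
                       phase = fix$sim$counts$sample_meta$phase)
  expect_error(classify(crop, fit), "lacks model gene")
})
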