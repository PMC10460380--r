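#' Repeated stratified fivefold cross-validation
#'
#' Estimates classification accuracy by repeatedly partitioning the labelled
#' samples into `n_folds` subgroups, training the full model from scratch on
#' all but one fold (normalisation, scaling, Horn's parallel analysis,
#' centroids — nothing is shared across splits) and classifying the held-out
#' fold. Partitions are stratified by rejection sampling: a partition is
#' redrawn until every test fold contains at least one sample of each
#' reference class. Held-out samples are assigned the most probable of the
#' three reference classes (transitionary classes are not used in
#' cross-validation). The reported macro accuracy is the unweighted mean of
#' per-class recall, averaged over repeats; micro accuracy (overall fraction
#' correct) is reported alongside.
#'
#' @param m a [count_matrix()] with phase labels for every sample.
#' @param housekeeper_ids housekeeper gene ids.
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of repeated partitions (default 100).
#' @param seed integer seed for fold construction and Horn permutations.
#' @param permute_labels permute the class labels freshly in every repeat,
#'   giving a proper chance-level permutation null for the accuracy.
#' @param ... passed to [fit_reference()] (e.g. `horn_iter`).
#' @return object of class `cv_result`: `macro_accuracy`, `micro_accuracy`,
#'   `per_class_recall` (averaged over repeats), `per_repeat_macro`,
#'   `confusion` (summed over repeats), `fold_assignments` (list of integer
#'   vectors), `n_folds`, `n_repeats`, `seed`.
#' @export
crossvalidate <- function(m, housekeeper_ids, n_folds = 5L,
                          n_repeats = 100L, seed = NULL,
                          permute_labels = FALSE, ...) {
  stopifnot(inherits(m, "count_matrix"))
  phase <- m$sample_meta$phase
  if (any(!phase %in% PHASE_LEVELS)) {
    stop("cross-validation requires phase labels for all samples",
         call. = FALSE)
  }
  cls <- unname(PHASE_TO_CLASS[phase])
  n <- nrow(m$counts)
  n_per <- table(factor(cls, levels = REFERENCE_CLASSES))
  if (any(n_per < n_folds)) {
    stop("each reference class needs >= ", n_folds, " samples for ",
         n_folds, "-fold stratified CV (lower n_folds); got ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "),
         call. = FALSE)
  }

  phase0 <- phase
  cls0 <- cls
  with_seed(seed, {
    confusion <- matrix(0L, 3L, 3L,
                        dimnames = list(truth = REFERENCE_CLASSES,
                                        predicted = REFERENCE_CLASSES))
    per_repeat_macro <- numeric(n_repeats)
    recall_sum <- stats::setNames(numeric(3L), REFERENCE_CLASSES)
    fold_assignments <- vector("list", n_repeats)

    for (r in seq_len(n_repeats)) {
      if (permute_labels) {
        # a fresh permutation per repeat: a single fixed permutation can
        # correlate by chance with real cluster structure and bias the null
        perm <- sample(n)
        phase <- phase0[perm]
        cls <- cls0[perm]
      }
      folds <- stratified_folds(cls, n_folds)
      fold_assignments[[r]] <- folds
      pred <- character(n)
      for (f in seq_len(n_folds)) {
        test_idx <- which(folds == f)
        train_idx <- which(folds != f)
        if (length(intersect(train_idx, test_idx))) {
          stop("internal error: train/test overlap in fold ", f,
               call. = FALSE)
        }
        train <- subset_counts(m, train_idx)
        train$sample_meta$phase <- phase[train_idx]
        fit <- fit_reference(train, housekeeper_ids, ...)
        pr <- project_counts(subset_counts(m, test_idx), fit)
        for (i in seq_len(nrow(pr$scores))) {
          d2 <- vapply(fit$class_order, function(cl) {
            mahalanobis_sq(pr$scores[i, ], fit$centroids[cl, ],
                           fit$within_cov_inv)
          }, numeric(1))
          pred[test_idx[i]] <- names(d2)[which.min(d2)]
        }
      }
      tab <- table(factor(cls, levels = REFERENCE_CLASSES),
                   factor(pred, levels = REFERENCE_CLASSES))
      confusion <- confusion + tab
      recalls <- diag(tab) / rowSums(tab)
      recall_sum <- recall_sum + recalls
      per_repeat_macro[r] <- mean(recalls)
    }

    structure(list(
      macro_accuracy = mean(per_repeat_macro),
      micro_accuracy = sum(diag(confusion)) / sum(confusion),
      per_class_recall = recall_sum / n_repeats,
      per_repeat_macro = per_repeat_macro,
      confusion = confusion,
      fold_assignments = fold_assignments,
      n_folds = as.integer(n_folds),
      n_repeats = as.integer(n_repeats),
      seed = seed,
      permuted = permute_labels
    ), class = "cv_result")
  })
}

# Stratified partition by rejection: redraw until every fold holds >= 1
# sample of each class. Terminates because each class has >= n_folds samples.
stratified_folds <- function(cls, n_folds) {
  n <- length(cls)
  repeat {
    folds <- sample(rep_len(seq_len(n_folds), n))
    ok <- all(vapply(seq_len(n_folds), function(f) {
      all(REFERENCE_CLASSES %in% cls[folds == f])
    }, logical(1)))
    if (ok) return(folds)
  }
}

subset_counts <- function(m, idx) {
  count_matrix(m$counts[idx, , drop = FALSE],
               phase = m$sample_meta$phase[idx],
               cohort = m$sample_meta$cohort[idx])
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats%s\n", x$n_folds, x$n_repeats,
              if (x$permuted) " (permuted labels)" else ""))
  cat(sprintf("  macro accuracy: %.3f  micro accuracy: %.3f\n",
              x$macro_accuracy, x$micro_accuracy))
  cat("  per-class recall:",
      paste(sprintf("%s=%.3f", names(x$per_class_recall),
                    x$per_class_recall), collapse = " "), "\n")
  invisible(x)
}

#' Concordance between predicted class and expected collection phase
#'
#' Cross-tabulates predicted five-way receptivity classes against the phase
#' each sample was collected in, and summarises agreement the way a
#' receptivity-validation study reads such a table: an ESE sample is expected
#' pre-receptive, an LSE sample post-receptive, and an MSE sample anything in
#' the receptive range (early-receptive, receptive or late-receptive —
#' transitionary calls at MSE count as normal WOI variability, not
#' displacement). A displaced call is any prediction outside the expected
#' set. The in-range shift rate is the fraction of MSE-expected samples
#' called early- or late-receptive.
#'
#' @param predicted character vector of five-way classes, or a (list of)
#'   `classification_result`.
#' @param expected_phase character vector in `ESE`/`MSE`/`LSE`; samples with
#'   any other label are excluded with a warning.
#' @return object of class `concordance_table`: `table` (expected x
#'   predicted counts), `n`, `concordant`, `displaced`, `in_range_shift`
#'   (count among MSE-expected), and the exact-ratio percentages
#'   `concordance_pct`, `displaced_pct`, `in_range_shift_pct`.
#' @export
evaluate_concordance <- function(predicted, expected_phase) {
  if (inherits(predicted, "classification_result")) predicted <-
      list(predicted)
  if (is.list(predicted)) {
    predicted <- vapply(predicted, `[[`, character(1), "final_class")
  }
  predicted <- as.character(predicted)
  expected_phase <- as.character(expected_phase)
  if (length(predicted) != length(expected_phase)) {
    stop("predicted and expected_phase lengths differ", call. = FALSE)
  }
  bad_pred <- !predicted %in% RECEPTIVITY_CLASSES
  if (any(bad_pred)) {
    stop("unknown predicted class(es): ",
         paste(unique(predicted[bad_pred]), collapse = ", "), call. = FALSE)
  }
  known <- expected_phase %in% c("ESE", "MSE", "LSE")
  if (any(!known)) {
    warning("excluding sample(s) with unknown expected phase: ",
            paste(unique(expected_phase[!known]), collapse = ", "),
            call. = FALSE)
  }
  predicted <- predicted[known]
  expected_phase <- expected_phase[known]
  n <- length(predicted)
  if (n == 0L) stop("no samples with a usable expected phase", call. = FALSE)

  expected_sets <- list(
    ESE = "pre-receptive",
    MSE = c("early-receptive", "receptive", "late-receptive"),
    LSE = "post-receptive"
  )
  concordant_i <- mapply(function(p, e) p %in% expected_sets[[e]],
                         predicted, expected_phase)
  tab <- table(expected = factor(expected_phase,
                                 levels = c("ESE", "MSE", "LSE")),
               predicted = factor(predicted, levels = RECEPTIVITY_CLASSES))
  n_mse <- sum(expected_phase == "MSE")
  in_range_shift <- sum(predicted %in% c("early-receptive",
                                         "late-receptive") &
                          expected_phase == "MSE")
  concordant <- sum(concordant_i)
  displaced <- n - concordant
  structure(list(
    table = tab, n = n,
    concordant = concordant, displaced = displaced,
    in_range_shift = in_range_shift, n_mse = n_mse,
    concordance_pct = 100 * concordant / n,
    displaced_pct = 100 * displaced / n,
    in_range_shift_pct = if (n_mse > 0L) 100 * in_range_shift / n_mse
                         else NA_real_
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "concordant %d/%d (%.1f%%), displaced %d/%d (%.1f%%), in-range shift %d/%d MSE (%.1f%%)\n",
    x$concordant, x$n, x$concordance_pct, x$displaced, x$n,
    x$displaced_pct, x$in_range_shift, x$n_mse, x$in_range_shift_pct))
  invisible(x)
}

#' Lower-tailed Fisher's exact test on a 2 x 2 table
#'
#' Exact hypergeometric one-sided p-value for the first cell of a 2 x 2
#' contingency table: `P[X <= x11]` over all tables with the observed
#' margins. Used to compare the displaced-WOI proportion between two cohorts
#' (first row = cohort with the putatively smaller proportion).
#'
#' @param table 2 x 2 matrix of non-negative integer counts, rows = groups,
#'   columns = (event, non-event).
#' @return p-value in `(0, 1]`. A degenerate all-zero table returns 1 with a
#'   warning.
#' @examples
#' fisher_lower(matrix(c(1, 7, 56, 37), nrow = 2))  # ~0.012
#' @export
fisher_lower <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2 x 2",
                                          call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) {
    warning("all-zero table; p = 1", call. = FALSE)
    return(1)
  }
  x11 <- table[1, 1]
  r1 <- sum(table[1, ])          # first row margin
  c1 <- sum(table[, 1])          # first column margin
  n <- sum(table)
  lo <- max(0L, r1 + c1 - n)
  if (x11 < lo) stop("inconsistent table margins", call. = FALSE)
  sum(stats::dhyper(lo:x11, c1, n - c1, r1))
}

#' Per-gene two-group differential-expression test
#'
#' Independent two-sided t-test per gene (Welch's unequal-variance form by
#' default) on shifted-log normalised values, with Bonferroni (default) or
#' Benjamini-Hochberg multiplicity correction and a significance flag at
#' `alpha`. A gene with zero variance in both groups is reported with
#' statistic 0 and p = 1 rather than `NaN`.
#'
#' @param m a `normalized_matrix` in the `shifted-log` state, or a plain
#'   numeric matrix (samples x genes).
#' @param groups two-level factor (or character) of length `nrow`.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame with one row per gene: group means, difference,
#'   `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
de_test <- function(m, groups, correction = c("bonferroni", "bh"),
                    var_equal = FALSE, alpha = 0.05) {
  correction <- match.arg(correction)
  if (inherits(m, "normalized_matrix")) {
    if (m$state != "shifted-log") {
      stop("de_test expects shifted-log values (state '", m$state, "')",
           call. = FALSE)
    }
    m <- m$values
  }
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels",
                                  call. = FALSE)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples",
                                    call. = FALSE)
  a <- m[groups == levels(groups)[1], , drop = FALSE]
  b <- m[groups == levels(groups)[2], , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  degenerate <- se == 0
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  df[degenerate] <- NA_real_
  p_adj <- stats::p.adjust(p, method = if (correction == "bh") "BH"
                                       else "bonferroni")
  data.frame(gene = colnames(m), mean_a = ma, mean_b = mb,
             diff = ma - mb, t = tstat, df = df, p = p, p_adj = p_adj,
             significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-way ANOVA with interaction
#'
#' Fits `value ~ factor1 * factor2` per gene and reports the interaction
#' F-statistic and p-value, with main effects available in the full ANOVA
#' tables (type II sums of squares, so unbalanced cell counts are handled).
#' If any design cell is empty the interaction is not estimable for any gene;
#' a warning names the empty cell(s) and a zero-row table is returned.
#'
#' @param m a `normalized_matrix` (shifted-log recommended) or numeric matrix.
#' @param factor1,factor2 factors of length `nrow` (e.g. cycle phase and
#'   condition).
#' @return data frame with one row per gene: `F_interaction`,
#'   `p_interaction`, plus main-effect F and p columns; attribute
#'   `ss_type = "II"`.
#' @export
anova_interaction <- function(m, factor1, factor2) {
  if (inherits(m, "normalized_matrix")) m <- m$values
  m <- as.matrix(m)
  f1 <- as.factor(factor1); f2 <- as.factor(factor2)
  stopifnot(length(f1) == nrow(m), length(f2) == nrow(m))
  cells <- table(f1, f2)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    warning("empty design cell(s): ",
            paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                          colnames(cells)[empty[, 2]]), collapse = ", "),
            "; interaction not estimable, no genes tested", call. = FALSE)
    out <- data.frame(gene = character(0), F_interaction = numeric(0),
                      p_interaction = numeric(0), F_factor1 = numeric(0),
                      p_factor1 = numeric(0), F_factor2 = numeric(0),
                      p_factor2 = numeric(0), stringsAsFactors = FALSE)
    attr(out, "ss_type") <- "II"
    return(out)
  }
  rows <- lapply(seq_len(ncol(m)), function(j) {
    fit <- stats::lm(m[, j] ~ f1 * f2)
    aa <- car::Anova(fit, type = 2)
    data.frame(gene = colnames(m)[j],
               F_interaction = aa["f1:f2", "F value"],
               p_interaction = aa["f1:f2", "Pr(>F)"],
               F_factor1 = aa["f1", "F value"],
               p_factor1 = aa["f1", "Pr(>F)"],
               F_factor2 = aa["f2", "F value"],
               p_factor2 = aa["f2", "Pr(>F)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ss_type") <- "II"
  out
}
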