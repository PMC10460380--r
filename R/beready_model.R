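#' Horn's parallel analysis for PCA component retention
#'
#' Determines how many principal components of a scaled matrix carry more
#' variance than expected under an independence null. The null is built by
#' independently permuting each column of the observed matrix (preserving
#' every gene's marginal distribution while destroying correlation),
#' recomputing the PCA eigenvalues `n_iter` times, and taking per-component
#' empirical quantiles at probability `1 - quantile`. The retained count `k`
#' is the number of leading observed eigenvalues exceeding their null
#' threshold, floored at 1.
#'
#' @param x numeric matrix (samples x genes), already centred/scaled.
#' @param n_iter number of permutation iterations (default 100).
#' @param quantile tail probability of the null eigenvalue distribution
#'   (default 0.05, i.e. observed eigenvalues must exceed the null 95th
#'   percentile).
#' @param seed optional integer seed for the permutations.
#' @return integer `k >= 1`, with attributes `eigenvalues` (observed) and
#'   `thresholds` (null quantiles).
#' @export
horn_parallel <- function(x, n_iter = 100L, quantile = 0.05, seed = NULL) {
  if (inherits(x, "normalized_matrix")) x <- x$values
  x <- as.matrix(x)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)",
                                           call. = FALSE)
  ev_obs <- pca_eigenvalues(x)
  if (!any(ev_obs > 0)) stop("matrix has rank 0; PCA is degenerate",
                             call. = FALSE)
  m <- length(ev_obs)
  n <- nrow(x); p <- ncol(x)
  colkey <- rep(seq_len(p), each = n)
  null_ev <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      # permute rows within every column in one radix sort
      xp <- matrix(x[order(colkey, stats::runif(n * p))], n, p)
      g <- if (n <= p) tcrossprod(xp) else crossprod(xp)
      ev <- eigen(g / (n - 1), symmetric = TRUE, only.values = TRUE)$values
      ev[seq_len(m)]
    }, numeric(m))
  })
  if (is.null(dim(null_ev))) null_ev <- matrix(null_ev, nrow = m)
  thr <- apply(null_ev, 1L, stats::quantile, probs = 1 - quantile,
               names = FALSE)
  keep <- ev_obs > thr
  # leading run of retained components; floor at one component
  k <- if (!keep[1]) 1L else which.min(c(keep, FALSE)) - 1L
  k <- max(1L, as.integer(k))
  attr(k, "eigenvalues") <- ev_obs
  attr(k, "thresholds") <- thr
  k
}

# PCA eigenvalues (sample covariance scale): svd singular values^2 / (n - 1)
pca_eigenvalues <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need >= 2 samples for PCA", call. = FALSE)
  d <- svd(x, nu = 0L, nv = 0L)$d
  d^2 / (n - 1)
}

#' Fit the receptivity reference model
#'
#' Fits the full classification model on a development set of phase-labelled
#' samples: housekeeper normalisation, optional shifted log, per-gene
#' z-scaling, PCA, Horn's parallel analysis for the retained dimension `k`,
#' per-class centroids of the projected training samples, and a ridge-
#' regularised pooled within-class covariance in PC space. Phase labels map
#' onto the three reference classes as PE/ESE -> pre-receptive, MSE ->
#' receptive, LSE -> post-receptive; the transitionary classes are never
#' training labels.
#'
#' @param dev a [count_matrix()] whose `sample_meta$phase` is in
#'   `PE`/`ESE`/`MSE`/`LSE` for every training sample.
#' @param housekeeper_ids housekeeper gene ids (from the panel).
#' @param log_before_scale apply the shifted log before scaling on the model
#'   path (default `FALSE`: the model path normalises and scales only).
#' @param shift shift constant if `log_before_scale = TRUE`.
#' @param horn_iter,horn_quantile Horn's parallel analysis parameters.
#' @param ridge_factor ridge added to the pooled covariance diagonal as
#'   `ridge_factor * trace / k` (default 1e-6).
#' @param outlier_alpha chi-square tail level flagging outliers (default
#'   0.025).
#' @param outlier_tail which chi-square tail flags outliers: `"upper"`
#'   (default; unusually distant samples), `"lower"` or `"both"`.
#' @param boundaries relative-probability boundaries `(lo, hi)` separating a
#'   reference call from a transitionary call (default `c(0.25, 0.75)`).
#' @param seed integer seed for the Horn permutations (fit is otherwise
#'   deterministic).
#' @return an object of class `reference_model`.
#' @export
fit_reference <- function(dev, housekeeper_ids,
                          log_before_scale = FALSE, shift = 1.0,
                          horn_iter = 100L, horn_quantile = 0.05,
                          ridge_factor = 1e-6,
                          outlier_alpha = 0.025,
                          outlier_tail = c("upper", "lower", "both"),
                          boundaries = c(0.25, 0.75),
                          seed = NULL) {
  stopifnot(inherits(dev, "count_matrix"))
  outlier_tail <- match.arg(outlier_tail)
  if (!(boundaries[1] < 0.5 && 0.5 < boundaries[2] && boundaries[2] <= 1)) {
    stop("boundaries must satisfy lo < 0.5 < hi <= 1", call. = FALSE)
  }

  nm <- normalize_housekeepers(dev, housekeeper_ids)
  phase <- nm$sample_meta$phase
  if (any(!phase %in% PHASE_LEVELS)) {
    stop("training requires phase labels in ",
         paste(PHASE_LEVELS, collapse = "/"), "; offending sample(s): ",
         paste(nm$sample_meta$sample_id[!phase %in% PHASE_LEVELS],
               collapse = ", "), call. = FALSE)
  }
  cls <- unname(PHASE_TO_CLASS[phase])
  n_per <- table(factor(cls, levels = REFERENCE_CLASSES))
  if (any(n_per < 2L)) {
    stop("each reference class needs >= 2 training samples; got ",
         paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "),
         call. = FALSE)
  }

  if (log_before_scale) nm <- shifted_log(nm, shift)
  scaling <- fit_scaling(nm)
  sc <- apply_scaling(nm, scaling)
  if (any(!is.finite(sc$values))) stop("non-finite values after scaling",
                                       call. = FALSE)

  pca <- stats::prcomp(sc$values, center = FALSE, scale. = FALSE)
  k <- horn_parallel(sc$values, n_iter = horn_iter,
                     quantile = horn_quantile, seed = seed)
  rotation <- pca$rotation[, seq_len(k), drop = FALSE]
  scores <- sc$values %*% rotation

  centroids <- do.call(rbind, lapply(REFERENCE_CLASSES, function(cl) {
    colMeans(scores[cls == cl, , drop = FALSE])
  }))
  rownames(centroids) <- REFERENCE_CLASSES

  # pooled within-class covariance with a small ridge on the diagonal
  n_tot <- nrow(scores)
  pooled <- Reduce(`+`, lapply(REFERENCE_CLASSES, function(cl) {
    s <- scores[cls == cl, , drop = FALSE]
    stats::cov(s) * (nrow(s) - 1L)
  })) / (n_tot - length(REFERENCE_CLASSES))
  ridge <- ridge_factor * sum(diag(pooled)) / k
  within_cov <- pooled + diag(ridge, k)

  model <- list(
    k = as.integer(k),
    genes = names(scaling$center),
    housekeeper_ids = as.character(housekeeper_ids),
    class_order = REFERENCE_CLASSES,
    label_map = PHASE_TO_CLASS,
    log_before_scale = log_before_scale,
    shift = shift,
    scaling = scaling,
    rotation = rotation,
    centroids = centroids,
    within_cov = within_cov,
    within_cov_inv = solve(within_cov),
    ridge = ridge,
    outlier_alpha = outlier_alpha,
    outlier_tail = outlier_tail,
    boundaries = as.numeric(boundaries),
    horn = list(n_iter = as.integer(horn_iter), quantile = horn_quantile,
                eigenvalues = unname(attr(k, "eigenvalues")),
                thresholds = unname(attr(k, "thresholds")))
  )
  class(model) <- "reference_model"
  model
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "reference_model: %d genes, k = %d PCs (Horn %d iter), classes: %s\n",
    length(x$genes), x$k, x$horn$n_iter,
    paste(x$class_order, collapse = " < ")))
  invisible(x)
}

#' Squared Mahalanobis distance
#'
#' `d2 = (x - centroid)' cov_inv (x - centroid)`; under a Gaussian model this
#' is chi-square distributed with `length(x)` degrees of freedom.
#'
#' @param x numeric vector.
#' @param centroid numeric vector of the same length.
#' @param cov_inv inverse covariance matrix (symmetric positive definite).
#' @return non-negative scalar.
#' @examples
#' mahalanobis_sq(c(3, 4), c(0, 0), diag(2))  # 25
#' @export
mahalanobis_sq <- function(x, centroid, cov_inv) {
  x <- as.numeric(x); centroid <- as.numeric(centroid)
  if (length(x) != length(centroid) || length(x) != nrow(cov_inv) ||
      nrow(cov_inv) != ncol(cov_inv)) {
    stop("dimension mismatch between x, centroid and cov_inv", call. = FALSE)
  }
  d <- x - centroid
  drop(t(d) %*% cov_inv %*% d)
}

#' Chi-square outlier gate for a squared Mahalanobis distance
#'
#' Converts a squared Mahalanobis distance in a `k`-dimensional space into a
#' chi-square tail probability and flags the sample as an outlier when the
#' probability falls below `alpha`. The default `"upper"` direction flags
#' unusually distant samples; `"lower"` flags samples unusually close to the
#' centroid, and `"both"` uses twice the smaller tail (capped at 1).
#'
#' @param d2 squared Mahalanobis distance (>= 0).
#' @param k degrees of freedom (retained PC count, >= 1).
#' @param alpha outlier level (default 0.025).
#' @param direction `"upper"`, `"lower"` or `"both"`.
#' @return list with `p` and `is_outlier`.
#' @export
outlier_p <- function(d2, k, alpha = 0.025,
                      direction = c("upper", "lower", "both")) {
  direction <- match.arg(direction)
  if (any(d2 < 0)) stop("d2 must be >= 0", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  p <- switch(direction,
    upper = stats::pchisq(d2, df = k, lower.tail = FALSE),
    lower = stats::pchisq(d2, df = k, lower.tail = TRUE),
    both = pmin(1, 2 * pmin(stats::pchisq(d2, df = k),
                            stats::pchisq(d2, df = k, lower.tail = FALSE)))
  )
  list(p = p, is_outlier = p < alpha)
}

#' Relative probability between the two closest classes
#'
#' Gaussian-kernel likelihood ratio
#' `p_a = exp(-d2_a/2) / (exp(-d2_a/2) + exp(-d2_b/2))`, evaluated in a
#' log-sum-exp-stable form so astronomically large distances still return a
#' valid pair summing to one.
#'
#' @param d2_a,d2_b squared Mahalanobis distances to the two classes.
#' @return numeric vector `c(p_a, p_b)` in `[0,1]^2` with `p_a + p_b == 1`.
#' @examples
#' relative_probability(2, 4)  # c(0.731..., 0.268...)
#' @export
relative_probability <- function(d2_a, d2_b) {
  stopifnot(is.finite(d2_a), is.finite(d2_b), d2_a >= 0, d2_b >= 0)
  p_a <- stats::plogis((d2_b - d2_a) / 2)
  c(p_a, 1 - p_a)
}

# Normalise + (log) + scale + project count rows with model parameters.
# m: count_matrix. Returns list(scores, sample_meta, qc_failed).
project_counts <- function(m, model) {
  stopifnot(inherits(m, "count_matrix"), inherits(model, "reference_model"))
  miss <- setdiff(union(model$genes, model$housekeeper_ids),
                  colnames(m$counts))
  if (length(miss)) {
    stop("sample matrix lacks model gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  nm <- normalize_housekeepers(m, model$housekeeper_ids)
  if (model$log_before_scale) nm <- shifted_log(nm, model$shift)
  sc <- apply_scaling(nm, model$scaling)
  scores <- sc$values %*% model$rotation
  list(scores = scores, sample_meta = nm$sample_meta,
       qc_failed = attr(nm, "qc_failed"))
}

adjacent_pairs <- list(
  c("pre-receptive", "receptive"),
  c("receptive", "post-receptive")
)
transitionary_of <- c("pre-receptive|receptive" = "early-receptive",
                      "receptive|post-receptive" = "late-receptive")

# Hierarchical decision for one projected sample given its three distances.
classify_scores <- function(d2, model) {
  op <- outlier_p(d2, model$k, model$outlier_alpha, model$outlier_tail)
  closest <- names(d2)[which.min(d2)]
  stage1_pair <- names(sort(d2))[1:2]

  cand <- Filter(function(p) closest %in% p, adjacent_pairs)
  if (length(cand) > 1L) {
    sums <- vapply(cand, function(p) sum(d2[p]), numeric(1))
    # tie on summed distance: prefer the pair containing receptive
    if (sums[1] == sums[2]) {
      cand <- Filter(function(p) "receptive" %in% p, cand)
      if (length(cand) > 1L) cand <- cand[1]
    } else {
      cand <- cand[which.min(sums)]
    }
  }
  pair <- cand[[1]]
  rp <- relative_probability(d2[pair[1]], d2[pair[2]])
  names(rp) <- pair
  leading <- pair[which.max(rp)]
  p_lead <- max(rp)
  lo <- model$boundaries[1]; hi <- model$boundaries[2]
  final <- if (p_lead >= hi) {
    leading
  } else {
    unname(transitionary_of[paste(pair, collapse = "|")])
  }
  list(d2 = d2, outlier_p = op$p, is_outlier = op$is_outlier,
       overall_outlier = all(op$is_outlier), stage1_pair = stage1_pair,
       stage2_pair = pair, rel_prob = rp, leading_class = leading,
       final_class = final)
}

#' Classify samples into the five receptivity classes
#'
#' Projects each sample with the model's normalisation, scaling and
#' eigenvectors, computes squared Mahalanobis distances to the three
#' reference centroids with the pooled within-class covariance, gates each
#' distance through the chi-square outlier rule, and runs the two-stage
#' hierarchical decision: the closest reference class selects the temporally
#' adjacent pair with the smaller summed distance, the Gaussian-kernel
#' relative probability is computed within that pair, and the final call is
#' the pair's leading class when its relative probability reaches the upper
#' boundary, or the transitionary class between the pair (early-receptive for
#' pre/receptive, late-receptive for receptive/post) otherwise. Exactly one
#' final class is reported per sample.
#'
#' @param m a [count_matrix()] of one or more samples containing every model
#'   gene.
#' @param model a fitted [fit_reference()] model.
#' @return a list of `classification_result` objects (one per QC-passing
#'   sample), each with fields `sample_id`, `scores`, `d2`, `outlier_p`,
#'   `is_outlier`, `overall_outlier`, `stage1_pair`, `stage2_pair`,
#'   `rel_prob`, `leading_class`, `final_class` and `thresholds`. Samples
#'   failing housekeeper QC are dropped with a warning. For a single sample
#'   the result is returned directly.
#' @export
classify <- function(m, model) {
  pr <- project_counts(m, model)
  res <- lapply(seq_len(nrow(pr$scores)), function(i) {
    x <- pr$scores[i, ]
    d2 <- vapply(model$class_order, function(cl) {
      mahalanobis_sq(x, model$centroids[cl, ], model$within_cov_inv)
    }, numeric(1))
    out <- classify_scores(d2, model)
    out$sample_id <- rownames(pr$scores)[i]
    out$scores <- x
    out$thresholds <- list(boundaries = model$boundaries,
                           outlier_alpha = model$outlier_alpha,
                           outlier_tail = model$outlier_tail)
    class(out) <- "classification_result"
    out
  })
  names(res) <- rownames(pr$scores)
  if (length(res) == 1L) res[[1]] else res
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("sample %s -> %s\n", x$sample_id, x$final_class))
  cat(sprintf("  d2: %s\n", paste(sprintf("%s=%.3f", names(x$d2), x$d2),
                                  collapse = " ")))
  cat(sprintf("  pair %s vs %s: P(%s) = %.3f%s\n",
              x$stage2_pair[1], x$stage2_pair[2], x$leading_class,
              max(x$rel_prob),
              if (x$overall_outlier) "  [outlier - interpret with caution]"
              else ""))
  invisible(x)
}

#' Tabular classification report
#'
#' Flattens [classify()] output into one row per sample for TSV export.
#'
#' @param results a `classification_result` or list of them.
#' @return data frame with distances, outlier p-values, the compared pair,
#'   relative probability of its leading class, and the final class.
#' @export
classification_report <- function(results) {
  if (inherits(results, "classification_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      sample_id = r$sample_id,
      d2_pre = unname(r$d2["pre-receptive"]),
      d2_receptive = unname(r$d2["receptive"]),
      d2_post = unname(r$d2["post-receptive"]),
      p_outlier_pre = unname(r$outlier_p["pre-receptive"]),
      p_outlier_receptive = unname(r$outlier_p["receptive"]),
      p_outlier_post = unname(r$outlier_p["post-receptive"]),
      pair = paste(r$stage2_pair, collapse = "|"),
      leading_class = r$leading_class,
      rel_prob_leading = max(r$rel_prob),
      outlier = r$overall_outlier,
      final_class = r$final_class,
      stringsAsFactors = FALSE
    )
  }))
}
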