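#' Normalised expression matrix
#'
#' Internal container for housekeeper-normalised expression values. Carries a
#' transform-state flag that only moves forward along
#' `linear -> shifted-log -> scaled`; mixing transform orders is an error.
#' The raw `count_matrix` is never modified.
#'
#' @name normalized_matrix
#' @keywords internal
NULL

new_normalized <- function(values, housekeeper_ids, state,
                           sample_meta = NULL) {
  structure(list(values = values, housekeeper_ids = housekeeper_ids,
                 state = state, sample_meta = sample_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d samples x %d genes [state: %s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Normalise molecule counts by the housekeeper geometric mean
#'
#' Divides every sample row by the geometric mean of that sample's
#' housekeeper molecule counts, removing library-size effects: scaling a whole
#' sample row by any constant `c > 0` leaves its normalised values unchanged.
#' The geometric mean is computed in log space. A sample with a zero count in
#' any housekeeper indicates assay failure; such samples are excluded from the
#' output with a warning (no pseudocount is applied), and their ids are
#' recorded in the `qc_failed` attribute.
#'
#' @param m a [count_matrix()].
#' @param housekeeper_ids gene ids to use as housekeepers; all must be present
#'   in `m`.
#' @return a `normalized_matrix` in the `linear` state. Per sample, the
#'   geometric mean of the normalised housekeeper values is exactly 1.
#' @examples
#' m <- count_matrix(matrix(c(10L, 10L, 50L), 1,
#'                   dimnames = list("s1", c("hk1", "hk2", "g"))))
#' normalize_housekeepers(m, c("hk1", "hk2"))$values
#' @export
normalize_housekeepers <- function(m, housekeeper_ids) {
  stopifnot(inherits(m, "count_matrix"))
  housekeeper_ids <- as.character(housekeeper_ids)
  if (length(housekeeper_ids) == 0L) {
    stop("at least one housekeeper is required for normalisation",
         call. = FALSE)
  }
  miss <- setdiff(housekeeper_ids, colnames(m$counts))
  if (length(miss)) {
    stop("housekeeper(s) absent from count matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hk <- m$counts[, housekeeper_ids, drop = FALSE]
  fail <- rowSums(hk == 0L) > 0L
  if (any(fail)) {
    warning("excluding sample(s) with a zero housekeeper count (QC fail): ",
            paste(rownames(m$counts)[fail], collapse = ", "), call. = FALSE)
  }
  keep <- !fail
  if (!any(keep)) stop("all samples failed housekeeper QC", call. = FALSE)
  geo <- exp(rowMeans(log(hk[keep, , drop = FALSE])))
  values <- m$counts[keep, , drop = FALSE] / geo
  out <- new_normalized(values, housekeeper_ids, "linear",
                        sample_meta = m$sample_meta[keep, , drop = FALSE])
  attr(out, "qc_failed") <- rownames(m$counts)[fail]
  out
}

#' Shifted logarithm transform
#'
#' Elementwise `x -> ln(x + shift)`, used on normalised values before
#' statistical testing. Requires non-negative input in the `linear` state.
#'
#' @param m a `normalized_matrix` (state `linear`).
#' @param shift shift constant added before the log (default 1, so zeros map
#'   to zero).
#' @return the matrix in the `shifted-log` state.
#' @export
shifted_log <- function(m, shift = 1.0) {
  stopifnot(inherits(m, "normalized_matrix"))
  if (m$state != "linear") {
    stop("shifted_log expects a matrix in the 'linear' state, got '",
         m$state, "'", call. = FALSE)
  }
  if (any(m$values < 0)) stop("negative values: normalise before the log",
                              call. = FALSE)
  m$values <- log(m$values + shift)
  m$state <- "shifted-log"
  m
}

#' Per-gene scaling (z-score) parameters
#'
#' [fit_scaling()] learns per-gene centre (mean) and scale (standard
#' deviation) on a development set; [apply_scaling()] applies them to any
#' matrix — test samples are always scaled with the development parameters,
#' never their own. Genes with zero variance in the development set are
#' dropped and listed in the returned parameters.
#'
#' @param dev a `normalized_matrix` with at least 2 samples.
#' @return [fit_scaling()] returns a `scaling_params` object with fields
#'   `center`, `scale` (named, dropped genes removed) and `dropped`.
#' @export
fit_scaling <- function(dev) {
  stopifnot(inherits(dev, "normalized_matrix"))
  if (nrow(dev$values) < 2L) stop("need >= 2 samples to fit scaling",
                                  call. = FALSE)
  center <- colMeans(dev$values)
  scale <- apply(dev$values, 2L, stats::sd)
  # relative tolerance: a gene constant up to floating-point noise (e.g. a
  # lone housekeeper after exp(log(x)) normalisation) is still zero-variance
  dropped <- names(scale)[scale <= 1e-10 * pmax(abs(center), 1)]
  keep <- setdiff(names(scale), dropped)
  structure(list(center = center[keep], scale = scale[keep],
                 dropped = dropped),
            class = "scaling_params")
}

#' @param m a `normalized_matrix` to scale (states `linear` or `shifted-log`).
#' @param params a `scaling_params` from [fit_scaling()].
#' @rdname fit_scaling
#' @export
apply_scaling <- function(m, params) {
  stopifnot(inherits(m, "normalized_matrix"),
            inherits(params, "scaling_params"))
  if (m$state == "scaled") stop("matrix is already scaled", call. = FALSE)
  miss <- setdiff(names(params$center), colnames(m$values))
  if (length(miss)) {
    stop("gene(s) required by scaling parameters absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- m$values[, names(params$center), drop = FALSE]
  v <- sweep(v, 2L, params$center, "-")
  v <- sweep(v, 2L, params$scale, "/")
  m$values <- v
  m$state <- "scaled"
  m
}
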