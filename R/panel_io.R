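#' Probe panel definition
#'
#' A probe panel describes the targets of a ligation-probe expression assay:
#' one fixed-length target sequence per gene, with a flag marking the
#' housekeeper genes whose geometric mean is used for normalisation.
#'
#' @param target_id character vector of unique gene symbols.
#' @param target_seq character vector of uppercase DNA sequences (A/C/G/T),
#'   all of the same length.
#' @param is_housekeeper logical vector.
#' @return An object of class `probe_panel` (a data frame with the three
#'   columns above).
#' @examples
#' probe_panel(c("SDHA", "OGT"), c("ACGTACGT", "TTGCAGCA"), c(TRUE, FALSE))
#' @export
probe_panel <- function(target_id, target_seq, is_housekeeper) {
  df <- data.frame(
    target_id = as.character(target_id),
    target_seq = toupper(as.character(target_seq)),
    is_housekeeper = as.logical(is_housekeeper),
    stringsAsFactors = FALSE
  )
  validate_panel(df)
}

validate_panel <- function(df) {
  if (nrow(df) == 0L) stop("panel has zero targets", call. = FALSE)
  dup <- unique(df$target_id[duplicated(df$target_id)])
  if (length(dup)) {
    stop("duplicate target_id in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$target_seq))) {
    bad <- df$target_id[!nzchar(df$target_seq)]
    stop("empty target_seq for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lens <- nchar(df$target_seq)
  if (length(unique(lens)) != 1L) {
    tab <- split(df$target_id, lens)
    stop("ragged target_seq lengths in panel (",
         paste(vapply(names(tab), function(l) {
           paste0("length ", l, ": ", paste(head(tab[[l]], 3), collapse = ","))
         }, character(1)), collapse = "; "), ")", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", df$target_seq))) {
    bad <- df$target_id[grepl("[^ACGTN]", df$target_seq)]
    stop("non-ACGTN characters in target_seq for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$is_housekeeper)) stop("is_housekeeper must be TRUE/FALSE",
                                     call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("probe_panel", "data.frame")
  df
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel: %d targets (%d housekeepers), target length %d nt\n",
              nrow(x), sum(x$is_housekeeper), nchar(x$target_seq[1])))
  invisible(x)
}

#' Housekeeper gene ids of a panel
#' @param panel a [probe_panel()].
#' @return character vector of housekeeper target ids.
#' @export
housekeepers <- function(panel) {
  stopifnot(inherits(panel, "probe_panel"))
  panel$target_id[panel$is_housekeeper]
}

#' Read / write a probe panel TSV
#'
#' The panel format is a tab-separated file with columns `target_id`,
#' `target_seq` and `is_housekeeper` (logical, `TRUE`/`FALSE` or 0/1).
#'
#' @param path file path.
#' @return [read_panel()] returns a validated `probe_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("target_id", "target_seq", "is_housekeeper")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$is_housekeeper <- as.logical(utils::type.convert(df$is_housekeeper,
                                                      as.is = TRUE))
  validate_panel(df[need])
}

#' @param panel a `probe_panel`.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read layout of a targeted-assay sequencing read
#'
#' Positions within a read are 0-based half-open. The default layout places
#' one UMI on each side of the ligated target region
#' (`[UMI][target][UMI]`), matching a 2 x 4 bp UMI design; the molecule key is
#' the concatenation of both UMI segments.
#'
#' @param target_len length of the panel target sequences (nt).
#' @param umi_len_each nucleotides per UMI segment (default 4).
#' @param umi_count number of UMI segments, 1 or 2.
#' @return object of class `read_layout` with fields `umi_len_each`,
#'   `umi_count`, `target_region` (0-based half-open `c(start, end)`) and
#'   `umi_regions` (list of 0-based half-open intervals).
#' @export
read_layout <- function(target_len, umi_len_each = 4L, umi_count = 2L) {
  umi_len_each <- as.integer(umi_len_each)
  umi_count <- as.integer(umi_count)
  target_len <- as.integer(target_len)
  if (umi_len_each < 1L) stop("umi_len_each must be >= 1", call. = FALSE)
  if (!umi_count %in% c(1L, 2L)) stop("umi_count must be 1 or 2",
                                      call. = FALSE)
  if (target_len < 1L) stop("target_len must be >= 1", call. = FALSE)
  tr <- c(umi_len_each, umi_len_each + target_len)
  umis <- list(c(0L, umi_len_each))
  if (umi_count == 2L) {
    umis <- c(umis, list(c(tr[2], tr[2] + umi_len_each)))
  }
  structure(
    list(umi_len_each = umi_len_each, umi_count = umi_count,
         target_region = tr, umi_regions = umis,
         read_len = tr[2] + if (umi_count == 2L) umi_len_each else 0L),
    class = "read_layout"
  )
}

#' Sample-by-gene molecule count matrix
#'
#' Container for UMI-corrected molecule counts plus per-sample metadata
#' (menstrual-cycle phase label and cohort tag). Counts are non-negative
#' integers; normalisation never modifies this object.
#'
#' @param counts non-negative integer matrix, samples in rows (rownames =
#'   sample ids), genes in columns (colnames = gene ids).
#' @param phase per-sample phase label in `PE`, `ESE`, `MSE`, `LSE`; anything
#'   else is stored as `"unknown"` with a warning.
#' @param cohort per-sample cohort tag (e.g. `MD`, `MV`, `RIF`, `synthetic`).
#' @return object of class `count_matrix` with fields `counts` and
#'   `sample_meta`.
#' @export
count_matrix <- function(counts, phase = NULL, cohort = "synthetic") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    stop("counts must have gene ids as colnames", call. = FALSE)
  }
  check_counts_integer(counts)
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (is.null(phase)) phase <- rep("unknown", n)
  phase <- as.character(phase)
  if (length(phase) != n) stop("phase must have one entry per sample",
                               call. = FALSE)
  bad <- !(phase %in% c(PHASE_LEVELS, "unknown"))
  if (any(bad)) {
    warning("unknown phase label(s) ",
            paste(unique(phase[bad]), collapse = ", "),
            " stored as \"unknown\"", call. = FALSE)
    phase[bad] <- "unknown"
  }
  cohort <- rep_len(as.character(cohort), n)
  structure(
    list(counts = counts,
         sample_meta = data.frame(sample_id = rownames(counts),
                                  phase = phase, cohort = cohort,
                                  stringsAsFactors = FALSE)),
    class = "count_matrix"
  )
}

check_counts_integer <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "invalid count %s for sample '%s', gene '%s' (counts must be non-negative integers)",
      format(counts[i, j]), rownames(counts)[i], colnames(counts)[j]),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  ph <- table(factor(x$sample_meta$phase,
                     levels = c(PHASE_LEVELS, "unknown")))
  cat(sprintf("count_matrix: %d samples x %d genes\n", nrow(x$counts),
              ncol(x$counts)))
  cat("phases:", paste(sprintf("%s=%d", names(ph), ph), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write a count matrix TSV
#'
#' Counts are stored as a tab-separated table whose first column is
#' `sample_id` and whose remaining columns are gene counts. Sample metadata
#' (columns `sample_id`, `phase`, `cohort`) travels in a companion TSV;
#' samples missing from the metadata get phase `"unknown"` with a warning.
#'
#' @param path counts TSV path.
#' @param meta_path optional metadata TSV path.
#' @return [read_counts()] returns a `count_matrix`;
#'   `write_counts` invisibly returns `path`.
#' @export
read_counts <- function(path, meta_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("counts TSV must start with a sample_id column", call. = FALSE)
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$sample_id
  check_counts_integer(counts)
  phase <- rep("unknown", nrow(counts))
  cohort <- rep("unknown", nrow(counts))
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    idx <- match(rownames(counts), meta$sample_id)
    if (anyNA(idx)) {
      warning("no metadata for sample(s) ",
              paste(rownames(counts)[is.na(idx)], collapse = ", "),
              "; phase set to \"unknown\"", call. = FALSE)
    }
    if ("phase" %in% names(meta)) {
      phase <- ifelse(is.na(idx), "unknown", meta$phase[idx])
    }
    if ("cohort" %in% names(meta)) {
      cohort <- ifelse(is.na(idx), "unknown", meta$cohort[idx])
    }
  }
  count_matrix(counts, phase = phase, cohort = cohort)
}

#' @param m a `count_matrix`.
#' @rdname read_counts
#' @export
write_counts <- function(m, path, meta_path = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(sample_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(m$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

MODEL_FORMAT <- "beready-model/1"

# Doubles are stored as 17-significant-digit decimal strings: that many
# digits round-trip IEEE-754 doubles exactly, which plain JSON numbers do not
# guarantee through every writer/parser, and a reloaded model must classify
# bit-identically.
ser_num <- function(x) sprintf("%.17g", x)
deser_num <- function(x) as.numeric(unlist(x, use.names = FALSE))

ser_matrix <- function(m) {
  list(dim = dim(m), rownames = rownames(m), colnames = colnames(m),
       data = ser_num(as.vector(m)))
}

deser_matrix <- function(x) {
  m <- matrix(deser_num(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
  rownames(m) <- unlist(x$rownames)
  colnames(m) <- unlist(x$colnames)
  m
}

#' Save / load a fitted reference model
#'
#' Models are serialised to a versioned, self-describing JSON file with
#' matrices embedded at full double precision, so a reloaded model reproduces
#' classification output bit-identically. Loading a file with a different
#' format version is an explicit error.
#'
#' @param model a fitted [reference_model][fit_reference].
#' @param path JSON file path.
#' @return [load_model()] returns the `reference_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  obj <- list(
    format = MODEL_FORMAT,
    k = model$k,
    genes = model$genes,
    housekeeper_ids = model$housekeeper_ids,
    class_order = model$class_order,
    label_map = as.list(model$label_map),
    log_before_scale = model$log_before_scale,
    shift = model$shift,
    scaling = list(genes = names(model$scaling$center),
                   center = ser_num(model$scaling$center),
                   scale = ser_num(model$scaling$scale),
                   dropped = model$scaling$dropped),
    rotation = ser_matrix(model$rotation),
    centroids = ser_matrix(model$centroids),
    within_cov = ser_matrix(model$within_cov),
    ridge = model$ridge,
    outlier_alpha = model$outlier_alpha,
    outlier_tail = model$outlier_tail,
    boundaries = model$boundaries,
    horn = model$horn
  )
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(obj$format) || !identical(obj$format, MODEL_FORMAT)) {
    stop("model file format '", if (is.null(obj$format)) "<missing>"
         else obj$format, "' does not match supported '", MODEL_FORMAT, "'",
         call. = FALSE)
  }
  sgenes <- as.character(unlist(obj$scaling$genes))
  model <- list(
    k = as.integer(obj$k),
    genes = unlist(obj$genes),
    housekeeper_ids = unlist(obj$housekeeper_ids),
    class_order = unlist(obj$class_order),
    label_map = unlist(obj$label_map),
    log_before_scale = isTRUE(obj$log_before_scale),
    shift = as.numeric(obj$shift),
    scaling = structure(
      list(center = stats::setNames(deser_num(obj$scaling$center), sgenes),
           scale = stats::setNames(deser_num(obj$scaling$scale), sgenes),
           dropped = as.character(unlist(obj$scaling$dropped))),
      class = "scaling_params"),
    rotation = deser_matrix(obj$rotation),
    centroids = deser_matrix(obj$centroids),
    within_cov = deser_matrix(obj$within_cov),
    ridge = as.numeric(obj$ridge),
    outlier_alpha = as.numeric(obj$outlier_alpha),
    outlier_tail = as.character(obj$outlier_tail),
    boundaries = as.numeric(unlist(obj$boundaries)),
    horn = lapply(obj$horn, function(x) unlist(x))
  )
  model$within_cov_inv <- solve(model$within_cov)
  class(model) <- "reference_model"
  model
}
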