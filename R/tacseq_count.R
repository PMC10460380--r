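#' Assign a single read to a panel target
#'
#' Computes the Hamming distance between the read's target region and every
#' panel target sequence and assigns the unique minimum-distance target when
#' that distance does not exceed `max_mismatches` (an inclusive bound: a read
#' at exactly `max_mismatches` is assigned). Ambiguous bases (`N`) count as
#' mismatches. A tie between two targets at the minimal distance is discarded
#' as ambiguous rather than broken arbitrarily.
#'
#' @param read_seq character DNA string.
#' @param panel a [probe_panel()].
#' @param layout a [read_layout()]; its target region must have the panel's
#'   target length.
#' @param max_mismatches maximum Hamming distance allowed (default 5).
#' @param read_id identifier carried into the result.
#' @return list with fields `read_id`, `target_id` (`NA` if unassigned),
#'   `mismatches`, `umi` (concatenated UMI segments, `NA` if unassigned) and
#'   `reason` (`"assigned"`, `"short"`, `"ambiguous"` or `"distant"`).
#' @examples
#' p <- synthetic_panel(n_biomarkers = 2, target_len = 12, seed = 1)
#' lay <- read_layout(target_len = 12)
#' read <- paste0("ACGT", p$target_seq[1], "TTTT")
#' assign_read(read, p, lay)
#' @export
assign_read <- function(read_seq, panel, layout, max_mismatches = 5L,
                        read_id = "read") {
  res <- assign_reads(read_seq, panel, layout, max_mismatches,
                      read_ids = read_id)
  lapply(res, `[[`, 1L)
}

# Vectorised core: reads -> per-read target assignment.
# Returns list(read_id, target_id, mismatches, umi, reason), each length n.
assign_reads <- function(reads, panel, layout, max_mismatches = 5L,
                         read_ids = NULL) {
  stopifnot(inherits(panel, "probe_panel"), inherits(layout, "read_layout"))
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  tlen <- nchar(panel$target_seq[1])
  if (diff(layout$target_region) != tlen) {
    stop("layout target region length (", diff(layout$target_region),
         ") does not match panel target length (", tlen, ")", call. = FALSE)
  }
  n <- length(reads)
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(n))
  reads <- toupper(reads)
  target_id <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  umi <- rep(NA_character_, n)
  reason <- rep("short", n)

  min_len <- max(layout$target_region[2],
                 vapply(layout$umi_regions, `[`, integer(1), 2L))
  ok <- nchar(reads) >= min_len
  if (any(ok)) {
    region <- substr(reads[ok], layout$target_region[1] + 1L,
                     layout$target_region[2])
    # character matrix tlen x n_ok; distance to each target by column sums
    rm <- matrix(unlist(strsplit(region, "", fixed = TRUE)), nrow = tlen)
    dist <- matrix(0L, nrow = sum(ok), ncol = nrow(panel),
                   dimnames = list(NULL, panel$target_id))
    for (j in seq_len(nrow(panel))) {
      tchars <- strsplit(panel$target_seq[j], "", fixed = TRUE)[[1]]
      dist[, j] <- as.integer(colSums(rm != tchars))
    }
    dmin <- do.call(pmin, as.data.frame(dist))
    n_at_min <- rowSums(dist == dmin)
    best <- max.col(-dist, ties.method = "first")
    idx <- which(ok)
    assigned <- dmin <= max_mismatches & n_at_min == 1L
    reason[idx] <- ifelse(dmin > max_mismatches, "distant",
                          ifelse(n_at_min > 1L, "ambiguous", "assigned"))
    target_id[idx[assigned]] <- panel$target_id[best[assigned]]
    mismatches[idx[assigned]] <- dmin[assigned]
    umis <- vapply(layout$umi_regions, function(r) {
      substr(reads[ok], r[1] + 1L, r[2])
    }, character(sum(ok)))
    if (is.null(dim(umis))) umis <- matrix(umis, nrow = sum(ok))
    umi[idx[assigned]] <- apply(umis, 1L, paste0,
                                collapse = "")[assigned]
  }
  list(read_id = read_ids, target_id = target_id, mismatches = mismatches,
       umi = umi, reason = reason)
}

#' Count UMI-deduplicated molecules from targeted-assay reads
#'
#' Assigns every read to a panel target (see [assign_read()]), groups
#' assigned reads by (target, UMI), and reports as the molecule count of a
#' target the number of distinct UMIs supported by at least
#' `umi_read_threshold` reads. With the default threshold of 1, every distinct
#' UMI observed for a target contributes one molecule, which collapses PCR
#' duplicates while keeping singletons.
#'
#' @param fastq path to a FASTQ file (plain or gzip), or a character vector of
#'   read sequences.
#' @param panel a [probe_panel()].
#' @param layout a [read_layout()]; defaults to the two-sided 4 nt UMI layout
#'   for the panel's target length.
#' @param max_mismatches inclusive Hamming-distance bound (default 5).
#' @param umi_read_threshold minimum reads supporting a UMI for it to count as
#'   a molecule (default 1). Raising it can only lower molecule counts.
#' @param sample_id sample name for the output row.
#' @return list with fields
#'   `counts` — a single-sample [count_matrix()] over all panel targets;
#'   `umi_table` — per target, a table `umi -> supporting reads`;
#'   `qc` — list with `total_reads`, `assigned_reads`, `assigned_fraction`,
#'   `unassigned` (reads by reason), `total_molecules`,
#'   `duplication_rate` (assigned reads per molecule) and `umi_per_target`.
#' @export
count_reads <- function(fastq, panel, layout = NULL, max_mismatches = 5L,
                        umi_read_threshold = 1L, sample_id = "sample") {
  stopifnot(inherits(panel, "probe_panel"))
  if (is.null(layout)) layout <- read_layout(nchar(panel$target_seq[1]))
  if (umi_read_threshold < 1L) stop("umi_read_threshold must be >= 1",
                                    call. = FALSE)
  if (length(fastq) == 1L && file.exists(fastq)) {
    reads <- read_fastq_seqs(fastq)
  } else {
    reads <- as.character(fastq)
  }
  n <- length(reads)
  counts <- matrix(0L, nrow = 1L, ncol = nrow(panel),
                   dimnames = list(sample_id, panel$target_id))
  umi_table <- stats::setNames(vector("list", nrow(panel)), panel$target_id)
  if (n == 0L) {
    warning("no reads in input; returning all-zero counts", call. = FALSE)
    asg <- list(target_id = character(0), umi = character(0),
                reason = character(0))
  } else {
    asg <- assign_reads(reads, panel, layout, max_mismatches)
  }
  keep <- !is.na(asg$target_id)
  if (any(keep)) {
    by_target <- split(asg$umi[keep], asg$target_id[keep])
    for (tid in names(by_target)) {
      support <- table(by_target[[tid]])
      umi_table[[tid]] <- support
      counts[1L, tid] <- sum(support >= umi_read_threshold)
    }
  }
  n_assigned <- sum(keep)
  n_mol <- sum(counts)
  qc <- list(
    total_reads = n,
    assigned_reads = n_assigned,
    assigned_fraction = if (n > 0L) n_assigned / n else NA_real_,
    unassigned = table(asg$reason[!keep]),
    total_molecules = n_mol,
    duplication_rate = if (n_mol > 0L) n_assigned / n_mol else NA_real_,
    umi_per_target = counts[1L, ]
  )
  list(counts = count_matrix(counts), umi_table = umi_table, qc = qc)
}

# FASTQ -> character vector of read sequences (plain or gzipped file).
# Parsing is delegated to Biostrings; malformed records are reported with the
# parser's message and the file name.
read_fastq_seqs <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", use.names = FALSE),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  as.character(seqs)
}
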