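#' Synthetic probe panel
#'
#' Builds a panel with the four housekeepers (SDHA, CYC1, TBP, HMBS), the
#' eleven named WOI-related genes (CAMK2D, CAAP1, FOXN2, GGNBP2, ICA1L,
#' LEFTY1, OGT, PPIP5K2, RIC3, TPM2, YARS2) and `n_biomarkers` placeholder
#' receptivity biomarkers (`BM01`, `BM02`, ...; the published biomarker
#' identities are a user input, not shipped). Target sequences are random
#' fixed-length DNA drawn from `seed`, so any two targets are far apart in
#' Hamming distance with overwhelming probability.
#'
#' @param n_biomarkers number of placeholder biomarker genes (default 57, for
#'   a 72-gene panel).
#' @param target_len target sequence length in nt (default 50).
#' @param seed integer seed for the sequence draw.
#' @return a [probe_panel()].
#' @export
synthetic_panel <- function(n_biomarkers = 57L, target_len = 50L, seed = 1L) {
  hk <- c("SDHA", "CYC1", "TBP", "HMBS")
  woi <- c("CAMK2D", "CAAP1", "FOXN2", "GGNBP2", "ICA1L", "LEFTY1", "OGT",
           "PPIP5K2", "RIC3", "TPM2", "YARS2")
  bm <- if (n_biomarkers > 0L) sprintf("BM%02d", seq_len(n_biomarkers))
        else character(0)
  ids <- c(hk, woi, bm)
  seqs <- with_seed(seed, {
    vapply(seq_along(ids), function(i) {
      paste0(sample(c("A", "C", "G", "T"), target_len, replace = TRUE),
             collapse = "")
    }, character(1))
  })
  probe_panel(ids, seqs, ids %in% hk)
}

#' Simulation configuration for phase-structured panel counts
#'
#' Defines the generative model for synthetic receptivity data: per-gene,
#' per-phase expected molecule counts (housekeepers constant across phases),
#' negative-binomial overdispersion, a log-normal per-sample library-size
#' factor, and read-level noise parameters for the FASTQ simulator.
#'
#' @param panel a [probe_panel()].
#' @param n_per_phase named integer vector over `PE`, `ESE`, `MSE`, `LSE`.
#' @param phase_means genes x 4 matrix of expected molecule counts (columns
#'   `PE`,`ESE`,`MSE`,`LSE`); housekeeper rows must be phase-constant.
#' @param dispersion per-gene negative-binomial size parameter (recycled);
#'   `Inf` gives the Poisson limit.
#' @param libsize_sigma log-normal sd of the per-sample scaling factor.
#' @param read_sim list with `mean_reads_per_molecule`, `per_base_error_rate`.
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(panel, n_per_phase, phase_means,
                              dispersion = 20, libsize_sigma = 0.35,
                              read_sim = list(mean_reads_per_molecule = 5,
                                              per_base_error_rate = 0.002),
                              seed = 1L) {
  stopifnot(inherits(panel, "probe_panel"))
  n_per_phase <- n_per_phase[PHASE_LEVELS]
  if (anyNA(n_per_phase)) stop("n_per_phase must name all of ",
                               paste(PHASE_LEVELS, collapse = "/"),
                               call. = FALSE)
  phase_means <- as.matrix(phase_means)[, PHASE_LEVELS, drop = FALSE]
  if (nrow(phase_means) != nrow(panel)) {
    stop("phase_means must have one row per panel target", call. = FALSE)
  }
  rownames(phase_means) <- panel$target_id
  hk <- panel$is_housekeeper
  if (any(phase_means[hk, ] <= 0)) stop("housekeeper means must be > 0",
                                        call. = FALSE)
  hk_ratio <- apply(phase_means[hk, , drop = FALSE], 1L,
                    function(r) max(r) / min(r))
  if (any(hk_ratio != 1)) {
    stop("housekeeper means must be constant across phases", call. = FALSE)
  }
  dispersion <- rep_len(dispersion, nrow(panel))
  if (any(dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (libsize_sigma < 0) stop("libsize_sigma must be >= 0", call. = FALSE)
  structure(list(panel = panel, n_per_phase = n_per_phase,
                 phase_means = phase_means, dispersion = dispersion,
                 libsize_sigma = libsize_sigma, read_sim = read_sim,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default configuration emulating a model-development cohort
#'
#' A 72-gene panel with phase sample sizes (PE 18, ESE 18, MSE 17, LSE 10)
#' matching a typical natural-cycle development cohort. Biomarker expression
#' follows a 3-latent-factor structure on the log scale: a temporal factor
#' tracing the cycle (PE and ESE close together on the pre-receptive side,
#' MSE and LSE well apart), plus two weaker shape factors, so the phase
#' groups separate in a few principal components (well beyond four pooled
#' standard deviations along the dominant factor) and Horn's analysis has a
#' genuine low-rank signal to detect. Housekeeper means are phase-constant
#' by construction. Counts are negative-binomial (size 20) with a log-normal
#' library-size factor (sigma 0.35).
#'
#' @param seed integer seed used for the panel, the latent loadings and the
#'   downstream count draw.
#' @return a [simulation_config()].
#' @export
default_md_like_config <- function(seed = 104L) {
  panel <- synthetic_panel(seed = seed)
  hk_means <- c(SDHA = 150, CYC1 = 300, TBP = 80, HMBS = 120)
  n_genes <- nrow(panel)
  hk <- panel$is_housekeeper
  # phase scores of the 3 latent factors (rows: factors, cols: phases)
  fscore <- rbind(
    temporal = c(PE = -1.2, ESE = -0.9, MSE = 0.3, LSE = 1.4),
    shape1   = c(PE = 0.6, ESE = 0.3, MSE = -0.7, LSE = 0.5),
    shape2   = c(PE = 0.1, ESE = -0.2, MSE = 0.3, LSE = -0.4)
  )
  phase_means <- with_seed(seed + 1L, {
    base <- stats::rlnorm(n_genes, meanlog = log(80), sdlog = 0.6)
    load <- cbind(stats::rnorm(n_genes, 0, 0.45),
                  stats::rnorm(n_genes, 0, 0.25),
                  stats::rnorm(n_genes, 0, 0.15))
    logmu <- log(base) + load %*% fscore
    mu <- exp(logmu)
    mu[hk, ] <- hk_means[panel$target_id[hk]]
    colnames(mu) <- PHASE_LEVELS
    mu
  })
  simulation_config(panel,
                    n_per_phase = c(PE = 18L, ESE = 18L, MSE = 17L,
                                    LSE = 10L),
                    phase_means = phase_means, seed = seed)
}

#' Simulate a phase-structured molecule count matrix
#'
#' Draws `count[s, g] ~ NegBin(mean = L_s * phase_mean[g, phase(s)],
#' size = dispersion_g)` with `L_s ~ LogNormal(0, libsize_sigma)`.
#' Deterministic given `cfg$seed`. Because housekeeper means are
#' phase-constant, housekeeper geometric-mean normalisation is the correct
#' de-noising for the library-size factor.
#'
#' @param cfg a [simulation_config()].
#' @return list with `counts` (a [count_matrix()] with phase labels, cohort
#'   `synthetic`) and `truth` (data frame with per-sample phase, reference
#'   class and library factor, plus the `phase_means` matrix).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  phases <- rep(PHASE_LEVELS, times = cfg$n_per_phase)
  n <- length(phases)
  genes <- cfg$panel$target_id
  with_seed(cfg$seed, {
    L <- if (cfg$libsize_sigma > 0)
           stats::rlnorm(n, 0, cfg$libsize_sigma) else rep(1, n)
    counts <- matrix(0L, n, length(genes),
                     dimnames = list(sprintf("sim%03d", seq_len(n)), genes))
    for (g in seq_along(genes)) {
      mu <- L * cfg$phase_means[g, phases]
      counts[, g] <- if (is.infinite(cfg$dispersion[g])) {
        stats::rpois(n, lambda = mu)
      } else {
        stats::rnbinom(n, mu = mu, size = cfg$dispersion[g])
      }
    }
    m <- count_matrix(counts, phase = phases, cohort = "synthetic")
    truth <- data.frame(sample_id = rownames(counts), phase = phases,
                        class = unname(PHASE_TO_CLASS[phases]),
                        libsize_factor = L, stringsAsFactors = FALSE)
    list(counts = m, truth = truth, phase_means = cfg$phase_means)
  })
}

#' Simulate UMI-tagged reads for one sample
#'
#' Emits a FASTQ read stream from known molecule counts: each true molecule
#' draws a UMI uniformly over all `4^(2*umi_len)` combined tags and a PCR
#' duplicate count (geometric on `{1, 2, ...}` with the configured mean), and
#' every read is `[UMI1][target][UMI2]` with independent per-base
#' substitution errors over the target region. UMI segments are emitted
#' error-free: a substituted UMI base would mint a phantom molecule and
#' silently break the ground-truth accounting, whereas target-region errors
#' exercise the mismatch-tolerant assignment the way sequencing noise does.
#' Read headers carry `gene:molecule:umi` ground-truth
#' tags so counting can be checked read-by-read. If any gene's molecule count
#' is high enough that the birthday-bound UMI collision probability exceeds
#' 1%, a warning is issued (collisions deflate recovered counts).
#'
#' @param mol_counts named integer vector of true molecule counts per gene
#'   (names must be panel target ids), or a single-sample [count_matrix()].
#' @param panel a [probe_panel()].
#' @param layout a [read_layout()] (default: two-sided 4 nt UMIs).
#' @param mean_reads_per_molecule mean PCR duplicate count (>= 1).
#' @param per_base_error_rate substitution probability per sequenced base.
#' @param seed integer seed.
#' @param path optional file path; when given, reads are written as FASTQ
#'   (gzipped if the path ends in `.gz`) and the path is returned in the
#'   result.
#' @return list with `fastq` (character vector of FASTQ lines), `truth`
#'   (data frame gene/molecule/umi per emitted molecule), `n_reads`, and
#'   `path` if written.
#' @export
simulate_reads <- function(mol_counts, panel, layout = NULL,
                           mean_reads_per_molecule = 5,
                           per_base_error_rate = 0.002,
                           seed = 1L, path = NULL) {
  stopifnot(inherits(panel, "probe_panel"))
  if (inherits(mol_counts, "count_matrix")) {
    stopifnot(nrow(mol_counts$counts) == 1L)
    mol_counts <- mol_counts$counts[1L, ]
  }
  if (is.null(layout)) layout <- read_layout(nchar(panel$target_seq[1]))
  if (mean_reads_per_molecule < 1) {
    stop("mean_reads_per_molecule must be >= 1", call. = FALSE)
  }
  genes <- names(mol_counts)
  bad <- setdiff(genes, panel$target_id)
  if (length(bad)) stop("unknown gene(s) in mol_counts: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  umi_bits <- layout$umi_count * layout$umi_len_each
  n_umis <- 4^umi_bits
  coll <- mol_counts * (mol_counts - 1) / 2 / n_umis
  if (any(coll > 0.01)) {
    warning("UMI collision probability exceeds 1% (birthday bound) for: ",
            paste(genes[coll > 0.01], collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    recs <- list(); truth <- list()
    for (g in genes[mol_counts > 0]) {
      m <- mol_counts[[g]]
      tseq <- panel$target_seq[panel$target_id == g]
      umis <- vapply(seq_len(m), function(i) {
        paste0(sample(bases, umi_bits, replace = TRUE), collapse = "")
      }, character(1))
      dups <- 1L + stats::rgeom(m, prob = 1 / mean_reads_per_molecule)
      tmpl <- if (layout$umi_count == 2L) {
        paste0(substr(umis, 1L, layout$umi_len_each), tseq,
               substr(umis, layout$umi_len_each + 1L, umi_bits))
      } else {
        paste0(umis, tseq)
      }
      reads <- rep(tmpl, dups)
      mol_idx <- rep(seq_len(m), dups)
      if (per_base_error_rate > 0 && length(reads)) {
        # substitution errors confined to the target region (see docs)
        tlen <- diff(layout$target_region)
        n_err <- stats::rbinom(length(reads), tlen, per_base_error_rate)
        for (i in which(n_err > 0L)) {
          pos <- layout$target_region[1] + sample.int(tlen, n_err[i])
          ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
          for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
          reads[i] <- paste0(ch, collapse = "")
        }
      }
      hdr <- sprintf("@%s:%d:%s", g, mol_idx, umis[mol_idx])
      qual <- strrep("I", nchar(reads))
      recs[[g]] <- as.vector(rbind(hdr, reads, "+", qual))
      truth[[g]] <- data.frame(gene = g, molecule = seq_len(m), umi = umis,
                               n_reads = dups, stringsAsFactors = FALSE)
    }
    fastq <- unlist(recs, use.names = FALSE)
    if (is.null(fastq)) fastq <- character(0)
    truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
             else data.frame(gene = character(0), molecule = integer(0),
                             umi = character(0), n_reads = integer(0))
    out <- list(fastq = fastq, truth = truth,
                n_reads = length(fastq) / 4L)
    if (!is.null(path)) {
      con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
      writeLines(fastq, con)
      close(con)
      out$path <- path
    }
    out
  })
}
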