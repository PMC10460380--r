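# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's own code paths.

# small panel with explicit ids; first `n_hk` ids are housekeepers
make_panel <- function(ids, target_len = 20L, seed = 42L, n_hk = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_along(ids), function(i) {
    paste0(sample(c("A", "C", "G", "T"), target_len, replace = TRUE),
           collapse = "")
  }, character(1))
  probe_panel(ids, seqs, seq_along(ids) <= n_hk)
}

# substitute a different base at 1-based positions
mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste0(ch, collapse = "")
}

# wrap a target region into a full read under the default 2-sided UMI layout
make_read <- function(target_region, umi1 = "ACGT", umi2 = "TTTT") {
  paste0(umi1, target_region, umi2)
}

# exhaustive read-by-read, target-by-target scoring oracle for count_reads
oracle_count <- function(reads, panel, layout, max_mismatches = 5L,
                         umi_read_threshold = 1L) {
  tlen <- nchar(panel$target_seq[1])
  umi_map <- list()
  for (r in reads) {
    if (nchar(r) < layout$umi_len_each * layout$umi_count + tlen) next
    region <- substr(r, layout$target_region[1] + 1L,
                     layout$target_region[2])
    dists <- vapply(panel$target_seq, function(t) {
      sum(strsplit(region, "")[[1]] != strsplit(t, "")[[1]])
    }, numeric(1))
    dmin <- min(dists)
    if (dmin > max_mismatches || sum(dists == dmin) > 1L) next
    tid <- panel$target_id[which.min(dists)]
    umi <- paste0(vapply(layout$umi_regions, function(u) {
      substr(r, u[1] + 1L, u[2])
    }, character(1)), collapse = "")
    key <- paste(tid, umi, sep = "/")
    umi_map[[key]] <- (umi_map[[key]] %||% 0L) + 1L
  }
  counts <- setNames(integer(nrow(panel)), panel$target_id)
  for (key in names(umi_map)) {
    if (umi_map[[key]] >= umi_read_threshold) {
      tid <- sub("/.*", "", key)
      counts[tid] <- counts[tid] + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_one <- function(m, i) {
  count_matrix(m$counts[i, , drop = FALSE], phase = m$sample_meta$phase[i])
}

# explicit double-loop quadratic form oracle for the Mahalanobis distance
oracle_mahalanobis_sq <- function(x, centroid, cov) {
  cov_inv <- solve(cov)
  d <- x - centroid
  total <- 0
  for (i in seq_along(d)) {
    for (j in seq_along(d)) {
      total <- total + d[i] * cov_inv[i, j] * d[j]
    }
  }
  total
}

# hypergeometric enumeration oracle for the lower-tailed Fisher test,
# built from binomial coefficients only
oracle_fisher_lower <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  sum(probs[(lo:hi) <= a])
}

# small labelled count matrix with three well-separated phase clusters
make_separated_counts <- function(n_per_phase = c(PE = 7, ESE = 7, MSE = 7,
                                                  LSE = 7),
                                  seed = 1L) {
  panel <- synthetic_panel(n_biomarkers = 10, target_len = 20, seed = seed)
  means <- matrix(rep(c(SDHA = 100, CYC1 = 100, TBP = 100, HMBS = 100,
                        rep(50, nrow(panel) - 4)), 4),
                  nrow = nrow(panel),
                  dimnames = list(panel$target_id,
                                  c("PE", "ESE", "MSE", "LSE")))
  # strong monotone gradient on the biomarkers only
  bm <- !panel$is_housekeeper
  means[bm, "PE"] <- means[bm, "PE"] * 0.25
  means[bm, "ESE"] <- means[bm, "ESE"] * 0.35
  means[bm, "MSE"] <- means[bm, "MSE"] * 1.0
  means[bm, "LSE"] <- means[bm, "LSE"] * 3.5
  cfg <- simulation_config(panel, n_per_phase = n_per_phase,
                           phase_means = means, dispersion = 50,
                           libsize_sigma = 0.2, seed = seed)
  list(cfg = cfg, sim = simulate_counts(cfg), panel = panel)
}
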