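# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately naive (enumeration / direct transcription) and independent of
# the package's computation paths.

# --- container builders -----------------------------------------------------

# haplotype_set from a sites x haplotypes 0/1 matrix (two haplotypes per
# sample, in order); populations assigns each SAMPLE a population
toy_hapset <- function(hap, pos = seq_len(nrow(hap)) * 100L,
                       populations = NULL, chrom = "chr1",
                       chrom_len = NULL) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  n_samp <- ncol(hap) / 2L
  samples <- sprintf("s%02d", seq_len(n_samp))
  if (is.null(populations)) populations <- rep("pop1", n_samp)
  pops <- stats::setNames(populations, samples)
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = "A", alt = "T")
  sweepscan:::new_haplotype_set(hap, sites, samples, pops,
                                if (is.null(chrom_len)) NULL
                                else stats::setNames(chrom_len, chrom))
}

toy_gset <- function(dosage, pos = seq_len(nrow(dosage)) * 100L,
                     populations = NULL, chrom = "chr1", chrom_len = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  colnames(dosage) <- samples
  if (is.null(populations)) populations <- rep("pop1", ncol(dosage))
  pops <- stats::setNames(populations, samples)
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          ref = "A", alt = "T")
  sweepscan:::new_genotype_set(dosage, sites, samples, pops,
                               if (is.null(chrom_len)) NULL
                               else stats::setNames(chrom_len, chrom))
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# --- oracles ----------------------------------------------------------------

# mean pairwise Hamming distance between haplotypes over all C(n,2) pairs,
# divided by window length
oracle_pi <- function(hapmat, L) {
  n <- ncol(hapmat)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(hapmat[, i] != hapmat[, j])
    }
  }
  tot / choose(n, 2) / L
}

# literal step-by-step transcription of the Weir & Cockerham (1984) a, b, c
# formulas for r = 2 populations (scalar)
oracle_wc <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 / (r * nbar) + n2^2 / (r * nbar))) / (r - 1)
  pbar <- (n1 * p1) / (r * nbar) + (n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2) / ((r - 1) * nbar) +
    (n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1) / (r * nbar) + (n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# EHH by exhaustive substring grouping: at extension x (in walk order from
# the core), haplotypes are grouped by their exact allele string over the
# sites strictly beyond the core up to x; EHH = sum C(n_g,2)/C(n,2).
oracle_ehh <- function(hapmat, core, carriers, direction) {
  n <- length(carriers)
  S <- nrow(hapmat)
  idx <- if (direction == "right") {
    if (core < S) (core + 1):S else integer()
  } else {
    if (core > 1) (core - 1):1 else integer()
  }
  ehh <- numeric(length(idx) + 1)
  ehh[1] <- 1
  for (k in seq_along(idx)) {
    seg <- hapmat[idx[seq_len(k)], carriers, drop = FALSE]
    key <- apply(seg, 2, paste, collapse = "")
    cnt <- table(key)
    ehh[k + 1] <- sum(choose(cnt, 2)) / choose(n, 2)
  }
  tibble::tibble(site = c(core, idx), ehh = ehh)
}

# all-pairs interval overlap (1-based inclusive gene vs query intervals)
oracle_overlap_genes <- function(genes, q_start, q_end, q_chrom) {
  if (length(q_chrom) == 1L) q_chrom <- rep(q_chrom, length(q_start))
  hits <- character()
  for (g in seq_len(nrow(genes))) {
    for (k in seq_along(q_start)) {
      if (genes$chrom[g] == q_chrom[k] &&
          genes$start[g] <= q_end[k] && genes$end[g] >= q_start[k]) {
        hits <- c(hits, genes$gene_id[g])
      }
    }
  }
  sort(unique(hits))
}

# independent quadrature-based evaluation of the hitchhiking mixture density
# (component boundary masses and interior values assembled from scratch)
oracle_sweep_loglik <- function(p_test, p_ref, c, omega) {
  sig <- sqrt(omega * p_ref * (1 - p_ref))
  mass <- function(mu, lower, upper) {
    stats::integrate(function(z) stats::dnorm(z, mu, sig), lower, upper,
                     rel.tol = 1e-10)$value
  }
  dens_one <- function(x, mu) {
    if (x <= 0) {
      mass(mu, -Inf, 0)
    } else if (x >= 1) {
      mass(mu, 1, Inf)
    } else {
      stats::dnorm(x, mu, sig)
    }
  }
  mu1 <- 1 - c + c * p_ref
  mu2 <- c * p_ref
  log(p_ref * dens_one(p_test, mu1) + (1 - p_ref) * dens_one(p_test, mu2))
}

# standard sweep scenario used across power experiments (study conditions)
sweep_scenario <- function(seed, out_dir = NULL) {
  simulate_populations(
    sim_config(L = 1e6, t_split = 60, seed = seed,
               sweep = list(pos = 550000, s = 0.5)),
    out_dir = out_dir)
}
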