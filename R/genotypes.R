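# Core containers: genotype_set (diploid dosages) and haplotype_set (phased
# binary alleles). Both wrap a sites-by-columns integer matrix plus a site
# tibble; the site tibble carries pooled MAF, missingness, and per-population
# allele counts, so every downstream statistic reads from one place.

new_genotype_set <- function(dosage, sites, samples, pops, chrom_lengths = NULL) {
  stopifnot(nrow(dosage) == nrow(sites), ncol(dosage) == length(samples))
  if (!all(samples %in% names(pops))) {
    abort("every sample must be assigned to a population")
  }
  pops <- pops[samples]
  x <- structure(
    list(dosage = dosage, sites = sites, samples = samples, pops = pops,
         chrom_lengths = chrom_lengths),
    class = "genotype_set"
  )
  x$sites <- site_stats_gset(x)
  x
}

new_haplotype_set <- function(hap, sites, samples, pops, chrom_lengths = NULL) {
  stopifnot(nrow(hap) == nrow(sites), ncol(hap) == 2L * length(samples))
  if (anyNA(hap)) abort("haplotype_set cannot contain missing alleles")
  pops <- pops[samples]
  x <- structure(
    list(hap = hap, sites = sites, samples = samples, pops = pops,
         chrom_lengths = chrom_lengths),
    class = "haplotype_set"
  )
  x$sites <- site_stats_hset(x)
  x
}

# population label for each haplotype column (two per sample, in sample order)
hap_pops <- function(hset) rep(unname(hset$pops), each = 2L)

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$dosage), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$pops)),
                                    table(x$pops)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$hap), " sites x ", ncol(x$hap),
      " haplotypes (", length(x$samples), " samples)\n", sep = "")
  invisible(x)
}

site_stats_gset <- function(x) {
  d <- x$dosage
  sites <- x$sites[c("chrom", "pos", "ref", "alt")]
  miss <- rowSums(is.na(d))
  called_hap <- 2L * (ncol(d) - miss)
  alt_hap <- rowSums(d, na.rm = TRUE)
  p <- ifelse(called_hap > 0, alt_hap / called_hap, NA_real_)
  sites$missing_count <- as.integer(miss)
  sites$maf <- pmin(p, 1 - p)
  for (pop in unique(unname(x$pops))) {
    cols <- which(unname(x$pops) == pop)
    dm <- d[, cols, drop = FALSE]
    sites[[paste0("alt_", pop)]] <- as.integer(rowSums(dm, na.rm = TRUE))
    sites[[paste0("called_", pop)]] <-
      as.integer(2L * (length(cols) - rowSums(is.na(dm))))
  }
  sites
}

site_stats_hset <- function(x) {
  h <- x$hap
  sites <- x$sites[c("chrom", "pos", "ref", "alt")]
  p <- rowMeans(h)
  sites$missing_count <- 0L
  sites$maf <- pmin(p, 1 - p)
  hp <- hap_pops(x)
  for (pop in unique(unname(x$pops))) {
    cols <- which(hp == pop)
    sites[[paste0("alt_", pop)]] <-
      as.integer(rowSums(h[, cols, drop = FALSE]))
    sites[[paste0("called_", pop)]] <- length(cols)
  }
  sites
}

subset_sites <- function(x, idx) {
  if (inherits(x, "genotype_set")) {
    x$dosage <- x$dosage[idx, , drop = FALSE]
  } else {
    x$hap <- x$hap[idx, , drop = FALSE]
  }
  x$sites <- x$sites[idx, , drop = FALSE]
  x
}

# per-site allele summaries for one population: n (called haplotypes), p (alt
# frequency), h (observed heterozygote proportion; NA for haplotype input)
pop_site_summary <- function(x, population) {
  if (inherits(x, "haplotype_set")) {
    cols <- which(hap_pops(x) == population)
    if (length(cols) == 0L) abort(paste0("unknown population: ", population))
    h <- x$hap[, cols, drop = FALSE]
    tibble(n = length(cols), p = rowMeans(h), h_obs = NA_real_)
  } else {
    cols <- which(unname(x$pops) == population)
    if (length(cols) == 0L) abort(paste0("unknown population: ", population))
    d <- x$dosage[, cols, drop = FALSE]
    n_dip <- length(cols) - rowSums(is.na(d))
    n <- 2L * n_dip
    p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / n, NA_real_)
    h_obs <- ifelse(n_dip > 0, rowSums(d == 1L, na.rm = TRUE) / n_dip, NA_real_)
    tibble(n = as.integer(n), p = p, h_obs = h_obs)
  }
}

#' Filter sites by missingness and minor allele frequency
#'
#' Keeps sites whose missing-genotype fraction is at most `max_missing` and
#' whose pooled minor allele frequency is at least `min_maf`. The defaults
#' reproduce the strict population-genomics filter of no missing calls in any
#' accession and MAF >= 0.05; a site at exactly the MAF boundary survives.
#' Site order is preserved and the operation is idempotent.
#'
#' @param x a `genotype_set` or `haplotype_set`
#' @param max_missing maximum tolerated fraction of missing genotypes in
#'   `[0, 1]` (0 = no missing calls allowed)
#' @param min_maf minimum pooled minor allele frequency in `[0, 0.5]`
#' @return an object of the same class with failing sites removed
#' @export
filter_sites <- function(x, max_missing = 0, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  n_samp <- length(x$samples)
  miss_frac <- x$sites$missing_count / n_samp
  keep <- miss_frac <= max_missing & !is.na(x$sites$maf) &
    x$sites$maf >= min_maf
  subset_sites(x, which(keep))
}
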