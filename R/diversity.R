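# Windowed nucleotide diversity, reduction of diversity (ROD), and the
# Weir & Cockerham (1984) two-population FST estimator with ratio-of-averages
# window summaries.

#' Windowed nucleotide diversity (pi)
#'
#' Per window, pi is the unbiased per-bp expected pairwise difference:
#' `sum_j [n_j/(n_j-1)] * 2*p_j*(1-p_j) / L` over variant sites `j` in the
#' window, with `n_j` the called haplotype count and `p_j` the alt frequency in
#' the chosen population; this equals the mean pairwise Hamming distance over
#' all haplotype pairs divided by the window length. Sites with fewer than two
#' called haplotypes are skipped and counted.
#'
#' @param x a `genotype_set` or `haplotype_set`
#' @param population population whose diversity is measured
#' @param windows window tibble from [make_windows()]
#' @return the window tibble plus `pi`, `n_snps` (variant records used) and
#'   `n_skipped`
#' @export
window_pi <- function(x, population, windows) {
  ps <- pop_site_summary(x, population)
  usable <- ps$n >= 2L & !is.na(ps$p)
  term <- rep(0, nrow(ps))
  term[usable] <- (ps$n[usable] / (ps$n[usable] - 1)) *
    2 * ps$p[usable] * (1 - ps$p[usable])
  widx <- assign_windows(x$sites$chrom, x$sites$pos, windows)
  out <- windows
  L <- out$end - out$start
  out$pi <- 0
  out$n_snps <- 0L
  out$n_skipped <- 0L
  inw <- !is.na(widx)
  if (any(inw)) {
    sums <- tapply(term[inw & usable], widx[inw & usable], sum)
    cnts <- table(widx[inw & usable])
    skp <- table(widx[inw & !usable])
    out$pi[as.integer(names(sums))] <- as.numeric(sums)
    out$n_snps[as.integer(names(cnts))] <- as.integer(cnts)
    out$n_skipped[as.integer(names(skp))] <- as.integer(skp)
  }
  out$pi <- out$pi / L
  out
}

#' Reduction of diversity between two windowed pi tracks
#'
#' `ROD = 1 - pi_test / pi_ref` per window; 0 when diversities are equal and
#' approaching 1 as the test population loses diversity. Windows with
#' `pi_ref = 0` or with fewer than `min_snps` variant records (in either
#' track) are flagged invalid and excluded from outlier ranking, but kept in
#' the output.
#'
#' @param track_ref pi track of the reference (landrace-like) population
#' @param track_test pi track of the test (weedy-like) population
#' @param min_snps minimum variant records per window for a valid ROD
#' @return window tibble with `rod`, `n_snps` and `valid`
#' @export
rod <- function(track_ref, track_test, min_snps = 10) {
  if (!identical(track_ref[c("chrom", "start", "end")],
                 track_test[c("chrom", "start", "end")])) {
    abort("pi tracks must be computed on identical windows")
  }
  n_snps <- pmin(track_ref$n_snps, track_test$n_snps)
  valid <- track_ref$pi > 0 & n_snps >= min_snps
  tibble(chrom = track_ref$chrom, start = track_ref$start,
         end = track_ref$end,
         rod = ifelse(track_ref$pi > 0, 1 - track_test$pi / track_ref$pi,
                      NA_real_),
         n_snps = n_snps, valid = valid)
}

#' Per-site Weir-Cockerham (1984) variance components
#'
#' Computes the a (among-population), b (among individuals within
#' populations) and c (within-individual) variance components and
#' `theta = a/(a+b+c)` for two populations, from per-population diploid sample
#' sizes, alt allele frequencies and observed heterozygote proportions.
#' Negative per-site theta values are retained (standard estimator
#' behaviour). Sites where `a+b+c = 0` (e.g. both populations monomorphic for
#' the same allele) are flagged invalid.
#'
#' @param n1,n2 called diploid sample sizes per population (vectors)
#' @param p1,p2 alt allele frequencies per population
#' @param h1,h2 observed heterozygote proportions per population
#' @return a tibble with columns `a`, `b`, `c`, `theta`, `valid`
#' @export
wc_fst_site <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) *
       hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- !is.finite(denom) | denom == 0 | nbar <= 1 | n1 < 1 | n2 < 1
  tibble(a = a, b = b, c = cc,
         theta = ifelse(bad, NA_real_, a / denom),
         valid = !bad)
}

#' Per-site FST components between two populations of a genotype set
#'
#' @param x a `genotype_set` (heterozygosity from dosages) or
#'   `haplotype_set` (haplotypes treated as haploid pairs with h = 0 is not
#'   meaningful; use genotype input for the WC84 estimator)
#' @param pop_ref,pop_test the two population names
#' @return the site tibble (chrom, pos) with WC84 components appended
#' @export
fst_sites <- function(x, pop_ref, pop_test) {
  if (!inherits(x, "genotype_set")) {
    abort("fst_sites expects a genotype_set (diploid dosages)")
  }
  s1 <- pop_site_summary(x, pop_ref)
  s2 <- pop_site_summary(x, pop_test)
  wc <- wc_fst_site(s1$n / 2, s2$n / 2, s1$p, s2$p, s1$h_obs, s2$h_obs)
  bind_cols(x$sites[c("chrom", "pos")], wc)
}

#' Windowed FST (ratio of averages)
#'
#' The window estimate is `sum(a) / sum(a+b+c)` over valid sites -- the ratio
#' of averages, not the average of per-site ratios. Windows whose component
#' sum is non-positive, or that contain no valid site, are flagged invalid.
#'
#' @param site_components output of [fst_sites()] (or any tibble with chrom,
#'   pos, a, b, c, valid)
#' @param windows window tibble from [make_windows()]
#' @return window tibble with `fst`, `n_snps`, `valid`
#' @export
windowed_fst <- function(site_components, windows) {
  sc <- site_components[site_components$valid, , drop = FALSE]
  widx <- assign_windows(sc$chrom, sc$pos, windows)
  out <- windows
  out$fst <- NA_real_
  out$n_snps <- 0L
  inw <- !is.na(widx)
  if (any(inw)) {
    num <- tapply(sc$a[inw], widx[inw], sum)
    den <- tapply((sc$a + sc$b + sc$c)[inw], widx[inw], sum)
    cnt <- table(widx[inw])
    i <- as.integer(names(num))
    out$fst[i] <- ifelse(as.numeric(den) > 0,
                         as.numeric(num) / as.numeric(den), NA_real_)
    out$n_snps[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out$valid <- !is.na(out$fst)
  out
}
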