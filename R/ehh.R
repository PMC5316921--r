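# EHH / iHH / iHS / XP-EHH. The partition-refinement walks live in src/; this
# file owns carrier selection, ancestral-allele policy, integration and score
# standardization. EHH at the core is 1 by definition (a single group), and
# refinement uses sites strictly beyond the core, so for XP-EHH the core's own
# alleles never split the partition. Gaps carry no scaling penalty (a
# documented divergence from selscan's max-gap heuristic).

#' Extended haplotype homozygosity profile from a core site
#'
#' `EHH(x) = sum_g C(n_g, 2) / C(n, 2)` where `n_g` counts carrier haplotypes
#' identical at every site from the core out to `x`; computed by incremental
#' partition refinement. The profile starts at 1 at the core and is
#' non-increasing.
#'
#' @param hset a `haplotype_set`
#' @param core_index site row index of the core SNP
#' @param carriers haplotype column indices (e.g. carriers of one core allele
#'   for iHS, or all haplotypes of one population for XP-EHH); at least 2
#' @param direction `"right"` (increasing position) or `"left"`
#' @param map a `genetic_map` (default uniform 4 cM/Mb)
#' @param max_extension_bp stop the walk beyond this physical extension
#' @return a tibble with `site`, `pos`, `cM`, `ehh`; attribute `hit_zero`
#'   records whether the profile reached a value of 0 (beyond which it cannot
#'   change). Fewer than 2 carriers yield a zero-row (invalid) profile.
#' @export
ehh <- function(hset, core_index, carriers, direction = c("right", "left"),
                map = uniform_map(), max_extension_bp = Inf) {
  direction <- match.arg(direction)
  if (length(carriers) < 2L) {
    out <- tibble(site = integer(), pos = integer(), cM = numeric(),
                  ehh = numeric())
    return(structure(out, hit_zero = FALSE, valid = FALSE))
  }
  bp <- as.numeric(hset$sites$pos)
  w <- ehh_walk_cpp(hset$hap, core_index - 1L, as.integer(carriers - 1L),
                    if (direction == "right") 1L else -1L,
                    0, bp, max_extension_bp)
  idx <- w$idx + 1L
  cm <- map_cM(map, hset$sites$chrom[core_index], bp[idx])
  structure(tibble(site = idx, pos = hset$sites$pos[idx], cM = cm,
                   ehh = w$ehh),
            hit_zero = w$hit_cutoff, valid = TRUE)
}

#' Integrated EHH (iHH) of a one-direction profile
#'
#' Trapezoidal integral of EHH over genetic distance, truncated at the first
#' site where EHH drops below `ehh_cutoff` (that final trapezoid is
#' included). A profile that never falls below the cutoff before the
#' chromosome end is flagged invalid; a single-point profile integrates to 0.
#'
#' @param profile a profile from [ehh()] (columns `cM`, `ehh`)
#' @param ehh_cutoff truncation threshold
#' @return a list with `ihh` (cM units) and `valid`
#' @export
ihh <- function(profile, ehh_cutoff = 0.05) {
  e <- profile$ehh
  g <- profile$cM
  if (length(e) == 0L) return(list(ihh = NA_real_, valid = FALSE))
  cut_at <- which(e < ehh_cutoff)
  valid <- length(cut_at) > 0L
  last <- if (valid) min(cut_at) else length(e)
  if (last == 1L) return(list(ihh = 0, valid = valid))
  dg <- abs(diff(g[seq_len(last)]))
  list(ihh = sum(0.5 * (e[seq_len(last - 1L)] + e[2:last]) * dg),
       valid = valid)
}

#' iHS scan
#'
#' Per core SNP with in-population derived-allele MAF at or above `maf_min`:
#' the unstandardized score is `ln(iHH_ancestral / iHH_derived)`, then scores
#' are standardized to mean 0, sd 1 within derived-allele-frequency bins
#' (default 50 equal-width bins; bins with fewer than `min_bin` scores are
#' merged with neighbours). Cores with an invalid iHH on either allele (the
#' EHH profile never fell below `ehh_cutoff` inside `max_extension_bp`, or an
#' allele has fewer than two carriers) are flagged invalid and excluded from
#' standardization.
#'
#' @param hset phased `haplotype_set`
#' @param population population to scan
#' @param ancestral `"ref_is_ancestral"` (default) or `"annotation"`, in
#'   which case `anc_alleles` supplies per-site ancestral bases
#' @param anc_alleles tibble with `chrom`, `pos`, `ancestral` (bases); sites
#'   whose ancestral base matches neither allele are dropped
#' @param maf_min minimum within-population MAF for a core
#' @param ehh_cutoff EHH truncation threshold
#' @param max_extension_bp maximum physical extension of a walk
#' @param map a `genetic_map`
#' @param n_bins number of derived-frequency bins for standardization
#' @param min_bin minimum scores per bin before merging
#' @return tibble per core: `chrom`, `pos`, `freq_derived`, `ihh_d`, `ihh_a`,
#'   `unstd`, `std`, `valid`
#' @export
ihs_scan <- function(hset, population,
                     ancestral = c("ref_is_ancestral", "annotation"),
                     anc_alleles = NULL, maf_min = 0.05, ehh_cutoff = 0.05,
                     max_extension_bp = 1e6, map = uniform_map(),
                     n_bins = 50, min_bin = 20) {
  ancestral <- match.arg(ancestral)
  cols <- which(hap_pops(hset) == population)
  if (length(cols) < 4L) abort("need at least 4 haplotypes in the population")

  # which allele (0 = ref, 1 = alt) is derived at each site
  if (ancestral == "ref_is_ancestral") {
    derived <- rep(1L, nrow(hset$hap))
  } else {
    if (is.null(anc_alleles)) abort("anc_alleles required for annotation policy")
    key <- paste(hset$sites$chrom, hset$sites$pos)
    akey <- paste(anc_alleles$chrom, anc_alleles$pos)
    anc <- anc_alleles$ancestral[match(key, akey)]
    derived <- dplyr::case_when(anc == hset$sites$ref ~ 1L,
                                anc == hset$sites$alt ~ 0L,
                                TRUE ~ NA_integer_)
  }

  out <- purrr::map_dfr(unique(hset$sites$chrom), function(ch) {
    rows <- which(hset$sites$chrom == ch)
    H <- hset$hap[rows, cols, drop = FALSE]
    bp <- as.numeric(hset$sites$pos[rows])
    cm <- map_cM(map, ch, bp)
    der <- derived[rows]
    p_alt <- rowMeans(H)
    freq_derived <- ifelse(der == 1L, p_alt, 1 - p_alt)
    cores <- which(!is.na(der) &
                     pmin(freq_derived, 1 - freq_derived) >= maf_min)
    res <- ihs_scan_cpp(H, bp, cm, as.integer(cores - 1L),
                        as.integer(der[cores]), ehh_cutoff, max_extension_bp)
    tibble(chrom = ch, pos = hset$sites$pos[rows][cores],
           freq_derived = freq_derived[cores],
           ihh_d = res[, 1L], ihh_a = res[, 2L], valid = res[, 3L] == 1)
  })
  out$unstd <- ifelse(out$valid, log(out$ihh_a / out$ihh_d), NA_real_)
  std <- standardize_by_bin(out$unstd, out$freq_derived, n_bins, min_bin)
  out$std <- as.numeric(std)
  out$std_bin <- attr(std, "bin")  # merged frequency bin used to standardize
  out[c("chrom", "pos", "freq_derived", "ihh_d", "ihh_a", "unstd", "std",
        "std_bin", "valid")]
}

#' XP-EHH scan
#'
#' Per core SNP, EHH is computed over all haplotypes of each population (the
#' core allele does not partition them); the unstandardized score is
#' `ln(iHH_A / iHH_B)` and swapping the populations negates it exactly.
#' Scores are standardized genome-wide over valid cores. Positive scores mark
#' longer haplotypes (slower EHH decay) in population A -- the convention is
#' A = test/weedy-like when scanning for selection in the test population.
#'
#' @param hset phased `haplotype_set`
#' @param pop_a,pop_b population names (A is the numerator)
#' @param maf_min minimum pooled MAF for a core SNP
#' @inheritParams ihs_scan
#' @return tibble per core: `chrom`, `pos`, `ihh_a`, `ihh_b`, `unstd`,
#'   `std`, `valid`
#' @export
xpehh_scan <- function(hset, pop_a, pop_b, maf_min = 0.05, ehh_cutoff = 0.05,
                       max_extension_bp = 1e6, map = uniform_map()) {
  hp <- hap_pops(hset)
  hapA <- which(hp == pop_a)
  hapB <- which(hp == pop_b)
  if (length(hapA) < 2L || length(hapB) < 2L) {
    abort("both populations need at least 2 haplotypes")
  }
  out <- purrr::map_dfr(unique(hset$sites$chrom), function(ch) {
    rows <- which(hset$sites$chrom == ch)
    H <- hset$hap[rows, , drop = FALSE]
    bp <- as.numeric(hset$sites$pos[rows])
    cm <- map_cM(map, ch, bp)
    pool <- rowMeans(H[, c(hapA, hapB), drop = FALSE])
    cores <- which(pmin(pool, 1 - pool) >= maf_min)
    res <- xpehh_scan_cpp(H, as.integer(hapA - 1L), as.integer(hapB - 1L),
                          bp, cm, as.integer(cores - 1L), ehh_cutoff,
                          max_extension_bp)
    tibble(chrom = ch, pos = hset$sites$pos[rows][cores],
           ihh_a = res[, 1L], ihh_b = res[, 2L], valid = res[, 3L] == 1)
  })
  out$unstd <- ifelse(out$valid, log(out$ihh_a / out$ihh_b), NA_real_)
  mu <- mean(out$unstd[out$valid])
  sg <- sd(out$unstd[out$valid])
  out$std <- if (isTRUE(sg > 0)) (out$unstd - mu) / sg else NA_real_
  out[c("chrom", "pos", "ihh_a", "ihh_b", "unstd", "std", "valid")]
}

# Standardize scores within equal-width frequency bins; bins with fewer than
# min_bin valid scores are merged with their right neighbour (the trailing
# remainder folds back into the previous bin). Returns NA for invalid scores.
standardize_by_bin <- function(score, freq, n_bins = 50, min_bin = 20) {
  std <- rep(NA_real_, length(score))
  ok <- !is.na(score)
  if (!any(ok)) return(std)
  raw_bin <- pmin(pmax(ceiling(freq * n_bins), 1L), n_bins)
  counts <- tabulate(raw_bin[ok], nbins = n_bins)
  merged <- integer(n_bins)  # raw bin -> merged bin id
  gid <- 1L
  acc <- 0L
  for (b in seq_len(n_bins)) {
    merged[b] <- gid
    acc <- acc + counts[b]
    if (acc >= min_bin) {
      gid <- gid + 1L
      acc <- 0L
    }
  }
  if (acc > 0L && gid > 1L) {
    merged[merged == gid] <- gid - 1L  # fold short tail into previous group
  }
  grp <- merged[raw_bin]
  for (g in unique(grp[ok])) {
    i <- which(ok & grp == g)
    mu <- mean(score[i])
    sg <- sd(score[i])
    if (isTRUE(sg > 0)) std[i] <- (score[i] - mu) / sg
  }
  attr(std, "bin") <- ifelse(ok, grp, NA_integer_)
  std
}
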