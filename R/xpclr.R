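# Simplified cross-population composite likelihood ratio (XP-CLR class) test.
# The test-population allele frequency at a neutral site is modelled as the
# reference frequency plus Gaussian drift noise with variance
# omega * p_ref * (1 - p_ref), truncated to (0,1) with the truncated tail
# masses placed as point masses at 0 and 1. Near a selected site, a lineage
# escapes the sweep with probability c = 1 - exp(-d / s_eff) (d = genetic
# distance in Morgans); a non-escaping lineage is dragged to the beneficial
# background, giving the two-component hitchhiking mixture below. At c = 1
# the sweep density reduces exactly to the neutral one, so the neutral model
# is nested at the small-s grid edge and CLR >= 0. This is a deliberate
# simplification of the published XP-CLR: no LD-based SNP down-weighting, and
# Gaussian drift in place of the full diffusion transition.

#' Estimate the background drift parameter omega
#'
#' `omega = mean[(p_test - p_ref)^2 / (p_ref (1 - p_ref))]` over sites
#' polymorphic in the reference. Under pure drift for `T` generations along
#' the test branch (reference tracking the ancestral frequency) its
#' expectation is `1 - (1 - 1/(2N))^T`, approximately `T/(2N)` for short
#' divergence.
#'
#' @param p_ref,p_test per-site allele frequencies
#' @return an `omega` scalar (floored at 1e-6 with a warning when the
#'   populations are identical)
#' @export
estimate_omega <- function(p_ref, p_test) {
  ok <- !is.na(p_ref) & !is.na(p_test) & p_ref > 0 & p_ref < 1
  if (!any(ok)) abort("no sites with 0 < p_ref < 1")
  omega <- mean((p_test[ok] - p_ref[ok])^2 / (p_ref[ok] * (1 - p_ref[ok])))
  if (omega <= 0) {
    warn("estimated omega is 0 (identical frequencies); floored at 1e-6")
    omega <- 1e-6
  }
  omega
}

#' Hitchhiking mixture density of the test-population frequency
#'
#' Density of `p_test` given `p_ref`, escape probability `c` and drift
#' variance `omega * p_ref * (1 - p_ref)`:
#' `f = p_ref * g(x; 1 - c + c p_ref) + (1 - p_ref) * g(x; c p_ref)` where
#' `g(.; mu)` is Normal(mu, omega p_ref (1-p_ref)) truncated to (0,1), the
#' truncated tail masses sitting as point masses at 0 and 1. Values of
#' `p_test` at the boundaries are evaluated as those point masses; interior
#' values as the continuous density.
#'
#' @param p_test observed test-population frequencies (in `[0, 1]`)
#' @param p_ref reference frequency in (0, 1)
#' @param c escape probability in `[0, 1]`; `c = 1` reduces to neutral drift,
#'   `c = 0` is complete hitchhiking
#' @param omega drift variance inflation, > 0
#' @param log return log density/mass
#' @return density (interior) or point mass (boundary) values
#' @export
sweep_density <- function(p_test, p_ref, c, omega, log = FALSE) {
  if (omega <= 0) abort("omega must be positive")
  stopifnot(c >= 0, c <= 1, p_ref > 0, p_ref < 1)
  sig <- sqrt(omega * p_ref * (1 - p_ref))
  mu1 <- 1 - c + c * p_ref
  mu2 <- c * p_ref
  w1 <- p_ref
  w2 <- 1 - p_ref
  comp <- function(x, mu) {
    # point masses at the boundaries, renormalized truncated density inside
    lo <- pnorm(0, mu, sig)
    hi <- 1 - pnorm(1, mu, sig)
    ifelse(x <= 0, lo,
           ifelse(x >= 1, hi, dnorm(x, mu, sig)))
  }
  f <- w1 * comp(p_test, mu1) + w2 * comp(p_test, mu2)
  if (log) base::log(f) else f
}

neutral_density <- function(p_test, p_ref, omega, log = FALSE) {
  sweep_density(p_test, p_ref, c = 1, omega = omega, log = log)
}

#' XP-CLR scan along a chromosome grid
#'
#' At grid points every `grid_spacing_bp`, the composite log-likelihood
#' `l(s) = sum_j ln f(p_test,j | p_ref,j, c_j(s), omega)` is maximized over a
#' logarithmic grid of effective selection strengths (Morgans), using the up
#' to `max_snps` SNPs nearest the grid point within `window_cM` genetic
#' distance; `CLR = 2 (max_s l(s) - l_neutral)`, clamped at 0. Sites
#' monomorphic in the reference are excluded (the escape probability is
#' undefined there). Grid points with fewer than `min_snps` usable SNPs are
#' flagged invalid.
#'
#' @param gset a `genotype_set`
#' @param pop_ref,pop_test reference and test population names
#' @param map a `genetic_map`
#' @param grid_spacing_bp spacing of evaluation points (default 10 kb)
#' @param window_cM genetic half-width of the SNP window around a grid point
#' @param s_grid selection-strength grid in Morgans (default 12 log-spaced
#'   points in `[1e-5, 1e-1]`)
#' @param omega drift parameter; estimated genome-wide with
#'   [estimate_omega()] when `NULL`
#' @param max_snps cap on SNPs per window (nearest first), limiting
#'   correlated-SNP inflation
#' @param min_snps minimum SNPs for a valid grid point
#' @return an `xpclr_track` tibble: `chrom`, `pos`, `clr`, `best_s`,
#'   `n_snps`, `valid`; attribute `omega`
#' @export
xpclr_scan <- function(gset, pop_ref, pop_test, map = uniform_map(),
                       grid_spacing_bp = 10000, window_cM = 0.5,
                       s_grid = 10^seq(-5, -1, length.out = 12),
                       omega = NULL, max_snps = 200, min_snps = 5) {
  sref <- pop_site_summary(gset, pop_ref)
  stest <- pop_site_summary(gset, pop_test)
  usable <- !is.na(sref$p) & !is.na(stest$p) & sref$p > 0 & sref$p < 1
  if (is.null(omega)) {
    omega <- estimate_omega(sref$p[usable], stest$p[usable])
  }
  out <- purrr::map_dfr(unique(gset$sites$chrom), function(ch) {
    rows <- which(gset$sites$chrom == ch & usable)
    pos <- gset$sites$pos[rows]
    if (length(pos) == 0L) return(tibble())
    pr <- sref$p[rows]
    pt <- stest$p[rows]
    cm <- map_cM(map, ch, pos)
    lim <- if (!is.null(gset$chrom_lengths) &&
               ch %in% names(gset$chrom_lengths)) {
      gset$chrom_lengths[[ch]]
    } else {
      max(pos)
    }
    grid <- seq(grid_spacing_bp, lim, by = grid_spacing_bp)
    grid_cm <- map_cM(map, ch, grid)
    purrr::map_dfr(seq_along(grid), function(gi) {
      d_cm <- abs(cm - grid_cm[gi])
      sel <- which(d_cm <= window_cM)
      if (length(sel) > max_snps) {
        sel <- sel[order(d_cm[sel])][seq_len(max_snps)]
      }
      if (length(sel) < min_snps) {
        return(tibble(chrom = ch, pos = grid[gi], clr = NA_real_,
                      best_s = NA_real_, n_snps = length(sel),
                      valid = FALSE))
      }
      d_M <- d_cm[sel] / 100  # Morgans
      ll_neutral <- sum(log(sweep_density_vec(pt[sel], pr[sel], 1, omega)))
      ll_s <- vapply(s_grid, function(s) {
        cj <- 1 - exp(-d_M / s)
        sum(log(sweep_density_vec(pt[sel], pr[sel], cj, omega)))
      }, numeric(1))
      best <- which.max(ll_s)
      tibble(chrom = ch, pos = grid[gi],
             clr = max(0, 2 * (ll_s[best] - ll_neutral)),
             best_s = s_grid[best], n_snps = length(sel), valid = TRUE)
    })
  })
  structure(out, omega = omega, class = c("xpclr_track", class(out)))
}

# vectorized over sites: p_ref and c vary per site
sweep_density_vec <- function(p_test, p_ref, c, omega) {
  sig <- sqrt(omega * p_ref * (1 - p_ref))
  mu1 <- 1 - c + c * p_ref
  mu2 <- c * p_ref
  comp <- function(x, mu) {
    ifelse(x <= 0, pnorm(0, mu, sig),
           ifelse(x >= 1, 1 - pnorm(1, mu, sig), dnorm(x, mu, sig)))
  }
  # floor against underflow so composite log-likelihoods stay finite
  pmax(p_ref * comp(p_test, mu1) + (1 - p_ref) * comp(p_test, mu2), 1e-300)
}

#' Windowed XP-CLR summary
#'
#' The per-window value is the maximum CLR among valid grid points inside the
#' window (the summary the outlier pipeline ranks).
#'
#' @param track an `xpclr_track` from [xpclr_scan()]
#' @param windows window tibble from [make_windows()]
#' @return window tibble with `clr`, `n_grid`, `valid`
#' @export
windowed_xpclr <- function(track, windows) {
  tr <- track[track$valid, , drop = FALSE]
  widx <- assign_windows(tr$chrom, tr$pos, windows)
  out <- windows
  out$clr <- NA_real_
  out$n_grid <- 0L
  inw <- !is.na(widx)
  if (any(inw)) {
    mx <- tapply(tr$clr[inw], widx[inw], max)
    cnt <- table(widx[inw])
    out$clr[as.integer(names(mx))] <- as.numeric(mx)
    out$n_grid[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out$valid <- !is.na(out$clr)
  out
}
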