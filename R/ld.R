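# Pairwise-r2 linkage disequilibrium decay. Phased input uses the true
# D-based haplotype r2 = D^2/(pA qA pB qB); unphased input uses the squared
# Pearson correlation of dosages (composite LD, the PLINK-default behaviour
# class). Monomorphic sites never form pairs.

#' LD decay curve
#'
#' Computes r2 for all site pairs within `max_dist_bp` of each other (within
#' chromosomes) for one population, averages per distance bin, and records the
#' half-decay distance: the midpoint of the first bin whose mean r2 has
#' dropped to half of the highest bin mean.
#'
#' @param x a `haplotype_set` (haplotype r2) or `genotype_set` (dosage r2)
#' @param population population name
#' @param max_dist_bp maximum pair distance considered
#' @param bin_width_bp distance bin width
#' @return an `ld_curve` object: tibble with `bin_start`, `bin_end`, `mid`,
#'   `mean_r2`, `n_pairs`, plus attributes `max_r2` and `half_decay_bp`
#' @export
ld_curve <- function(x, population, max_dist_bp = 100000,
                     bin_width_bp = 1000) {
  phased <- inherits(x, "haplotype_set")
  if (phased) {
    cols <- which(hap_pops(x) == population)
    M <- x$hap[, cols, drop = FALSE]
  } else {
    cols <- which(unname(x$pops) == population)
    M <- x$dosage[, cols, drop = FALSE]
  }
  if (length(cols) == 0L) abort(paste0("unknown population: ", population))
  if (nrow(M) < 2L) abort("need at least two sites for LD")

  pos <- x$sites$pos
  chrom <- x$sites$chrom
  p <- rowMeans(M, na.rm = TRUE) / (if (phased) 1 else 2)
  poly <- p > 0 & p < 1
  dists <- list(); r2s <- list(); k <- 1L
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch & poly)
    if (length(sel) < 2L) next
    ppos <- pos[sel]
    for (ii in seq_along(sel)) {
      jj <- which(ppos > ppos[ii] & ppos - ppos[ii] <= max_dist_bp)
      if (length(jj) == 0L) next
      i <- sel[ii]; j <- sel[jj]
      if (phased) {
        n <- ncol(M)
        p11 <- as.numeric(M[j, , drop = FALSE] %*% M[i, ]) / n
        D <- p11 - p[i] * p[j]
        r2 <- D^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
      } else {
        r2 <- as.numeric(cor(M[i, ], t(M[j, , drop = FALSE]),
                             use = "pairwise.complete.obs"))^2
      }
      dists[[k]] <- ppos[jj] - ppos[ii]
      r2s[[k]] <- r2
      k <- k + 1L
    }
  }
  d <- unlist(dists); r2 <- unlist(r2s)
  keep <- !is.na(r2)
  d <- d[keep]; r2 <- r2[keep]
  bin <- pmin(floor((d - 1) / bin_width_bp),
              ceiling(max_dist_bp / bin_width_bp) - 1)
  curve <- tibble(bin = bin, r2 = r2) |>
    group_by(.data$bin) |>
    summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
              .groups = "drop") |>
    mutate(bin_start = .data$bin * bin_width_bp,
           bin_end = (.data$bin + 1) * bin_width_bp,
           mid = .data$bin_start + bin_width_bp / 2) |>
    select("bin_start", "bin_end", "mid", "mean_r2", "n_pairs") |>
    arrange(.data$bin_start)
  structure(curve, class = c("ld_curve", class(curve)),
            max_r2 = if (nrow(curve)) max(curve$mean_r2) else NA_real_,
            half_decay_bp = half_decay_from_curve(curve))
}

half_decay_from_curve <- function(curve) {
  if (nrow(curve) == 0L) return(NA_real_)
  half <- max(curve$mean_r2) / 2
  i <- which(curve$mean_r2 <= half)
  if (length(i) == 0L) return(NA_real_)
  curve$mid[min(i)]
}

#' Half-decay distance of an LD curve
#'
#' The midpoint (bp) of the first distance bin whose mean r2 is at most half
#' of the highest bin mean; `NA` if the curve never decays that far.
#'
#' @param curve an `ld_curve` (or any tibble with `mid` and `mean_r2`)
#' @return distance in bp
#' @export
half_decay <- function(curve) half_decay_from_curve(curve)

#' @exportS3Method ggplot2::autoplot
autoplot.ld_curve <- function(object, ...) {
  hd <- attr(object, "half_decay_bp")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$mid / 1000, y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
  if (!is.na(hd)) {
    p <- p + ggplot2::geom_vline(xintercept = hd / 1000, linetype = "dashed")
  }
  p
}
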