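# Genetic maps: either a constant cM/Mb rate or per-chromosome anchor pairs
# (bp, cM) interpolated linearly (and extrapolated with the terminal segment's
# rate beyond the anchors, so genetic distance never collapses to zero at the
# chromosome ends). Positions map monotonically: pos_a <= pos_b implies
# cM(pos_a) <= cM(pos_b).

#' Uniform genetic map
#'
#' @param rate_cM_per_Mb constant recombination rate; the default 4 cM/Mb is a
#'   rice genome-wide average
#' @return a `genetic_map` object
#' @export
uniform_map <- function(rate_cM_per_Mb = 4.0) {
  stopifnot(rate_cM_per_Mb > 0)
  structure(list(rate = rate_cM_per_Mb, anchors = NULL),
            class = "genetic_map")
}

#' Read an anchored genetic map
#'
#' @param path three-column TSV: `chrom`, `pos` (bp), `cM`; anchors must be
#'   sorted by position with non-decreasing cM within each chromosome
#' @return a `genetic_map` object
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "pos", "cM")
  genetic_map_from_anchors(as_tibble(tab[, 1:3]))
}

genetic_map_from_anchors <- function(anchors) {
  by_chr <- split(anchors, anchors$chrom)
  for (a in by_chr) {
    if (is.unsorted(a$pos, strictly = TRUE)) {
      abort("genetic map anchors must be strictly increasing in position")
    }
    if (is.unsorted(a$cM)) {
      abort("genetic map cM values must be non-decreasing")
    }
  }
  structure(list(rate = NULL, anchors = by_chr), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  if (is.null(x$anchors)) {
    cat("<genetic_map> uniform,", x$rate, "cM/Mb\n")
  } else {
    cat("<genetic_map> anchored,", length(x$anchors), "chromosome(s)\n")
  }
  invisible(x)
}

#' Genetic position (cM) of physical positions
#'
#' @param map a `genetic_map`
#' @param chrom chromosome name (scalar)
#' @param pos bp positions
#' @return genetic positions in cM
#' @export
map_cM <- function(map, chrom, pos) {
  if (is.null(map$anchors)) {
    return(pos / 1e6 * map$rate)
  }
  a <- map$anchors[[chrom]]
  if (is.null(a)) abort(paste0("no map anchors for chromosome ", chrom))
  if (nrow(a) == 1L) return(rep(a$cM[1L], length(pos)))
  out <- approx(a$pos, a$cM, xout = pos, rule = 2)$y
  # linear extrapolation beyond the anchored range, at the terminal rates
  lo <- pos < a$pos[1L]
  hi <- pos > a$pos[nrow(a)]
  if (any(lo)) {
    r <- (a$cM[2L] - a$cM[1L]) / (a$pos[2L] - a$pos[1L])
    out[lo] <- a$cM[1L] + (pos[lo] - a$pos[1L]) * r
  }
  if (any(hi)) {
    k <- nrow(a)
    r <- (a$cM[k] - a$cM[k - 1L]) / (a$pos[k] - a$pos[k - 1L])
    out[hi] <- a$cM[k] + (pos[hi] - a$pos[k]) * r
  }
  out
}
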