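# Empirical outlier calling, outlier-to-gene mapping, and the >= 2-metric
# candidate-gene intersection -- the step that turns five scan tracks into a
# single candidate list.

#' Flag empirical top-quantile outliers in a scan track
#'
#' Valid records are ranked by the tail-appropriate score (the value for the
#' upper tail, its negation for the lower, |value| for two-sided) with ties
#' broken deterministically by genomic order (chrom, then start/pos
#' ascending), and exactly `ceiling(q * M)` of the `M` valid records are
#' flagged. Invalid records are never flagged and do not count towards `M`.
#'
#' @param track a tibble with a `value` column (or the column named in
#'   `value_col`), `chrom`, `start` or `pos`, and optionally `valid`
#' @param q outlier quantile in (0, 1); default the empirical top 2.5%
#' @param tail `"upper"`, `"lower"` or `"two_sided_abs"`
#' @param value_col name of the metric column (default `"value"`)
#' @return the track with a logical `outlier` column
#' @export
call_outliers <- function(track, q = 0.025,
                          tail = c("upper", "lower", "two_sided_abs"),
                          value_col = "value") {
  tail <- match.arg(tail)
  if (!(q > 0 && q < 1)) abort("q must be in (0, 1)")
  v <- track[[value_col]]
  if (is.null(v)) abort(paste0("no column '", value_col, "' in track"))
  valid <- if ("valid" %in% names(track)) track$valid & !is.na(v) else !is.na(v)
  score <- switch(tail, upper = v, lower = -v, two_sided_abs = abs(v))
  start_col <- if ("start" %in% names(track)) track$start else track$pos
  M <- sum(valid)
  track$outlier <- FALSE
  if (M >= 1L) {
    k <- ceiling(q * M)
    idx <- which(valid)
    ord <- idx[order(-score[idx], track$chrom[idx], start_col[idx])]
    track$outlier[ord[seq_len(k)]] <- TRUE
  }
  track
}

#' Map outlier records to overlapping genes
#'
#' Window-level tracks (columns `start`/`end`, 0-based half-open): a gene is
#' included iff its interval overlaps an outlier window by at least 1 bp
#' after the window is extended by `flank_bp` on each side. Site-level
#' tracks (column `pos`): a gene is included iff an outlier site lies within
#' `[start - flank_bp, end + flank_bp]`.
#'
#' @param track a track with an `outlier` column from [call_outliers()]
#' @param genes gene tibble from [read_gff()] (1-based inclusive coordinates)
#' @param flank_bp extension in bp
#' @return sorted character vector of gene ids
#' @export
outliers_to_genes <- function(track, genes, flank_bp = 0) {
  hits <- track[track$outlier, , drop = FALSE]
  if (nrow(hits) == 0L || nrow(genes) == 0L) return(character())
  window_unit <- all(c("start", "end") %in% names(hits))
  out <- character()
  for (ch in unique(hits$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    h <- hits[hits$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L || nrow(h) == 0L) next
    if (window_unit) {
      # 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
      q_start <- h$start + 1 - flank_bp
      q_end <- h$end + flank_bp
    } else {
      q_start <- h$pos - flank_bp
      q_end <- h$pos + flank_bp
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(q_start, q_end),
      IRanges::IRanges(g$start, g$end))
    out <- c(out, g$gene_id[unique(S4Vectors::subjectHits(ov))])
  }
  sort(unique(out))
}

#' Intersect per-metric outlier gene sets into candidate genes
#'
#' A gene supported by outliers of at least `min_support` metrics is a
#' candidate selection gene; each candidate carries the metrics supporting
#' it.
#'
#' @param gene_sets named list of character vectors (one per metric)
#' @param min_support minimum number of supporting metrics (default 2)
#' @return a tibble: `gene_id`, `n_support`, `metrics` (comma-joined, in
#'   `gene_sets` order), sorted by gene id
#' @export
candidate_genes <- function(gene_sets, min_support = 2) {
  if (length(gene_sets) < 2L) abort("at least two metric gene sets required")
  metrics <- names(gene_sets)
  all_genes <- sort(unique(unlist(gene_sets)))
  if (length(all_genes) == 0L) {
    return(tibble(gene_id = character(), n_support = integer(),
                  metrics = character()))
  }
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, metrics))
  n_support <- rowSums(member)
  keep <- n_support >= min_support
  tibble(
    gene_id = all_genes[keep],
    n_support = as.integer(n_support[keep]),
    metrics = unname(apply(member[keep, , drop = FALSE], 1L,
                           function(m) paste(metrics[m], collapse = ",")))
  )
}

#' Per-metric and overlap counts of outlier gene sets
#'
#' The Venn-style summary: per-metric gene counts plus the number of genes
#' found by exactly 1..k metrics.
#'
#' @param gene_sets named list of character vectors
#' @return a list with `per_metric` (named counts) and `by_support`
#'   (tibble `n_support`, `n_genes`)
#' @export
metric_overlap <- function(gene_sets) {
  all_genes <- sort(unique(unlist(gene_sets)))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes))
  support <- rowSums(member)
  by_support <- tibble(n_support = seq_along(gene_sets)) |>
    mutate(n_genes = vapply(.data$n_support,
                            function(k) sum(support == k), integer(1)))
  list(per_metric = vapply(gene_sets, length, integer(1)),
       by_support = by_support)
}

#' Genes within a flank of a locus
#'
#' Returns the genes whose interval intersects
#' `[locus_pos - flank_bp, locus_pos + flank_bp]` -- e.g. the 600-kb flank
#' query used to inspect the neighbourhood of a known domestication locus.
#'
#' @param genes gene tibble from [read_gff()]
#' @param chrom chromosome of the locus
#' @param locus_pos position (bp) of the locus
#' @param flank_bp flank half-width (default 600 kb)
#' @return the subset of `genes`, in genomic order
#' @export
flank_genes <- function(genes, chrom, locus_pos, flank_bp = 600000) {
  genes |>
    filter(.data$chrom == !!chrom,
           .data$start <= locus_pos + flank_bp,
           .data$end >= locus_pos - flank_bp) |>
    arrange(.data$start)
}
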