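# End-to-end selection scan: VCF + population table + GFF (+ map) in,
# per-metric tracks, outlier BED, candidate-gene TSV and a summary JSON out.
# Given the same config and seed the outputs are byte-identical.

#' Run the five-metric selection scan pipeline
#'
#' Reads and filters the input genotypes (no missing calls, MAF >= 0.05 by
#' default), computes the requested metrics between the reference
#' (landrace-like) and test (weedy-like) populations, flags the empirical
#' top-`q` outliers of each (ROD, FST and XP-CLR on 100-kb windows, upper
#' tail; XP-EHH per site, upper tail with the test population as numerator;
#' iHS per site on the test population, two-sided on |score|), maps outliers
#' to genes, and intersects: genes supported by at least `min_support`
#' metrics are the candidate selection genes.
#'
#' @param vcf path to a VCF (phased GT required for iHS/XP-EHH)
#' @param pops path to a sample-population TSV, or a data frame
#' @param gff path to a GFF3 of gene models, or a gene tibble
#' @param map path to a genetic-map TSV, a `genetic_map`, or `NULL` for the
#'   uniform default
#' @param ref_pop,test_pop population names
#' @param window_size window size in bp for the windowed metrics
#' @param q empirical outlier quantile (default top 2.5%)
#' @param min_support metrics required for a candidate gene
#' @param metrics subset of `c("rod", "fst", "ihs", "xpehh", "xpclr")`
#' @param min_snps minimum variant records per window for valid ROD/FST
#' @param xpclr_window_cM genetic half-width of the XP-CLR SNP window; match
#'   it to the map scale (about half the expected hitchhiking extent in cM)
#' @param flank_bp flank for site-metric gene mapping
#' @param max_missing,min_maf site filters (see [filter_sites()])
#' @param seed integer seed (recorded and set; the scan itself is
#'   deterministic)
#' @param out_dir optional output directory; tracks (TSV), outlier regions
#'   (BED, 0-based half-open), candidate genes (TSV) and a summary JSON are
#'   written there
#' @param chrom_lengths optional named vector overriding lengths from the
#'   VCF contig header
#' @return a `sweep_scan` object: list with `tracks`, `gene_sets`,
#'   `candidates`, `summary`, `params`
#' @export
run_sweep_scan <- function(vcf, pops, gff, map = NULL, ref_pop, test_pop,
                           window_size = 100000, q = 0.025, min_support = 2,
                           metrics = c("rod", "fst", "ihs", "xpehh", "xpclr"),
                           min_snps = 10, xpclr_window_cM = 0.5,
                           flank_bp = 0, max_missing = 0,
                           min_maf = 0.05, seed = 1, out_dir = NULL,
                           chrom_lengths = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  pop_tab <- stage("read_pops",
                   if (is.data.frame(pops)) pops else read_pop_table(pops))
  vcf_in <- stage("read_vcf", read_vcf(vcf, pop_tab))
  genes <- stage("read_gff", if (is.data.frame(gff)) gff else read_gff(gff))
  gmap <- stage("read_map", {
    if (is.null(map)) uniform_map()
    else if (inherits(map, "genetic_map")) map
    else read_genetic_map(map)
  })

  gset <- stage("filter_sites",
                filter_sites(vcf_in$genotypes, max_missing, min_maf))
  hset <- vcf_in$haplotypes
  if (!is.null(hset)) hset <- filter_sites(hset, max_missing, min_maf)
  needs_phase <- intersect(metrics, c("ihs", "xpehh"))
  if (length(needs_phase) > 0L && is.null(hset)) {
    abort(paste0("metrics ", paste(needs_phase, collapse = ", "),
                 " need fully phased genotypes"))
  }

  if (is.null(chrom_lengths)) chrom_lengths <- gset$chrom_lengths
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(gset$sites$pos, gset$sites$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths),
                              names(chrom_lengths))
  }
  windows <- make_windows(chrom_lengths, size = window_size)

  tracks <- list()
  if (any(c("rod") %in% metrics)) {
    pi_ref <- stage("window_pi", window_pi(gset, ref_pop, windows))
    pi_test <- stage("window_pi", window_pi(gset, test_pop, windows))
    tracks$rod <- stage("rod", rod(pi_ref, pi_test, min_snps = min_snps)) |>
      rename(value = "rod") |>
      call_outliers(q = q, tail = "upper")
    tracks$pi_ref <- pi_ref
    tracks$pi_test <- pi_test
  }
  if ("fst" %in% metrics) {
    fst_s <- stage("fst_sites", fst_sites(gset, ref_pop, test_pop))
    tr <- stage("windowed_fst", windowed_fst(fst_s, windows))
    tr$valid <- tr$valid & tr$n_snps >= min_snps
    tracks$fst <- tr |>
      rename(value = "fst") |>
      call_outliers(q = q, tail = "upper")
  }
  if ("ihs" %in% metrics) {
    tracks$ihs <- stage("ihs_scan",
                        ihs_scan(hset, test_pop, map = gmap)) |>
      rename(value = "std") |>
      call_outliers(q = q, tail = "two_sided_abs")
  }
  if ("xpehh" %in% metrics) {
    tracks$xpehh <- stage("xpehh_scan",
                          xpehh_scan(hset, test_pop, ref_pop, map = gmap)) |>
      rename(value = "std") |>
      call_outliers(q = q, tail = "upper")
  }
  if ("xpclr" %in% metrics) {
    xp <- stage("xpclr_scan",
                xpclr_scan(gset, ref_pop, test_pop, map = gmap,
                           window_cM = xpclr_window_cM))
    tracks$xpclr <- stage("windowed_xpclr", windowed_xpclr(xp, windows)) |>
      rename(value = "clr") |>
      call_outliers(q = q, tail = "upper")
    tracks$xpclr_grid <- xp
  }

  scan_names <- intersect(c("rod", "fst", "ihs", "xpehh", "xpclr"), metrics)
  gene_sets <- lapply(setNames(scan_names, scan_names), function(m) {
    fl <- if (m %in% c("ihs", "xpehh")) flank_bp else 0
    outliers_to_genes(tracks[[m]], genes, flank_bp = fl)
  })
  cands <- if (length(gene_sets) >= 2L) {
    candidate_genes(gene_sets, min_support = min_support)
  } else {
    tibble(gene_id = character(), n_support = integer(),
           metrics = character())
  }
  cands <- left_join(cands, genes[c("gene_id", "chrom", "start", "end")],
                     by = "gene_id")

  summary <- list(
    n_sites_input = nrow(vcf_in$genotypes$sites),
    n_sites_filtered = nrow(gset$sites),
    n_skipped_records = vcf_in$n_skipped,
    n_windows = nrow(windows),
    per_metric_outliers = lapply(setNames(scan_names, scan_names), function(m)
      sum(tracks[[m]]$outlier)),
    per_metric_genes = lapply(gene_sets, length),
    n_candidates = nrow(cands),
    q = q, min_support = min_support, seed = seed
  )

  res <- structure(
    list(tracks = tracks, gene_sets = gene_sets, candidates = cands,
         summary = summary, windows = windows,
         params = list(ref_pop = ref_pop, test_pop = test_pop,
                       window_size = window_size, q = q,
                       min_support = min_support, metrics = metrics,
                       seed = seed)),
    class = "sweep_scan")
  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

write_scan_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scan_names <- intersect(c("rod", "fst", "ihs", "xpehh", "xpclr"),
                          names(res$tracks))
  bed <- list()
  for (m in scan_names) {
    tr <- res$tracks[[m]]
    readr::write_tsv(tr, file.path(out_dir, paste0(m, "_track.tsv")))
    hits <- tr[tr$outlier, , drop = FALSE]
    if (nrow(hits) > 0L) {
      bed[[m]] <- if ("start" %in% names(hits)) {
        tibble(chrom = hits$chrom, start = as.integer(hits$start),
               end = as.integer(hits$end), name = m)
      } else {
        tibble(chrom = hits$chrom, start = as.integer(hits$pos - 1L),
               end = as.integer(hits$pos), name = m)
      }
    }
  }
  bed <- bind_rows(bed)
  if (nrow(bed) > 0L) bed <- arrange(bed, .data$chrom, .data$start,
                                     .data$name)
  readr::write_tsv(bed, file.path(out_dir, "outliers.bed"),
                   col_names = FALSE)
  readr::write_tsv(res$candidates,
                   file.path(out_dir, "candidate_genes.tsv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan> ", x$params$ref_pop, " vs ", x$params$test_pop, "\n",
      sep = "")
  cat("metrics:", paste(x$params$metrics, collapse = ", "), "\n")
  cat("candidate genes (>=", x$params$min_support, "metrics):",
      nrow(x$candidates), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sweep_scan <- function(x, ...) x$candidates

#' @exportS3Method generics::glance
glance.sweep_scan <- function(x, ...) {
  s <- x$summary
  tibble(n_sites = s$n_sites_filtered, n_windows = s$n_windows,
         n_candidates = s$n_candidates, q = s$q,
         min_support = s$min_support)
}

#' Manhattan-style panel of scan tracks
#'
#' @param object a `sweep_scan`
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_scan <- function(object, ...) {
  scan_names <- intersect(c("rod", "fst", "ihs", "xpehh", "xpclr"),
                          names(object$tracks))
  long <- purrr::map_dfr(scan_names, function(m) {
    tr <- object$tracks[[m]]
    tibble(metric = toupper(m), chrom = tr$chrom,
           pos = if ("start" %in% names(tr)) (tr$start + tr$end) / 2
                 else tr$pos,
           value = tr$value, outlier = tr$outlier,
           valid = if ("valid" %in% names(tr)) tr$valid else TRUE)
  })
  ggplot2::ggplot(long[long$valid, ],
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$value,
                               colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "outlier") +
    ggplot2::theme_minimal()
}
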