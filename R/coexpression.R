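# k-means co-expression clustering of candidate genes across tissues, with a
# centroid-level tissue-specificity rule (deviation beyond fold x sd across
# tissues) and a low-expression-cluster exclusion rule.

#' Cluster genes by tissue expression profile
#'
#' Rows are log2(x+1)-transformed and z-scored per gene (constant genes
#' become zero vectors, not dropped) before k-means; the best of `n_restarts`
#' random starts by within-cluster sum of squares is kept, deterministically
#' for a given seed.
#'
#' @param mat non-negative genes x tissues matrix (rownames = gene ids)
#' @param k number of clusters (default 10)
#' @param seed RNG seed
#' @param n_restarts k-means restarts
#' @return a `coexpr_report`: `assignments` (tibble gene_id, cluster),
#'   `centroid_z` (k x tissues, z-score space), `centroid_log` (k x tissues,
#'   mean log2(x+1) of member genes), `gene_log_means`, `tissues`,
#'   `low_expression` (flags, all FALSE until [drop_low_expression()]),
#'   `tot_withinss`
#' @export
cluster_expression <- function(mat, k = 10, seed = 1, n_restarts = 10) {
  stopifnot(k >= 1, k <= nrow(mat))
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  }
  lg <- log2(mat + 1)
  mu <- rowMeans(lg)
  sg <- apply(lg, 1L, sd)
  z <- (lg - mu) / ifelse(sg > 0, sg, 1)
  z[sg == 0, ] <- 0
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = n_restarts, iter.max = 100)
  centroid_log <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(lg[km$cluster == cl, , drop = FALSE])
  }))
  structure(
    list(assignments = tibble(gene_id = rownames(mat),
                              cluster = as.integer(km$cluster)),
         centroid_z = km$centers,
         centroid_log = centroid_log,
         gene_log_means = mu,
         tissues = colnames(mat),
         low_expression = rep(FALSE, k),
         tot_withinss = km$tot.withinss,
         k = k, seed = seed),
    class = "coexpr_report")
}

#' @export
print.coexpr_report <- function(x, ...) {
  cat("<coexpr_report> ", nrow(x$assignments), " genes in ", x$k,
      " clusters over ", length(x$tissues), " tissues\n", sep = "")
  if (any(x$low_expression)) {
    cat("low-expression clusters:",
        paste(which(x$low_expression), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tissue-specificity flags for a centroid matrix
#'
#' A cluster is specific for tissue `t` when
#' `|centroid_t - mean(centroid)| > fold * sd(centroid across tissues)`,
#' with the sign recording high-in-tissue vs low-in-tissue deviations. A
#' flat centroid (sd = 0) is never flagged (strict inequality).
#'
#' @param centroids clusters x tissues matrix
#' @param fold deviation multiplier (default 2)
#' @return tibble: `cluster`, `tissue`, `direction` (`"high"`/`"low"`),
#'   `deviation`
#' @export
tissue_specificity <- function(centroids, fold = 2.0) {
  tiss <- colnames(centroids) %||% paste0("t", seq_len(ncol(centroids)))
  purrr::map_dfr(seq_len(nrow(centroids)), function(cl) {
    v <- centroids[cl, ]
    dev <- v - mean(v)
    thr <- fold * sd(v)
    hit <- is.finite(thr) & abs(dev) > thr
    if (!any(hit)) return(tibble())
    tibble(cluster = cl, tissue = tiss[hit],
           direction = ifelse(dev[hit] > 0, "high", "low"),
           deviation = unname(dev[hit]))
  })
}

#' Tissue-specific clusters of a co-expression report
#'
#' Applies the twofold-of-sd rule to the cluster centroids in log-expression
#' space and propagates the flags to clusters; clusters flagged low
#' expression are excluded from tissue-specific calls.
#'
#' @param report a `coexpr_report`
#' @param fold deviation multiplier
#' @return tibble: `cluster`, `tissue`, `direction`, `deviation`
#' @export
tissue_specific_clusters <- function(report, fold = 2.0) {
  flags <- tissue_specificity(report$centroid_log, fold = fold)
  flags[!(flags$cluster %in% which(report$low_expression)), , drop = FALSE]
}

#' Flag low-expression clusters
#'
#' Clusters whose mean log-expression falls below the given quantile of the
#' gene-level log-means are flagged (retained in the report, but excluded
#' from tissue-specific gene lists).
#'
#' @param report a `coexpr_report`
#' @param quantile bottom quantile of gene-level means (default 0.1)
#' @return the report with `low_expression` updated
#' @export
drop_low_expression <- function(report, quantile = 0.1) {
  thr <- stats::quantile(report$gene_log_means, quantile, names = FALSE)
  report$low_expression <- rowMeans(report$centroid_log) < thr
  report
}

#' Tissue-specific genes
#'
#' Member genes of tissue-specific clusters (low-expression clusters
#' excluded).
#'
#' @param report a `coexpr_report`
#' @param fold deviation multiplier
#' @return tibble: `gene_id`, `cluster`, `tissue`, `direction`
#' @export
tissue_specific_genes <- function(report, fold = 2.0) {
  flags <- tissue_specific_clusters(report, fold = fold)
  if (nrow(flags) == 0L) {
    return(tibble(gene_id = character(), cluster = integer(),
                  tissue = character(), direction = character()))
  }
  inner_join(report$assignments, flags, by = "cluster") |>
    select("gene_id", "cluster", "tissue", "direction")
}
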