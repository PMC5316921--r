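# Genotype PCA with the standard allele-frequency normalization: dosages are
# mean-imputed, centred by 2*p_hat and scaled by sqrt(2*p_hat*(1-p_hat));
# sample coordinates are the left singular vectors scaled by the singular
# values (equivalently, eigenvectors of the sample covariance scaled by the
# square roots of its eigenvalues).

#' Genotype principal component analysis
#'
#' @param gset a `genotype_set`
#' @param n_components number of components to return
#' @return a `sweep_pca` object with `scores` (tibble: sample, population,
#'   PC1..), `explained` (proportion of variance per component), `sdev`, and
#'   `n_sites` used
#' @export
pca_genotypes <- function(gset, n_components = 2) {
  X <- t(gset$dosage)  # samples x sites
  n <- nrow(X)
  if (n_components > n) {
    abort("fewer samples than requested components")
  }
  # mean-impute missing dosages per site
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z, nu = n_components, nv = 0)
  d <- sv$d
  scores <- sv$u %*% diag(d[seq_len(n_components)], n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(
    list(scores = bind_cols(tibble(sample = gset$samples,
                                   population = unname(gset$pops)),
                            as_tibble(scores)),
         sdev = d / sqrt(max(n - 1, 1)),
         explained = d^2 / sum(d^2),
         n_sites = sum(keep), n_components = n_components),
    class = "sweep_pca"
  )
}

#' @export
print.sweep_pca <- function(x, ...) {
  cat("<sweep_pca> ", nrow(x$scores), " samples, ", x$n_sites, " sites; ",
      "PC1 ", sprintf("%.1f%%", 100 * x$explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * x$explained[2]), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sweep_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score")
}

#' @exportS3Method generics::glance
glance.sweep_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_sites = x$n_sites,
         var_pc1 = x$explained[1],
         var_pc2 = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sweep_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}
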