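# Synthetic-data generator: a two-population Wright-Fisher forward simulator
# (burn-in, split, drift, mutation, recombination, optional hard sweep
# conditioned on fixation) plus a fast frequency-only drift simulator and a
# tissue-expression simulator. Forward simulation keeps sweeps, conditioning
# and LD exact by construction; a desk-scale guard (N <= 1000, L <= 1 Mb)
# keeps runs in seconds-to-minutes.

#' Simulation configuration
#'
#' Defaults are scaled-population study conditions: N = 200 diploids, 500 kb,
#' mu = 1e-6 and r = 1e-6 per bp per generation (rho/theta = 1, so haplotype
#' blocks span tens of kb and a hard sweep's hitchhiking extent is about one
#' 100-kb analysis window), burn-in of 2N generations, a 40-generation neutral split, and 30
#' sampled individuals per population. The sweep, when given, is a list with
#' `pos` (bp), `s` (additive selection coefficient; fitnesses 1, 1+s/2, 1+s),
#' `start` (generation after the split at which the allele is seeded at count
#' 1 in the test population) and `condition_on_fixation` (restart the
#' test-population trajectory, with the RNG running on, until the allele
#' fixes).
#'
#' @param N diploid population size (<= 1000)
#' @param L sequence length in bp (<= 1e6)
#' @param mu per-site per-generation mutation rate
#' @param r per-adjacent-bp per-generation crossover probability
#' @param t_burn burn-in generations before the split
#' @param t_split generations each daughter population evolves after the split
#' @param sweep `NULL` or `list(pos, s, start, condition_on_fixation)`
#' @param n_sample diploid individuals sampled per population
#' @param seed integer RNG seed
#' @param pop_names names of the reference and test populations
#' @return a `sim_config` list
#' @export
sim_config <- function(N = 200, L = 500000, mu = 1e-6, r = 1e-6,
                       t_burn = 2 * N, t_split = 40, sweep = NULL,
                       n_sample = 30, seed = 1,
                       pop_names = c(ref = "landrace", test = "weedy")) {
  stopifnot(N >= 2, N <= 1000, L >= 1, L <= 1e6, mu >= 0, r >= 0,
            n_sample >= 1, n_sample <= N)
  if (!is.null(sweep)) {
    sweep <- modifyList(list(pos = floor(L / 2), s = 0.5, start = 0,
                             condition_on_fixation = TRUE), sweep)
    if (sweep$pos >= L) abort("sweep position must be < L")
    if (sweep$pos < 1) abort("sweep position must be >= 1")
  }
  structure(list(N = N, L = L, mu = mu, r = r, t_burn = t_burn,
                 t_split = t_split, sweep = sweep, n_sample = n_sample,
                 seed = seed, pop_names = pop_names),
            class = "sim_config")
}

#' Simulate two diverged populations
#'
#' Runs the forward simulator under `config` and packages the sampled phased
#' haplotypes as a `haplotype_set`, the derived diploid dosages as a
#' `genotype_set`, and the sweep ground truth. When `out_dir` is given, a
#' phased VCF, a genetic-map TSV (the simulator's own uniform map,
#' `cM/Mb = 1e8 * r`), a GFF3 of genes tiled every 20 kb (length 5 kb) and a
#' truth JSON are written there deterministically.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory for VCF/map/GFF/truth files
#' @return a list: `haplotypes`, `genotypes`, `truth` (sweep position, s,
#'   fixation status, final frequency, split time, realized FST), `map`,
#'   `genes`, and `files` when written
#' @export
simulate_populations <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sw <- config$sweep
  res <- wf_simulate_cpp(
    config$N, config$L, config$mu, config$r, config$t_burn, config$t_split,
    if (is.null(sw)) -1L else as.integer(sw$pos),
    if (is.null(sw)) 0 else sw$s,
    if (is.null(sw)) 0L else as.integer(sw$start),
    if (is.null(sw)) FALSE else isTRUE(sw$condition_on_fixation),
    500L, config$n_sample, config$n_sample)

  ref_name <- config$pop_names[["ref"]]
  test_name <- config$pop_names[["test"]]
  samples <- c(sprintf("%s_%02d", ref_name, seq_len(config$n_sample)),
               sprintf("%s_%02d", test_name, seq_len(config$n_sample)))
  pops <- setNames(rep(c(ref_name, test_name), each = config$n_sample),
                   samples)
  chrom <- "chr1"
  npos <- length(res$pos)
  # alternating REF/ALT bases keep records valid without storing sequence
  sites <- tibble(chrom = chrom, pos = as.integer(res$pos),
                  ref = rep_len(c("A", "C"), npos),
                  alt = rep_len(c("G", "T"), npos))
  H <- res$H
  colnames(H) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  chrom_lengths <- setNames(config$L, chrom)
  hset <- new_haplotype_set(H, sites, samples, pops, chrom_lengths)
  n <- length(samples)
  dosage <- H[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
    H[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  colnames(dosage) <- samples
  gset <- new_genotype_set(dosage, sites, samples, pops, chrom_lengths)

  map <- uniform_map(rate_cM_per_Mb = config$r * 1e8)
  genes <- tile_genes(chrom, config$L)
  fst <- fst_sites(gset, ref_name, test_name)
  realized_fst <- {
    ok <- fst$valid
    if (any(ok)) sum(fst$a[ok]) / sum((fst$a + fst$b + fst$c)[ok]) else NA_real_
  }
  truth <- list(
    sweep_pos = if (is.null(sw)) NA_integer_ else sw$pos,
    s = if (is.null(sw)) NA_real_ else sw$s,
    fixed = isTRUE(res$sweep_fixed),
    final_freq = res$sweep_final_freq,
    split_time = config$t_split,
    realized_fst = realized_fst,
    tries = res$tries,
    seed = config$seed
  )
  out <- list(haplotypes = hset, genotypes = gset, truth = truth, map = map,
              genes = genes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      vcf = file.path(out_dir, "sim.vcf"),
      map = file.path(out_dir, "sim.map.tsv"),
      gff = file.path(out_dir, "sim.gff3"),
      pops = file.path(out_dir, "sim.pops.tsv"),
      truth = file.path(out_dir, "sim.truth.json")
    )
    write_vcf(hset, files$vcf)
    rate_cM <- config$r * 1e8
    writeLines(c("chrom\tpos\tcM",
                 sprintf("%s\t%d\t%.8f", chrom, c(0L, as.integer(config$L)),
                         c(0, config$L / 1e6 * rate_cM))), files$map)
    write_gff3(genes, files$gff, chrom_lengths)
    writeLines(c("sample\tpopulation",
                 paste(samples, unname(pops), sep = "\t")), files$pops)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    out$files <- files
  }
  out
}

# deterministic toy gene models: one 5-kb gene every 20 kb
tile_genes <- function(chrom, L, every = 20000, len = 5000) {
  starts <- seq(1, L, by = every)
  starts <- starts[starts + len - 1 <= L]
  tibble(gene_id = sprintf("gene%04d", seq_along(starts)),
         chrom = chrom, start = as.integer(starts),
         end = as.integer(starts + len - 1), strand = "+")
}

write_gff3 <- function(genes, path, chrom_lengths = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(chrom_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                              names(chrom_lengths),
                              as.integer(chrom_lengths)))
  }
  lines <- c(lines, sprintf("%s\tsweepscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            genes$chrom, genes$start, genes$end,
                            genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Fast frequency-only drift simulator
#'
#' Ancestral frequencies are drawn from a neutral-SFS-shaped grid
#' (probability proportional to 1/x on `x = 1/(2N), ..., (2N-1)/(2N)`; or
#' uniform). The test branch then evolves by `T` binomial(2N) resampling
#' steps and the reference branch by `t_ref` steps -- by default 0, i.e. the
#' reference tracks the ancestral frequency, which is exactly the
#' test-around-reference drift the XP-CLR omega parameter measures. Fixation
#' is absorbing.
#'
#' @param n_sites number of independent sites
#' @param N diploid population size
#' @param T_gen generations of drift on the test branch
#' @param t_ref generations of drift on the reference branch (default 0)
#' @param seed optional RNG seed (the session RNG is used when `NULL`)
#' @param sfs_shape `"neutral"` (1/x) or `"uniform"`
#' @return a tibble with `p_anc`, `p_ref`, `p_test`
#' @export
drift_only <- function(n_sites, N, T_gen, t_ref = 0, seed = NULL,
                       sfs_shape = c("neutral", "uniform")) {
  sfs_shape <- match.arg(sfs_shape)
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(2 * N - 1) / (2 * N)
  w <- if (sfs_shape == "neutral") 1 / (x * 2 * N) else rep(1, length(x))
  p0 <- sample(x, n_sites, replace = TRUE, prob = w / sum(w))
  drift <- function(p, steps) {
    for (i in seq_len(steps)) p <- rbinom(length(p), 2 * N, p) / (2 * N)
    p
  }
  tibble(p_anc = p0, p_ref = drift(p0, t_ref), p_test = drift(p0, T_gen))
}

#' Simulate a tissue expression matrix with planted clusters
#'
#' Cluster centroids are drawn in log2 space with optional single-tissue
#' spikes (every other cluster gets one, +4 log2 units in a deterministic
#' tissue); one low-mean cluster is included by default. Gene profiles are
#' centroid + Gaussian noise, returned on the raw scale (`2^x - 1`).
#'
#' @param n_genes number of genes
#' @param n_tissues number of tissues (default 11)
#' @param n_clusters number of planted clusters
#' @param seed RNG seed
#' @param noise_sd per-tissue Gaussian noise sd in log2 units
#' @param low_cluster include one low-expression cluster
#' @return a list: `matrix` (genes x tissues, non-negative), `labels` (true
#'   cluster per gene), `centroids` (log2 scale)
#' @export
expression_sim <- function(n_genes = 400, n_tissues = 11, n_clusters = 10,
                           seed = 1, noise_sd = 0.5, low_cluster = TRUE) {
  stopifnot(n_clusters >= 1, n_genes >= n_clusters)
  set.seed(seed)
  tissues <- c("leaf_blade", "leaf_sheath", "root", "stem", "inflorescence",
               "anther", "pistil", "lemma", "palea", "embryo", "endosperm")
  tissues <- if (n_tissues <= length(tissues)) {
    tissues[seq_len(n_tissues)]
  } else {
    c(tissues, sprintf("tissue%02d", seq_len(n_tissues - length(tissues))))
  }
  centroids <- matrix(0, n_clusters, n_tissues,
                      dimnames = list(NULL, tissues))
  for (k in seq_len(n_clusters)) {
    base <- runif(1, 4, 8)
    centroids[k, ] <- base + rnorm(n_tissues, 0, 1)
    if (k %% 2L == 1L) {  # single-tissue spike
      centroids[k, (k - 1L) %% n_tissues + 1L] <-
        centroids[k, (k - 1L) %% n_tissues + 1L] + 4
    }
  }
  if (low_cluster) centroids[n_clusters, ] <- runif(n_tissues, 0.1, 0.5)
  labels <- rep(seq_len(n_clusters), length.out = n_genes)
  logx <- centroids[labels, , drop = FALSE] +
    matrix(rnorm(n_genes * n_tissues, 0, noise_sd), n_genes, n_tissues)
  mat <- pmax(2^logx - 1, 0)
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  colnames(mat) <- tissues
  list(matrix = mat, labels = labels, centroids = centroids)
}
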