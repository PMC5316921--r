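# Empirical outlier calling, gene mapping, candidate intersection, flanks.

make_track <- function(values, valid = TRUE, chrom = "chr1") {
  n <- length(values)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 1e5,
                 end = seq_len(n) * 1e5, value = values,
                 valid = rep_len(valid, n))
}

test_that("call_outliers flags exactly ceiling(q*M) valid records", {
  set.seed(1)
  tr <- call_outliers(make_track(rnorm(200)), q = 0.025)
  expect_equal(sum(tr$outlier), 5L)
  expect_equal(sum(call_outliers(make_track(rnorm(40)), 0.025)$outlier), 1L)
  # invalid records neither count towards M nor get flagged
  tr2 <- make_track(rnorm(100), valid = c(rep(TRUE, 60), rep(FALSE, 40)))
  out2 <- call_outliers(tr2, 0.025)
  expect_equal(sum(out2$outlier), ceiling(0.025 * 60))
  expect_true(all(!out2$outlier[!out2$valid]))
  expect_error(call_outliers(make_track(rnorm(10)), q = 0), "q must")
  # property over many (M, q)
  for (M in c(1, 7, 39, 40, 41, 199)) {
    for (q in c(0.01, 0.025, 0.3)) {
      got <- sum(call_outliers(make_track(rnorm(M)), q)$outlier)
      expect_equal(got, ceiling(q * M))
    }
  }
})

test_that("ties at the outlier boundary break by genomic order, reproducibly", {
  vals <- c(rep(5, 10), rnorm(90))           # ten tied at the top value
  tr <- make_track(vals)
  got1 <- call_outliers(tr, q = 0.025)        # 3 outliers among the tie
  got2 <- call_outliers(tr, q = 0.025)
  expect_identical(got1$outlier, got2$outlier)
  expect_equal(which(got1$outlier), 1:3)      # genomic-order prefix
  # lower and two-sided tails
  lo <- call_outliers(make_track(c(-9, 1, 2, 3)), 0.25, tail = "lower")
  expect_equal(which(lo$outlier), 1L)
  ab <- call_outliers(make_track(c(-9, 1, 2, 3)), 0.25,
                      tail = "two_sided_abs")
  expect_equal(which(ab$outlier), 1L)
})

test_that("outliers_to_genes follows the overlap and flank rules", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(1000L, 3000L), end = c(2000L, 4000L),
                          strand = "+")
  # window [1500, 2500) overlaps g1 by >= 1 bp
  tr <- tibble::tibble(chrom = "chr1", start = 1500, end = 2500,
                       value = 1, valid = TRUE, outlier = TRUE)
  expect_equal(outliers_to_genes(tr, genes), "g1")
  # site at 2500: flank 0 excludes g2, flank 600 includes it
  st <- tibble::tibble(chrom = "chr1", pos = 2500L, value = 1,
                       valid = TRUE, outlier = TRUE)
  expect_equal(outliers_to_genes(st, genes), character())
  # flank 600 reaches g2 (3000..4000) and also back onto g1 (1000..2000)
  fl <- outliers_to_genes(st, genes, flank_bp = 600)
  expect_true("g2" %in% fl)
  expect_equal(fl, c("g1", "g2"))
})

test_that("outliers_to_genes equals the all-pairs overlap oracle", {
  set.seed(19)
  for (rep in 1:10) {
    n_gene <- sample(50:300, 1)
    gs <- sort(sample.int(5e6, n_gene))
    genes <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_gene)),
                            chrom = "chr1", start = gs,
                            end = gs + sample(500:5000, n_gene, TRUE),
                            strand = "+")
    n_out <- sample(20:150, 1)
    ws <- sort(sample(seq(0, 5e6, by = 1e4), n_out))
    tr <- tibble::tibble(chrom = "chr1", start = ws, end = ws + 1e4,
                         value = 1, valid = TRUE, outlier = TRUE)
    got <- outliers_to_genes(tr, genes)
    ora <- oracle_overlap_genes(genes, ws + 1, ws + 1e4, "chr1")
    expect_equal(got, ora)
  }
})

test_that("candidate_genes intersects per-metric sets by support", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g4")
  expect_equal(candidate_genes(sets, 2)$gene_id, "g2")
  u <- candidate_genes(sets, 1)
  expect_equal(u$gene_id, c("g1", "g2", "g3", "g4"))
  expect_equal(u$n_support, c(1L, 2L, 1L, 1L))
  expect_equal(u$metrics[u$gene_id == "g2"], "A,B")
  expect_error(candidate_genes(sets["A"]), "two")
})

test_that("candidate_genes equals brute-force membership counting", {
  set.seed(23)
  universe <- sprintf("gene%04d", 1:1000)
  sets <- lapply(setNames(1:5, paste0("m", 1:5)),
                 function(i) sample(universe, 100))
  got <- candidate_genes(sets, min_support = 2)
  counts <- table(unlist(lapply(sets, unique)))
  ora <- sort(names(counts)[counts >= 2])
  expect_equal(got$gene_id, ora)
  expect_equal(got$n_support, as.integer(counts[ora]), ignore_attr = TRUE)
  # min_support 1 is the union; min_support 5 is inside every set
  expect_equal(candidate_genes(sets, 1)$gene_id,
               sort(unique(unlist(sets))))
  top <- candidate_genes(sets, 5)$gene_id
  for (s in sets) expect_true(all(top %in% s))
})

test_that("flank_genes returns genes intersecting the locus flank", {
  genes <- tibble::tibble(
    gene_id = c("near", "far"), chrom = "chr7",
    start = c(2e6 + 5e5, 2e6 + 7e5), end = c(2e6 + 5e5 + 1e3, 2e6 + 7e5 + 1e3),
    strand = "+")
  got <- flank_genes(genes, "chr7", 2e6, flank_bp = 6e5)
  expect_equal(got$gene_id, "near")
  # brute-force check on a tiled chromosome
  tiled <- tibble::tibble(gene_id = sprintf("t%02d", 1:50), chrom = "chr1",
                          start = (0:49) * 2e4 + 1, end = (0:49) * 2e4 + 5e3,
                          strand = "+")
  got2 <- flank_genes(tiled, "chr1", 5e5, flank_bp = 1e5)
  ora <- tiled$gene_id[tiled$start <= 6e5 & tiled$end >= 4e5]
  expect_equal(got2$gene_id, ora)
})

test_that("metric_overlap reports per-metric and support-level counts", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"))
  ov <- metric_overlap(sets)
  expect_equal(unname(ov$per_metric), c(2L, 2L))
  expect_equal(ov$by_support$n_genes, c(2L, 1L))
})
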