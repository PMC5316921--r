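# VCF/GFF/map readers, the site filter, and the windowing engine.

toy_vcf_lines <- function(records, samples = c("sA", "sB")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

two_pop_table <- function(samples = c("sA", "sB"),
                          pops = c("landrace", "weedy")) {
  tibble::tibble(sample = samples, population = pops)
}

test_that("a toy phased VCF parses to the hand-derived dosages and haplotypes", {
  path <- write_toy_vcf(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|1")))
  v <- read_vcf(path, two_pop_table())
  expect_equal(v$n_skipped, 0L)
  expect_true(v$phased)
  expect_equal(unname(v$genotypes$dosage[, "sA"]), c(1L, 2L))
  expect_equal(unname(v$genotypes$dosage[, "sB"]), c(0L, 1L))
  # haplotype columns: sA_1, sA_2, sB_1, sB_2
  expect_equal(unname(v$haplotypes$hap[1, ]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(v$haplotypes$hap[2, ]), c(1L, 1L, 0L, 1L))
  expect_equal(v$genotypes$sites$pos, c(100L, 200L))
  expect_equal(v$genotypes$chrom_lengths, c(chr1 = 10000))
})

test_that("non-biallelic-SNP records are skipped, never split", {
  path <- write_toy_vcf(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "chr1\t150\t.\tA\tG,T\t.\tPASS\t.\tGT\t1|2\t0|0",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1\t0|0")))
  v <- suppressMessages(read_vcf(path, two_pop_table()))
  expect_equal(v$n_skipped, 2L)
  expect_equal(nrow(v$genotypes$sites), 1L)
})

test_that("a VCF with zero variant records yields an empty genotype set", {
  path <- write_toy_vcf(toy_vcf_lines(character()))
  v <- read_vcf(path, two_pop_table())
  expect_equal(nrow(v$genotypes$sites), 0L)
  expect_equal(dim(v$genotypes$dosage), c(0L, 2L))
})

test_that("unknown samples and malformed genotypes are reported", {
  path <- write_toy_vcf(toy_vcf_lines(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0"))
  expect_error(read_vcf(path, two_pop_table(c("sA", "sZ"))), "absent")
  bad <- write_toy_vcf(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT\t0|x\t0|0")))
  expect_error(read_vcf(bad, two_pop_table()), "record 2")
})

test_that("unphased or incomplete genotypes do not produce a haplotype set", {
  path <- write_toy_vcf(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.")))
  v <- read_vcf(path, two_pop_table())
  expect_false(v$phased)
  expect_null(v$haplotypes)
  expect_true(is.na(v$genotypes$dosage[2, "sB"]))
  expect_equal(v$genotypes$sites$missing_count, c(0L, 1L))
})

test_that("write_vcf round-trips genotypes bit-exactly and deterministically", {
  path <- write_toy_vcf(toy_vcf_lines(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|1")))
  v1 <- read_vcf(path, two_pop_table())
  out1 <- tempfile(fileext = ".vcf")
  out2 <- tempfile(fileext = ".vcf")
  write_vcf(v1$haplotypes, out1)
  v2 <- read_vcf(out1, two_pop_table())
  expect_identical(v2$haplotypes$hap, v1$haplotypes$hap)
  expect_identical(v2$genotypes$sites$pos, v1$genotypes$sites$pos)
  write_vcf(v2$haplotypes, out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("filter_sites applies the no-missing / MAF >= 0.05 rule with a kept boundary", {
  # 10 diploids; site 2 has one missing call, site 3 has maf exactly 0.05
  d <- matrix(0L, nrow = 4, ncol = 10)
  d[1, 1:5] <- 1L            # maf 0.25
  d[2, 1] <- NA_integer_     # missing -> removed under max_missing = 0
  d[2, 2:6] <- 1L
  d[3, 1] <- 1L              # 1/20 = 0.05 exactly -> kept
  # site 4 monomorphic: maf 0 -> removed
  g <- toy_gset(d)
  f <- filter_sites(g, max_missing = 0, min_maf = 0.05)
  expect_equal(f$sites$pos, c(100L, 300L))
  expect_identical(filter_sites(f, 0, 0.05)$sites, f$sites)  # idempotent
})

test_that("filter_sites agrees with per-site brute-force re-testing", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 8
    d <- matrix(sample(c(0L, 1L, 2L, NA), 10 * n, replace = TRUE,
                       prob = c(.45, .25, .2, .1)), nrow = 10)
    g <- toy_gset(d)
    f <- filter_sites(g, max_missing = 0.1, min_maf = 0.05)
    keep <- vapply(seq_len(10), function(i) {
      row <- d[i, ]
      miss <- sum(is.na(row)) / n
      called <- 2 * sum(!is.na(row))
      p <- sum(row, na.rm = TRUE) / called
      maf <- min(p, 1 - p)
      miss <= 0.1 && !is.na(maf) && maf >= 0.05
    }, logical(1))
    expect_equal(f$sites$pos, g$sites$pos[keep])
  }
})

test_that("make_windows tiles chromosomes, including partial final windows", {
  w <- make_windows(c(chr1 = 250000))
  expect_equal(nrow(w), 3L)
  expect_equal(w$start[3], 200000)
  expect_equal(w$end[3], 250000)
  expect_equal(nrow(make_windows(c(chr1 = 100000))), 1L)
  ws <- make_windows(c(chr1 = 250000), size = 100000, step = 50000)
  starts <- seq(0, 250000 - 1, by = 50000)  # brute-force enumeration
  expect_equal(ws$start, starts[starts < 250000])
  expect_equal(ws$end, pmin(starts + 100000, 250000))
  # non-overlapping tiling covers [0, L) with no gaps
  w2 <- make_windows(c(chr1 = 330001), size = 25000)
  expect_equal(w2$start[-1], w2$end[-nrow(w2)])
  expect_equal(w2$end[nrow(w2)], 330001)
  expect_error(make_windows(c(chr1 = 0)), "positive")
  expect_error(make_windows(c(chr1 = 1000), size = 10, step = 20))
})

test_that("read_gff keeps gene features with native 1-based coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
               "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=geneA.1",
               "chr1\tsrc\tgene\t5000\t6000\t.\t-\t.\tID=geneB"), gff)
  g <- read_gff(gff)
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$start, c(1000L, 5000L))
  expect_equal(g$end, c(2000L, 6000L))
  expect_equal(g$strand, c("+", "-"))
})

test_that("genetic maps interpolate linearly and reject unsorted anchors", {
  u <- uniform_map(4.0)
  expect_equal(map_cM(u, "chr1", 1e6) - map_cM(u, "chr1", 0), 4.0)
  expect_equal(map_cM(u, "chr1", 250000) - map_cM(u, "chr1", 0), 1.0)
  anc <- tibble::tibble(chrom = "chr1", pos = c(0, 1e6), cM = c(0, 2))
  m <- sweepscan:::genetic_map_from_anchors(anc)
  expect_equal(map_cM(m, "chr1", 5e5), 1.0)
  # monotone: pos_a <= pos_b implies cM_a <= cM_b
  ps <- sort(runif(50, -1e5, 1.2e6))
  expect_true(all(diff(map_cM(m, "chr1", ps)) >= 0))
  bad <- tibble::tibble(chrom = "chr1", pos = c(1e6, 0), cM = c(0, 2))
  expect_error(sweepscan:::genetic_map_from_anchors(bad), "increasing")
  mapfile <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tcM", "chr1\t0\t0", "chr1\t1000000\t2"), mapfile)
  expect_equal(map_cM(read_genetic_map(mapfile), "chr1", 5e5), 1.0)
})
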