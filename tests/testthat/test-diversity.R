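# Windowed pi, ROD, the WC84 FST estimator, LD decay, and genotype PCA.

test_that("window_pi reproduces hand-computed site terms", {
  # 1000-bp window, 4 haplotypes, alt counts 1 and 2:
  # (4/3)*2*(1/4)*(3/4) + (4/3)*2*(1/2)*(1/2) = 0.5 + 0.6667
  hap <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0))
  hs <- toy_hapset(hap, pos = c(150L, 600L))
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  tr <- window_pi(hs, "pop1", w)
  expect_equal(tr$pi, (0.5 + 2 / 3) / 1000, tolerance = 1e-12)
  expect_equal(tr$n_snps, 2L)
  # monomorphic window
  hs0 <- toy_hapset(rbind(c(0, 0, 0, 0)), pos = 100L)
  expect_equal(window_pi(hs0, "pop1", w)$pi, 0)
  # all-heterozygote single site from dosages: p = 0.5, n = 4 haplotypes
  g <- toy_gset(rbind(c(1L, 1L)), pos = 100L)
  expect_equal(window_pi(g, "pop1", w)$pi * 1000, (4 / 3) * 0.5,
               tolerance = 1e-12)
})

test_that("window_pi equals the pairwise-difference oracle on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    n_hap <- 2 * sample(1:5, 1)          # <= 10 haplotypes
    n_site <- sample(1:20, 1)
    L <- 2000
    hap <- matrix(rbinom(n_site * n_hap, 1, runif(1, 0.1, 0.9)),
                  nrow = n_site)
    pos <- sort(sample.int(L, n_site))
    hs <- toy_hapset(hap, pos = pos)
    w <- tibble::tibble(chrom = "chr1", start = 0, end = L)
    got <- window_pi(hs, "pop1", w)$pi
    expect_equal(got, oracle_pi(hap, L), tolerance = 1e-12)
  }
})

test_that("rod follows its limits and flags invalid windows", {
  w <- tibble::tibble(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  tr_ref <- dplyr::mutate(w, pi = c(1e-3, 0), n_snps = c(50L, 12L),
                          n_skipped = 0L)
  tr_test <- dplyr::mutate(w, pi = c(1e-3, 1e-4), n_snps = c(50L, 12L),
                           n_skipped = 0L)
  r <- rod(tr_ref, tr_test)
  expect_equal(r$rod[1], 0)
  expect_false(r$valid[2])       # pi_ref = 0 -> excluded from ranking
  tr_test2 <- dplyr::mutate(tr_test, pi = c(0, 1e-4))
  expect_equal(rod(tr_ref, tr_test2)$rod[1], 1)  # pi_test = 0 -> ROD = 1
  # low-SNP windows flagged
  tr_ref3 <- dplyr::mutate(tr_ref, pi = c(1e-3, 1e-3), n_snps = c(50L, 3L))
  expect_false(rod(tr_ref3, tr_test)$valid[2])
  expect_error(rod(tr_ref, tr_test[2:1, ]), "identical")
})

test_that("wc_fst_site collapses to theta = 1 for a fixed difference", {
  wc <- wc_fst_site(10, 10, 1, 0, 0, 0)
  expect_equal(wc$b, 0)
  expect_equal(wc$c, 0)
  expect_gt(wc$a, 0)
  expect_equal(wc$theta, 1)
  # both populations monomorphic for the same allele -> undefined
  expect_false(wc_fst_site(10, 10, 0, 0, 0, 0)$valid)
})

test_that("wc_fst_site matches an independent transcription on random tables", {
  set.seed(11)
  for (rep in 1:200) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    a1 <- sample(0:(2 * n1), 1); a2 <- sample(0:(2 * n2), 1)
    p1 <- a1 / (2 * n1); p2 <- a2 / (2 * n2)
    h1 <- sample(0:min(a1, 2 * n1 - a1), 1) / n1
    h2 <- sample(0:min(a2, 2 * n2 - a2), 1) / n2
    got <- wc_fst_site(n1, n2, p1, p2, h1, h2)
    ora <- oracle_wc(n1, n2, p1, p2, h1, h2)
    expect_equal(got$a, ora$a, tolerance = 1e-12)
    expect_equal(got$b, ora$b, tolerance = 1e-12)
    expect_equal(got$c, ora$c, tolerance = 1e-12)
    if (got$valid) expect_equal(got$theta, ora$theta, tolerance = 1e-12)
    # invariance under swapping population labels
    swp <- wc_fst_site(n2, n1, p2, p1, h2, h1)
    expect_equal(got$a, swp$a, tolerance = 1e-12)
    expect_equal(got$theta, swp$theta, tolerance = 1e-12)
  }
})

test_that("windowed FST is the ratio of averages, not the average of ratios", {
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  sc <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                       a = c(1, 0), b = c(0, 3), c = c(0, 1),
                       valid = TRUE)
  got <- windowed_fst(sc, w)
  expect_equal(got$fst, 0.2)                        # (1+0)/(1+4)
  expect_false(isTRUE(all.equal(got$fst, mean(c(1, 0)))))  # mean of ratios 0.5
  # single-site window equals that site's theta
  one <- windowed_fst(sc[1, ], w)
  expect_equal(one$fst, 1)
  # all sites undefined -> window undefined
  sc$valid <- FALSE
  expect_false(windowed_fst(sc, w)$valid)
})

test_that("LD r2 matches hand calculations and half-decay applies its rule", {
  # two identical sites -> r2 = 1 (phased and unphased paths)
  hap <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  hs <- toy_hapset(hap, pos = c(100L, 600L))
  cv <- ld_curve(hs, "pop1", max_dist_bp = 1000, bin_width_bp = 1000)
  expect_equal(cv$mean_r2, 1)
  g <- toy_gset(rbind(c(2L, 1L, 0L), c(2L, 1L, 0L)), pos = c(100L, 600L))
  expect_equal(ld_curve(g, "pop1", 1000, 1000)$mean_r2, 1)
  # complete coupling AB/AB/ab/ab: D = 0.25, r2 = 1
  hap2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  p11 <- mean(hap2[1, ] * hap2[2, ])
  expect_equal(p11 - 0.5 * 0.5, 0.25)
  expect_equal(ld_curve(toy_hapset(hap2, pos = c(10L, 20L)), "pop1",
                        100, 100)$mean_r2, 1)
  # half-decay: first bin whose mean drops to half the curve maximum
  curve <- tibble::tibble(bin_start = c(0, 10, 20, 30) * 1000,
                          bin_end = c(10, 20, 30, 40) * 1000,
                          mid = c(5, 15, 25, 35) * 1000,
                          mean_r2 = c(0.6, 0.4, 0.25, 0.2),
                          n_pairs = 10L)
  expect_equal(half_decay(curve), 25000)
})

test_that("pca_genotypes matches a direct eigendecomposition and block structure", {
  set.seed(5)
  # duplicated sample -> identical coordinates
  d <- matrix(sample(0:2, 40, replace = TRUE), nrow = 10, ncol = 4)
  d <- cbind(d, d[, 4])
  p <- pca_genotypes(toy_gset(d), n_components = 2)
  expect_equal(unlist(p$scores[5, c("PC1", "PC2")]),
               unlist(p$scores[4, c("PC1", "PC2")]), tolerance = 1e-9)
  # two internally-identical populations differing at many sites
  blk <- cbind(matrix(0L, 30, 4), matrix(2L, 30, 4))
  pops <- rep(c("A", "B"), each = 4)
  pb <- pca_genotypes(toy_gset(blk, populations = pops), 2)
  pc1 <- pb$scores$PC1
  expect_true(all(sign(pc1[1:4]) != sign(pc1[5:8])))
  expect_equal(sd(pc1[1:4]), 0, tolerance = 1e-9)
  expect_equal(sd(pc1[5:8]), 0, tolerance = 1e-9)
  # random matrix vs explicit covariance eigendecomposition
  X <- matrix(sample(0:2, 120, replace = TRUE), nrow = 20, ncol = 6)
  g <- toy_gset(X)
  got <- pca_genotypes(g, 3)
  Xs <- t(X)
  pf <- colMeans(Xs) / 2
  keep <- pf > 0 & pf < 1
  Z <- sweep(Xs[, keep], 2, 2 * pf[keep], "-")
  Z <- sweep(Z, 2, sqrt(2 * pf[keep] * (1 - pf[keep])), "/")
  ev <- eigen(Z %*% t(Z))
  for (k in 1:3) {
    ora <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_equal(abs(got$scores[[paste0("PC", k)]]), abs(ora),
                 tolerance = 1e-8)
  }
  expect_equal(got$explained[1:3],
               (ev$values / sum(pmax(ev$values, 0)))[1:3], tolerance = 1e-8)
  expect_error(pca_genotypes(g, 10), "components")
})
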