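# VCF and population-table input/output. Parsing goes through vcfR; writing is
# an in-package plain-text VCF 4.2 emitter so that identical inputs produce
# byte-identical files (a determinism guarantee the pipeline relies on).

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns `sample` and `population` (header optional;
#'   two unnamed columns are taken in that order)
#' @return a tibble with columns `sample`, `population`
#' @export
read_pop_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("sample", "population")
  as_tibble(tab[, 1:2])
}

#' Read a multi-sample VCF into genotype (and haplotype) sets
#'
#' Parses a VCF 4.x file, keeps biallelic SNP records only (everything else is
#' skipped with a reported count), and returns diploid dosages. When every
#' genotype is phased (`|` separator) and complete, a phased
#' [haplotype_set][read_vcf] is returned alongside.
#'
#' @param path VCF file (plain text or bgzip)
#' @param populations a data frame with columns `sample` and `population`, or
#'   a named character vector (names = samples); every listed sample must be
#'   present in the VCF and samples are returned in this order
#' @return a list with elements `genotypes` (genotype_set), `haplotypes`
#'   (haplotype_set or NULL when not fully phased), `n_skipped` (records
#'   dropped by the biallelic-SNP rule) and `phased` (logical)
#' @export
read_vcf <- function(path, populations) {
  pops <- as_pop_map(populations)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)

  chrom_lengths <- vcf_contig_lengths(v)

  if (n_rec == 0L) {
    empty <- tibble(chrom = character(), pos = integer(),
                    ref = character(), alt = character())
    gset <- new_genotype_set(
      matrix(integer(), 0L, length(pops), dimnames = list(NULL, names(pops))),
      empty, names(pops), pops, chrom_lengths)
    return(list(genotypes = gset, haplotypes = NULL, n_skipped = 0L,
                phased = FALSE))
  }

  ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                   n_skipped))
  }

  gt_all <- v@gt
  vcf_samples <- colnames(gt_all)[-1L]
  missing_samples <- setdiff(names(pops), vcf_samples)
  if (length(missing_samples) > 0L) {
    abort(paste0("samples in the population table are absent from the VCF: ",
                 paste(missing_samples, collapse = ", ")))
  }

  keep <- which(ok)
  fmt <- gt_all[keep, 1L]
  gt <- gt_all[keep, names(pops), drop = FALSE]
  # GT is the first colon-separated subfield per VCF spec ordering
  first_field <- vapply(strsplit(fmt, ":", fixed = TRUE), `[`, "", 1L)
  if (length(first_field) > 0L && any(first_field != "GT")) {
    abort("read_vcf: GT must be the first FORMAT field")
  }
  gt[is.na(gt)] <- "./."  # vcfR parses fully-missing entries as NA
  gt <- sub(":.*$", "", gt)

  valid <- grepl("^[01.]([/|][01.])?$", gt)
  if (!all(valid)) {
    i <- which(!valid)[1L]  # gt is column-major: row = record, col = sample
    rec <- (i - 1L) %% length(keep) + 1L
    smp <- (i - 1L) %/% length(keep) + 1L
    abort(sprintf("malformed GT '%s' at variant record %d (sample %s)",
                  gt[i], keep[rec], names(pops)[smp]))
  }

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  # haploid-style single-allele entries count as missing second allele
  allele_code <- c(`0` = 0L, `1` = 1L)
  dos1 <- unname(allele_code[a1])
  dos2 <- unname(allele_code[a2])
  dosage <- matrix(dos1 + dos2, nrow = length(keep),
                   dimnames = list(NULL, names(pops)))

  sites <- tibble(chrom = fix$CHROM[keep],
                  pos = as.integer(fix$POS[keep]),
                  ref = fix$REF[keep], alt = fix$ALT[keep])
  dup_or_unsorted <- unlist(lapply(split(sites$pos, sites$chrom), function(p) {
    length(p) > 1L && any(diff(p) <= 0L)
  }))
  if (any(dup_or_unsorted)) {
    abort("VCF positions must be strictly increasing within each chromosome")
  }

  gset <- new_genotype_set(dosage, sites, names(pops), pops, chrom_lengths)

  phased <- length(gt) > 0L && all(sep == "|") && !anyNA(dosage)
  hset <- NULL
  if (phased) {
    hap <- matrix(0L, nrow = length(keep), ncol = 2L * length(pops))
    hap[, seq(1L, 2L * length(pops), by = 2L)] <-
      matrix(as.integer(a1), nrow = length(keep))
    hap[, seq(2L, 2L * length(pops), by = 2L)] <-
      matrix(as.integer(a2), nrow = length(keep))
    colnames(hap) <- paste0(rep(names(pops), each = 2L), c("_1", "_2"))
    hset <- new_haplotype_set(hap, sites, names(pops), pops, chrom_lengths)
  }
  list(genotypes = gset, haplotypes = hset, n_skipped = n_skipped,
       phased = phased)
}

as_pop_map <- function(populations) {
  if (is.data.frame(populations)) {
    setNames(as.character(populations$population),
             as.character(populations$sample))
  } else if (!is.null(names(populations))) {
    populations
  } else {
    abort("populations must be a data frame or a named character vector")
  }
}

vcf_contig_lengths <- function(v) {
  meta <- v@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg) == 0L) return(NULL)
  ids <- sub('.*ID=([^,>"]+).*', "\\1", ctg)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
  if (anyNA(lens)) return(NULL)
  setNames(lens, ids)
}

#' Write a genotype or haplotype set as a plain-text VCF 4.2
#'
#' Genotypes from a `haplotype_set` are written phased (`a|b`); from a
#' `genotype_set` unphased (`a/b`, `./.` for missing). Output is plain text
#' with deterministic formatting: the same object always yields a
#' byte-identical file.
#'
#' @param x a `genotype_set` or `haplotype_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  sites <- x$sites
  chroms <- unique(sites$chrom)
  lens <- x$chrom_lengths
  if (is.null(lens)) {
    lens <- vapply(chroms, function(ch) {
      max(sites$pos[sites$chrom == ch], 0L)
    }, numeric(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  if (inherits(x, "haplotype_set")) {
    n <- length(x$samples)
    gt <- matrix("", nrow = nrow(x$hap), ncol = n)
    for (i in seq_len(n)) {
      gt[, i] <- paste0(x$hap[, 2L * i - 1L], "|", x$hap[, 2L * i])
    }
  } else {
    d <- x$dosage
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    notna <- !is.na(d)
    gt[notna] <- code[as.character(d[notna])]
  }
  body <- character(nrow(sites))
  if (nrow(sites) > 0L) {
    gt_join <- do.call(paste, c(split(gt, col(gt)), sep = "\t"))
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                  "PASS", ".", "GT", gt_join, sep = "\t")
  }
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}
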