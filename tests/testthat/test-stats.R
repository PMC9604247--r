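test_that("global methylation pools counts over covered sites", {
  tab <- methylome_table("chr1", c(100, 200), meth = c(1, 3),
                         unmeth = c(1, 1))
  expect_equal(global_methylation(tab), 4 / 6)
  expect_equal(global_methylation(tab, per_site = TRUE),
               mean(c(1 / 2, 3 / 4)))

  all0 <- methylome_table("chr1", 1:3 * 10, meth = c(0, 0, 0),
                          unmeth = c(2, 1, 3))
  expect_equal(global_methylation(all0), 0)
  one <- methylome_table("chr1", 10, meth = 2, unmeth = 0)
  expect_equal(global_methylation(one), 1)
  empty_cov <- methylome_table("chr1", 1:2 * 10, meth = c(0, 0),
                               unmeth = c(0, 0))
  expect_error(global_methylation(empty_cov), "no covered")

  # concatenation equals the count-weighted mean of the parts
  a <- methylome_table("chr1", 1:5 * 10, meth = c(1, 0, 2, 1, 0),
                       unmeth = c(1, 2, 0, 1, 1))
  b <- methylome_table("chr2", 1:4 * 10, meth = c(3, 2, 0, 1),
                       unmeth = c(0, 1, 1, 2))
  ab <- methylome_table(c(a$chrom, b$chrom), c(a$pos, b$pos),
                        c(a$meth, b$meth), c(a$unmeth, b$unmeth))
  wa <- sum(a$meth + a$unmeth); wb <- sum(b$meth + b$unmeth)
  expect_equal(global_methylation(ab),
               (global_methylation(a) * wa + global_methylation(b) * wb) /
                 (wa + wb))
})

test_that("feature methylation averages contained CpGs and flags empties", {
  tab <- methylome_table("chr1", c(100, 150, 400),
                         meth = c(0, 0, 4), unmeth = c(4, 2, 0))
  feats <- data.frame(chrom = "chr1", start = c(50, 300, 900),
                      end = c(200, 450, 999))
  fm <- feature_methylation(tab, feats)
  expect_equal(fm$mean_meth, c(0, 1, NA))
  expect_equal(fm$n_cpg, c(2, 1, 0))
  sm <- attr(fm, "summary")
  expect_equal(sm$n, 2)
  expect_equal(sm$frac_hypo, 0.5)
  expect_equal(sm$frac_hyper, 0.5)
})

test_that("bins tile from coordinate 1 and conserve counts", {
  tab <- methylome_table("chr1", c(4999, 5000, 5001, 12000),
                         meth = c(1, 2, 3, 0), unmeth = c(1, 0, 1, 2))
  bins <- bin_methylation(tab, bin_size = 5000, min_cpg = 1)
  expect_equal(bins$bin_start, c(1, 5001, 10001))
  expect_equal(bins$bin_end, c(5000, 10000, 15000))
  expect_equal(bins$n_cpg, c(2, 1, 1))       # 4999 and 5000 share bin 1
  expect_equal(bins$meth, c(3, 3, 0))
  expect_equal(sum(bins$meth), sum(tab$meth))
  expect_equal(sum(bins$unmeth), sum(tab$unmeth))
  # sub-threshold bins keep counts but lose the mean
  bins3 <- bin_methylation(tab, bin_size = 5000, min_cpg = 3)
  expect_true(all(is.na(bins3$mean_meth)))
  expect_equal(sum(bins3$meth), sum(tab$meth))
  expect_equal(nrow(bin_methylation(tab[0, ], 5000)), 0)
})

test_that("sample correlation is Spearman over shared non-missing bins", {
  bins <- function(means) data.frame(chrom = "chr1",
                                     bin_start = seq_along(means),
                                     mean_meth = means)
  expect_equal(correlate_samples(bins(c(0.1, 0.5, 0.9, 0.3)),
                                 bins(c(0.1, 0.5, 0.9, 0.3)))$rho, 1)
  expect_equal(correlate_samples(bins(1:4 / 10), bins(4:1 / 10))$rho, -1)
  # hand-computed: ranks (1,2,3,4) vs (1,2,4,3) -> rho = 1 - 6*2/60 = 0.8
  r <- correlate_samples(bins(c(0.1, 0.2, 0.3, 0.4)),
                         bins(c(0.15, 0.25, 0.45, 0.35)))
  expect_equal(r$rho, 0.8)
  expect_equal(r$n_shared_bins, 4)
  expect_error(correlate_samples(bins(c(0.1, NA, NA, 0.2)),
                                 bins(c(0.1, 0.2, 0.3, 0.4))),
               "fewer than 3")
})

test_that("converted repeat references follow the CpG conversion rules", {
  refs <- build_repeat_references("ACGTCG")
  expect_equal(unname(refs$variants["top_methylated"]), "ACGTCG")
  expect_equal(unname(refs$variants["top_unmethylated"]), "ATGTTG")
  # bottom strand against the top: conversion reads as G -> A, CpG guanines
  # (preceded by C) survive in the methylated variant
  expect_equal(unname(refs$variants["bottom_methylated"]), "ACGTCG")
  expect_equal(unname(refs$variants["bottom_unmethylated"]), "ACATCA")

  no_cpg <- build_repeat_references("ACCT")
  expect_equal(unname(no_cpg$variants["top_methylated"]), "ATTT")
  expect_equal(unname(no_cpg$variants["top_unmethylated"]), "ATTT")

  expect_equal(unname(build_repeat_references("AAAA")$variants),
               rep("AAAA", 4))
  expect_error(build_repeat_references("ACGN"), "non-ACGT")

  # invariants on a CpG-rich monomer: the unmethylated variant has no CpG
  # cytosine left; the methylated variant differs from the monomer only at
  # non-CpG cytosines
  m <- "CGGATCGCTAC"
  r <- build_repeat_references(m)
  expect_false(grepl("CG", r$variants["top_unmethylated"]))
  expect_false(grepl("G", r$variants["bottom_unmethylated"]))
  s <- strsplit(m, "")[[1]]
  v <- strsplit(unname(r$variants["top_methylated"]), "")[[1]]
  expect_true(all(s[s != v] == "C"))
  vb <- strsplit(unname(r$variants["bottom_methylated"]), "")[[1]]
  expect_true(all(s[s != vb] == "G"))
})

test_that("reads simulated from a variant are classified back perfectly", {
  monomer <- "ACGGTACGTTCCAGT"
  refs <- build_repeat_references(monomer)
  tandem <- function(v) strrep(refs$variants[[v]], 4)
  revcomp <- function(x)
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
  reads <- c(substr(tandem("top_methylated"), 3, 30),
             substr(tandem("top_methylated"), 10, 42),
             # a bottom-strand read arrives in its own 5'->3' orientation
             revcomp(substr(tandem("bottom_methylated"), 5, 33)))
  ureads <- c(substr(tandem("top_unmethylated"), 3, 30),
              revcomp(substr(tandem("bottom_unmethylated"), 7, 36)))
  res <- classify_repeat_reads(c(reads, ureads), refs)
  expect_equal(res$methylated, 3)
  expect_equal(res$unmethylated, 2)
  expect_equal(res$unassigned, 0)
  expect_equal(res$fraction, 3 / 5)

  # CpG-free monomer: variants coincide, every read ties -> unassigned
  refs2 <- build_repeat_references("ACCTTGAT")
  res2 <- classify_repeat_reads(strrep("ATTTTGAT", 3), refs2)
  expect_equal(res2$unassigned, 1)
  expect_true(is.na(res2$fraction))

  # junk reads fall below the score threshold
  res3 <- classify_repeat_reads("TTTTTTTTTTTTTTTTTTTT", refs)
  expect_equal(res3$unassigned, 1)
})

test_that("two-group comparison is a two-sided rank test", {
  set.seed(2)
  a <- runif(7, 0.4, 0.6)
  b <- runif(9, 0.4, 0.6)
  h <- compare_global_levels(a, b)
  expect_s3_class(h, "htest")
  expect_equal(h$p.value,
               wilcox.test(a, b, alternative = "two.sided",
                           exact = FALSE)$p.value)
})

test_that("FASTA reader handles multi-record and wrapped sequences", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">mono1 description", "ACGT", "TTGG", ">mono2", "CCGG"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs, c(mono1 = "ACGTTTGG", mono2 = "CCGG"))
  bad <- tempfile(fileext = ".fa")
  writeLines("ACGT", bad)
  expect_error(read_fasta(bad), "header")
})
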