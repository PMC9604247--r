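make_states <- function(states, pos = NULL, depth = 1) {
  n <- length(states)
  if (is.null(pos)) pos <- seq_len(n) * 100
  depth <- rep_len(depth, n)
  df <- data.frame(chrom = "chr1", pos = pos, meth = 0,
                   unmeth = depth, state = as.integer(states))
  structure(df, class = c("methyl_states", "data.frame"),
            model = fixed_model())
}

test_that("runs collapse into segments; unknown sites bridge matching flanks", {
  st <- make_states(c(1, 1, NA, 1, 2, 2),
                    pos = c(100, 200, 300, 400, 500, 600))
  segs <- states_to_segments(st, min_cpg = 3)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 100)
  expect_equal(segs$end, 400)       # spans across the skipped unknown site
  expect_equal(segs$state, 1L)
  expect_equal(segs$n_cpg, 3)       # the unknown site is not a member
  dropped <- attr(segs, "dropped")
  expect_equal(dropped$state, 2L)   # 2-CpG run dropped at min_cpg = 3
  expect_equal(dropped$n_cpg, 2)
  # conservation: members + dropped members + unknowns = series length
  expect_equal(sum(segs$n_cpg) + sum(dropped$n_cpg) + attr(segs, "n_un"),
               nrow(st))

  # unknown between DIFFERENT states breaks the run
  st2 <- make_states(c(1, 1, 1, NA, 2, 2, 2))
  segs2 <- states_to_segments(st2, min_cpg = 3)
  expect_equal(nrow(segs2), 2)
  expect_equal(segs2$state, c(1L, 2L))

  expect_equal(nrow(states_to_segments(make_states(rep(NA, 5)))), 0)
  expect_equal(nrow(states_to_segments(make_states(c(1, 2, 1, 2)),
                                       min_cpg = 1)), 4)
})

test_that("segment output is sorted, non-overlapping and count-conserving", {
  sim <- simulate_methylome(chrom_lengths = c(chrA = 1e5, chrB = 1e5),
                            seed = 31)
  model <- fixed_model()
  dec <- decode_states(model, sim$table)
  segs <- states_to_segments(dec, min_cpg = 3)
  expect_true(all(segs$start <= segs$end))
  by_chr <- split(segs, segs$chrom)
  for (ch in by_chr)
    if (nrow(ch) > 1) expect_true(all(ch$start[-1] > ch$end[-nrow(ch)]))
  expect_equal(sum(segs$n_cpg) + sum(attr(segs, "dropped")$n_cpg) +
                 attr(segs, "n_un"), nrow(sim$table))
})

test_that("regime labels follow ascending state means", {
  expect_equal(assign_regimes(fixed_model(c(0.05, 0.5, 0.85))),
               c("hypo", "intermediate", "hyper"))
  expect_equal(assign_regimes(fixed_model(c(0.1, 0.8))), c("hypo", "hyper"))
  expect_equal(assign_regimes(fixed_model(c(0.1, 0.3, 0.6, 0.9))),
               c("hypo", "intermediate1", "intermediate2", "hyper"))
})

test_that("hypomethylation calls use an inclusive 20% boundary", {
  tab <- methylome_table(rep("chr1", 9), pos = c(1:3 * 10, 1:3 * 10 + 100,
                                                 1:3 * 10 + 200),
                         meth = c(0, 1, 2, 1, 1, 2, 5, 6, 0),
                         unmeth = c(10, 9, 8, 3, 7, 6, 5, 4, 0))
  segs <- data.frame(chrom = "chr1",
                     start = c(10, 110, 210), end = c(30, 130, 230),
                     regime = "hypo", mean_meth = NA)
  # segment means: 3/30 = 0.10, 4/20 = 0.20 (boundary), covered 11/20 = 0.55
  called <- call_hypomethylated(segs, tab, threshold = 0.20)
  expect_equal(called$start, c(10, 110))
  expect_equal(called$sample_mean, c(0.10, 0.20))
  # threshold = 1 keeps everything with coverage; threshold = 0 only
  # fully unmethylated segments
  expect_equal(nrow(call_hypomethylated(segs, tab, threshold = 1)), 3)
  expect_equal(nrow(call_hypomethylated(segs, tab, threshold = 0)), 0)
  # a segment with no covered CpGs is excluded with a message
  segs2 <- rbind(segs, data.frame(chrom = "chr1", start = 500, end = 600,
                                  regime = "hypo", mean_meth = NA))
  expect_message(call_hypomethylated(segs2, tab), "no covered CpG")
})

test_that("specificity requires the focal sample to oppose all others", {
  loci <- data.frame(chrom = "chr1", start = c(1, 101, 201, 301),
                     end = c(100, 200, 300, 400))
  means <- rbind(c(0.05, 0.50, 0.60, 0.40),  # focal hypo, others not
                 c(0.50, 0.10, 0.15, 0.20),  # reverse case
                 c(0.05, 0.10, 0.50, 0.60),  # one other hypo: not specific
                 c(0.50, 0.60, 0.70, NA))    # missing data: never flagged
  colnames(means) <- paste0("s", 1:4)
  expect_message(
    res <- call_specific_loci(loci, means, focal = "s1", threshold = 0.20),
    "missing")
  expect_equal(res$specific, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("permutation enrichment matches a closed-form overlap probability", {
  # one 1000-bp chromosome, one 100-bp feature at 401..500, one 100-bp locus:
  # a uniform start in 1..901 overlaps iff start in 302..500
  features <- data.frame(chrom = "chr1", start = 401, end = 500)
  loci <- data.frame(chrom = "chr1", start = 450, end = 549)
  res <- feature_enrichment(loci, features, c(chr1 = 1000), n_perm = 2000,
                            seed = 77)
  expect_equal(res$observed, 1)
  p <- 199 / 901
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(res$null_mean - p), 3 * se)
  # seed-reproducible
  res2 <- feature_enrichment(loci, features, c(chr1 = 1000), n_perm = 2000,
                             seed = 77)
  expect_identical(res$null, res2$null)
})

test_that("enrichment edge cases: saturating loci and empty locus sets", {
  features <- data.frame(chrom = "chr1", start = c(10, 500), end = c(50, 600))
  whole <- data.frame(chrom = "chr1", start = 1, end = 1000)
  res <- feature_enrichment(whole, features, c(chr1 = 1000), n_perm = 50,
                            seed = 1)
  expect_equal(res$observed, 2)
  expect_true(all(res$null == 2))   # a genome-length locus always overlaps
  expect_true(is.na(res$z))         # sd = 0 -> z undefined

  none <- feature_enrichment(whole[0, ], features, c(chr1 = 1000),
                             n_perm = 10, seed = 1)
  expect_equal(none$observed, 0)
})
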