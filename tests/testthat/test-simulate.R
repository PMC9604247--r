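test_that("simulation is byte-reproducible under a seed", {
  a <- simulate_methylome(chrom_lengths = c(chrA = 1e5), seed = 42)
  b <- simulate_methylome(chrom_lengths = c(chrA = 1e5), seed = 42)
  expect_identical(a, b)
  c2 <- simulate_methylome(chrom_lengths = c(chrA = 1e5), seed = 43)
  expect_false(identical(a$table$meth, c2$table$meth))
})

test_that("generated tables satisfy the container and QC invariants", {
  sim <- simulate_methylome(chrom_lengths = c(chrA = 2e5, chrB = 2e5),
                            seed = 8)
  tab <- sim$table
  for (s in as_observation_series(tab))
    expect_true(all(diff(s$pos) >= 1))
  expect_true(all(tab$meth <= cpg_depth(tab)))
  expect_true(all(cpg_depth(tab) <= 8))
  expect_equal(filter_coverage_artifacts(tab)$artifact_fraction, 0)
  # CpG spacing close to the configured mean
  gaps <- unlist(lapply(as_observation_series(tab), function(s) diff(s$pos)))
  expect_lt(abs(mean(gaps) - 100), 5)
})

test_that("per-state methylated fractions match the regime means", {
  sim <- simulate_methylome(seed = 21)        # ~50k sites
  tab <- sim$table
  depth <- cpg_depth(tab)
  for (k in 1:3) {
    rows <- sim$states$state == k & depth > 0
    n <- sum(depth[rows])
    phat <- sum(tab$meth[rows]) / n
    b <- sim$config$betas[k]
    expect_lt(abs(phat - b), 3 * sqrt(b * (1 - b) / n))
  }
})

test_that("the distance kernel limits give i.i.d. and frozen state chains", {
  # d0 -> 0: states i.i.d. uniform; stay fraction ~ 1/K
  iid <- simulate_methylome(chrom_lengths = c(chrA = 3e5), d0 = 1e-6,
                            seed = 3)
  st <- iid$states$state
  stay <- mean(st[-1] == st[-length(st)])
  n <- length(st) - 1
  expect_lt(abs(stay - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
  # d0 -> Inf: one state per chromosome
  frozen <- simulate_methylome(chrom_lengths = c(chrA = 1e5, chrB = 1e5),
                               d0 = 1e12, seed = 3)
  per_chr <- tapply(frozen$states$state, frozen$states$chrom,
                    function(x) length(unique(x)))
  expect_true(all(per_chr == 1))
})

test_that("true segments partition each chromosome's CpGs", {
  sim <- simulate_methylome(chrom_lengths = c(chrA = 1e5), seed = 12)
  expect_equal(sum(sim$segments$n_cpg), nrow(sim$table))
  expect_true(all(sim$segments$start <= sim$segments$end))
  # segment regime labels match the state rank
  expect_equal(unique(sim$segments$regime[sim$segments$state == 1]), "hypo")
})

test_that("multisample simulation plants recoverable specific loci", {
  spec <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(2e5, 6e5, 3e5),
                     end = c(2e5 + 8000, 6e5 + 8000, 3e5 + 8000),
                     mode = c("focal_hypo", "focal_hypo", "others_hypo"))
  ms <- simulate_multisample(n_samples = 4, focal = 1, specific_loci = spec,
                             chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                             mean_depth = 6, seed = 17)
  means <- locus_sample_means(spec, ms$tables)
  # planted focal-hypo loci: focal at the hypo regime, others at hyper
  expect_true(all(means[1:2, 1] <= 0.20))
  expect_true(all(means[1:2, -1] > 0.20))
  # reverse case
  expect_gt(means[3, 1], 0.20)
  expect_true(all(means[3, -1] <= 0.20))
  res <- call_specific_loci(spec, means, focal = 1)
  expect_true(all(res$specific))

  # empty spec: no locus should come out specific at backbone loci
  ms0 <- simulate_multisample(n_samples = 3, chrom_lengths = c(chr1 = 2e5),
                              mean_depth = 6, seed = 18)
  probe <- data.frame(chrom = "chr1", start = seq(1, 1.8e5, by = 2e4),
                      end = seq(1, 1.8e5, by = 2e4) + 1e4)
  pm <- locus_sample_means(probe, ms0$tables)
  r0 <- call_specific_loci(probe, pm, focal = 1)
  expect_false(any(r0$specific))

  # overlapping planted loci (collars included) are rejected
  bad <- data.frame(chrom = "chr1", start = c(1e5, 1.05e5),
                    end = c(1.04e5, 1.2e5), mode = "focal_hypo")
  expect_error(simulate_multisample(specific_loci = bad,
                                    chrom_lengths = c(chr1 = 1e6),
                                    seed = 1),
               "overlap")
})

test_that("written simulations are valid Bismark coverage files", {
  sim <- simulate_methylome(chrom_lengths = c(chrA = 5e4), seed = 6)
  prefix <- tempfile()
  paths <- write_simulation(sim, prefix)
  tab <- read_bismark_cov(paste0(prefix, ".cov"))
  expect_equal(tab$pos, sim$table$pos)
  expect_equal(tab$meth, sim$table$meth)
  expect_equal(tab$unmeth, sim$table$unmeth)
  expect_true(file.exists(paste0(prefix, ".truth.bed")))
  cfg <- jsonlite::read_json(paste0(prefix, ".config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, 6)
})
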