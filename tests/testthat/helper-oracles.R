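# Independent oracles and small fixture builders used across the suite.

# Exhaustive maximum-probability path over all K^T state sequences, computed
# by direct enumeration (vectorized over paths). Independent of the Viterbi
# recursion it is used to check.
brute_force_viterbi <- function(meth, depth, gaps, betas, pi, d0) {
  K <- length(betas)
  T <- length(meth)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  E <- sapply(seq_len(K), function(k)
    dbinom(meth, depth, betas[k], log = TRUE))          # T x K
  if (T == 1) E <- matrix(E, nrow = 1)
  lp <- log(pi[paths[, 1]]) + E[cbind(1, paths[, 1])]
  for (t in 2:T) {
    P <- log(transition_matrix(K, gaps[t - 1], d0))
    lp <- lp + P[cbind(paths[, t - 1], paths[, t])] + E[cbind(t, paths[, t])]
  }
  best <- which.max(lp)
  list(path = as.integer(paths[best, ]), logp = lp[best])
}

# random small observation series on one chromosome
random_series <- function(T, max_gap = 400, max_depth = 6, chrom = "chrA") {
  pos <- cumsum(sample(1:max_gap, T, replace = TRUE)) + 100
  depth <- sample(0:max_depth, T, replace = TRUE)
  meth <- rbinom(T, depth, runif(T))
  list(chrom = chrom, pos = pos, meth = meth, depth = depth)
}

# write a Bismark .cov file for a methylome table (or raw columns)
write_cov_file <- function(path, chrom, pos, meth, unmeth) {
  depth <- meth + unmeth
  pct <- ifelse(depth > 0, 100 * meth / depth, 0)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d", chrom, pos, pos,
                     format(pct, trim = TRUE), meth, unmeth), path)
  path
}

toy_table <- function() {
  methylome_table(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  pos = c(100, 200, 300, 50),
                  meth = c(2, 0, 3, 1), unmeth = c(2, 3, 0, 0),
                  sample_id = "toy")
}

# a small fitted model without running EM (for decode/segment unit tests)
fixed_model <- function(betas = c(0.05, 0.5, 0.85), d0 = 1250,
                        pi = NULL) {
  K <- length(betas)
  structure(list(K = K, betas = betas,
                 pi = if (is.null(pi)) rep(1 / K, K) else pi,
                 d0 = d0, logLik = NA_real_, n_obs = 0L, n_sites = 0L,
                 weighted_loglik = numeric(0), iterations = 0L,
                 converged = TRUE, include_uncovered = TRUE,
                 literal_eq1 = FALSE, seed = NULL, call = NULL),
            class = "methyl_hmm")
}
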