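## Distance-aware binomial HMM over CpG sites.
##
## The model has K latent methylation regimes. Regime k emits the methylated
## count m_t of a CpG with depth n_t as Binomial(n_t, beta_k). The chance of
## staying in the current regime decays with the genomic distance d between
## neighbouring CpGs:
##
##   P(stay)   = 1/K + (K-1)/K * exp(-d/d0)
##   P(switch) = 1/K * (1 - exp(-d/d0))     (each of the K-1 other regimes)
##
## which at K = 4 equals the classical 1/4 + 3/4 e and 1/4 - 1/4 e
## coefficients. During Baum-Welch training each site's emission
## log-likelihood is multiplied by (n_t + 2) so deep sites dominate learning;
## decoding and model comparison use the plain likelihood.

.BETA_FLOOR <- 1e-6

.clamp_beta <- function(b) pmin(pmax(b, .BETA_FLOOR), 1 - .BETA_FLOOR)

#' Distance-dependent transition matrix
#'
#' @param K number of states.
#' @param d genomic distance in bp between the two CpG sites (>= 0).
#' @param d0 distance parameter in bp (> 0); the correlation length of the
#'   methylation regimes.
#' @param literal_eq1 if `TRUE`, use the classical four-state coefficients
#'   (1/4 + 3/4 e on the diagonal, 1/4 - 1/4 e off it) renormalized row-wise
#'   for any K, instead of the generalized row-stochastic form.
#' @return A `K x K` row-stochastic matrix; entry `(i, j)` is the probability
#'   of moving from state i to state j across a gap of `d` bp. At `d = 0` it
#'   is the identity; as `d` grows all entries tend to `1/K`.
#' @examples
#' transition_matrix(3, d = 100, d0 = 1250)
#' @export
transition_matrix <- function(K, d, d0, literal_eq1 = FALSE) {
  stopifnot(K >= 1, d0 > 0)
  if (d < 0) stop("transition_matrix: distance d must be >= 0")
  e <- exp(-d / d0)
  if (K == 1) return(matrix(1, 1, 1))
  if (!literal_eq1) {
    stay <- 1 / K + (K - 1) / K * e
    sw <- (1 - e) / K
  } else {
    s0 <- 0.25 + 0.75 * e
    w0 <- 0.25 - 0.25 * e
    stay <- s0 / (s0 + (K - 1) * w0)
    sw <- w0 / (s0 + (K - 1) * w0)
  }
  P <- matrix(sw, K, K)
  diag(P) <- stay
  P
}

#' Binomial emission probability
#'
#' Probability of observing `meth` methylated calls out of `depth` at a site
#' emitted by a state with mean methylation `beta`. A depth of zero carries
#' no information and has probability 1 for every state.
#'
#' @param beta state mean methylation level in `[0, 1]`.
#' @param meth,depth observed methylated count and total depth
#'   (`0 <= meth <= depth`).
#' @param log return the log probability.
#' @return Numeric probability (or log probability).
#' @export
emission_prob <- function(beta, meth, depth, log = FALSE) {
  stopifnot(all(meth >= 0), all(meth <= depth))
  stats::dbinom(meth, depth, beta, log = log)
}

#' Training weight of a CpG site
#'
#' During Baum-Welch training the emission log-likelihood of site t is
#' multiplied by `depth + 2`, so cytosines with greater read depth contribute
#' more to learning; an uncovered site (weight 2 on a constant-1 emission) is
#' neutral.
#'
#' @param depth read depth `n_t` (>= 0).
#' @return `depth + 2`.
#' @export
training_weight <- function(depth) {
  stopifnot(all(depth >= 0))
  depth + 2
}

#' Observation series for the HMM
#'
#' Splits a methylome table into per-chromosome observation series: strictly
#' increasing positions, methylated counts and depths.
#'
#' @param x a [methylome_table()] or a list of series (returned unchanged).
#' @param include_uncovered keep CpGs with depth 0 in the series (default
#'   `TRUE`; they are emission-neutral but preserve the genomic distances).
#' @return A list of series, each a list with `chrom`, `pos`, `meth`, `depth`.
#' @export
as_observation_series <- function(x, include_uncovered = TRUE) {
  if (is.list(x) && !is.data.frame(x)) return(x)
  stopifnot(is.data.frame(x))
  if (!include_uncovered) x <- x[x$meth + x$unmeth > 0, , drop = FALSE]
  lapply(split(seq_len(nrow(x)), x$chrom), function(i) {
    list(chrom = x$chrom[i[1]], pos = x$pos[i], meth = x$meth[i],
         depth = x$meth[i] + x$unmeth[i])
  })
}

#' Reverse an observation series
#'
#' Returns the series read in the opposite genomic direction. Positions are
#' negated and reversed so they remain strictly increasing while the
#' sequence of inter-CpG gaps is mirrored exactly.
#'
#' @param series a series as produced by [as_observation_series()].
#' @return The reversed series.
#' @export
reverse_series <- function(series) {
  list(chrom = series$chrom, pos = rev(-series$pos),
       meth = rev(series$meth), depth = rev(series$depth))
}

#' Forward and reverse copies of a series
#'
#' The methylation state of a CpG is coupled to both its left and right
#' neighbours, so training and decoding use the series in both directions.
#'
#' @param series a series as produced by [as_observation_series()].
#' @return A list with elements `forward` and `reverse`.
#' @export
prepare_bidirectional <- function(series) {
  if (length(series$pos) == 0) stop("prepare_bidirectional: empty series")
  list(forward = series, reverse = reverse_series(series))
}

.series_gaps <- function(series) {
  g <- diff(series$pos)
  if (length(g) && any(g <= 0))
    stop("observation series positions must be strictly increasing")
  g
}

.fb <- function(series, betas, pi, d0, weights, literal) {
  fb_pass_cpp(series$meth, series$depth, .series_gaps(series),
              betas, pi, d0, weights, literal)
}

#' Fit the distance-aware binomial HMM
#'
#' Baum-Welch estimation of the K state means `beta_k` and the initial state
#' distribution. Transition probabilities are fixed by the distance kernel
#' given `d0` (tune `d0` with [select_methyl_hmm()]); per-site emission
#' log-likelihoods are weighted by [training_weight()] during the E step and
#' in the monitored objective; the reversed copy of every series is included
#' in the training set. States are returned in ascending `beta` order.
#'
#' @param x a [methylome_table()] or list of observation series.
#' @param K number of states (>= 1).
#' @param d0 distance parameter in bp.
#' @param tol relative improvement of the weighted log-likelihood below which
#'   EM stops.
#' @param max_iter maximum EM iterations.
#' @param include_uncovered keep depth-0 sites in the series.
#' @param literal_eq1 see [transition_matrix()].
#' @param seed recorded in the fit; estimation itself is deterministic
#'   (quantile initialization, no random restarts).
#' @param verbose print the weighted log-likelihood per iteration.
#' @return An object of class `"methyl_hmm"`: a list with `K`, `betas`, `pi`,
#'   `d0`, `logLik` (plain forward log-likelihood of the data), `n_obs`
#'   (covered sites), `weighted_loglik` (per-iteration trace), `iterations`,
#'   `converged`, and the call. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `simulate`, `plot`, `residuals`.
#' @examples
#' sim <- simulate_methylome(chrom_lengths = c(chrA = 2e5), seed = 1)
#' fit <- methyl_hmm(sim$table, K = 3, d0 = 1250)
#' coef(fit)
#' @export
methyl_hmm <- function(x, K = 3, d0 = 1250, tol = 1e-4, max_iter = 200L,
                       include_uncovered = TRUE, literal_eq1 = FALSE,
                       seed = NULL, verbose = FALSE) {
  cl <- match.call()
  stopifnot(K >= 1, d0 > 0, max_iter >= 1)
  series <- as_observation_series(x, include_uncovered)
  series <- Filter(function(s) length(s$pos) > 0, series)
  if (length(series) == 0) stop("methyl_hmm: no observation series")
  n_cov <- sum(vapply(series, function(s) sum(s$depth > 0), numeric(1)))
  if (n_cov < 10 * K)
    stop(sprintf("methyl_hmm: %d covered sites < 10 * K = %d", n_cov, 10 * K))

  ## quantile initialization over shrunken per-site methylated fractions
  ## ((m+1)/(n+2): raw fractions are almost all 0 or 1 at single-cell depth,
  ## which would pin the initial betas to the boundary)
  fr <- unlist(lapply(series, function(s) {
    i <- s$depth > 0
    (s$meth[i] + 1) / (s$depth[i] + 2)
  }))
  probs <- if (K == 1) 0.5 else seq(0.1, 0.9, length.out = K)
  betas <- .clamp_beta(stats::quantile(fr, probs, names = FALSE))
  if (K > 1) {
    for (k in 2:K)                      # keep states separated at start
      if (betas[k] - betas[k - 1] < 1e-3)
        betas[k] <- min(betas[k - 1] + 1e-3, 1 - .BETA_FLOOR)
  }
  pi <- rep(1 / K, K)

  both <- c(series, lapply(series, reverse_series))
  wtrace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sm <- sn <- g1 <- rep(0, K)
    wll <- 0
    for (s in both) {
      r <- .fb(s, betas, pi, d0, training_weight(s$depth), literal_eq1)
      wll <- wll + r$loglik
      sm <- sm + r$sm
      sn <- sn + r$sn
      g1 <- g1 + r$g1
    }
    wtrace <- c(wtrace, wll)
    if (verbose) message(sprintf("iter %3d  weighted logLik %.4f", it, wll))
    if (it > 1) {
      prev <- wtrace[it - 1]
      if ((wll - prev) < tol * (abs(prev) + 1e-10)) { converged <- TRUE; break }
    }
    betas <- .clamp_beta(ifelse(sn > 0, sm / sn, betas))
    pi <- g1 / sum(g1)
  }
  if (!converged && all(diff(utils::tail(wtrace, 2)) == 0)) converged <- TRUE

  ord <- order(betas)
  betas <- betas[ord]
  pi <- pi[ord]

  ll <- sum(vapply(series, function(s)
    .fb(s, betas, pi, d0, rep(1, length(s$depth)), literal_eq1)$loglik,
    numeric(1)))

  structure(list(K = as.integer(K), betas = as.numeric(betas),
                 pi = as.numeric(pi), d0 = d0, logLik = ll, n_obs = n_cov,
                 n_sites = sum(vapply(series, function(s) length(s$pos),
                                      numeric(1))),
                 weighted_loglik = wtrace, iterations = length(wtrace),
                 converged = converged, include_uncovered = include_uncovered,
                 literal_eq1 = literal_eq1, seed = seed, call = cl),
            class = "methyl_hmm")
}

#' Bidirectional Viterbi decoding
#'
#' Runs Viterbi decoding (plain binomial emissions) on every series in both
#' genomic directions and reconciles them: sites where the forward and
#' reverse decodings agree receive that state; discordant sites are labelled
#' unknown (`NA`, the "un" class) and are excluded from downstream state
#' assignment.
#'
#' @param model a fitted [methyl_hmm()].
#' @param x a [methylome_table()] or list of observation series.
#' @param include_uncovered keep depth-0 sites; defaults to the setting the
#'   model was fitted with.
#' @return A data frame of class `"methyl_states"` with columns `chrom`,
#'   `pos`, `meth`, `unmeth`, `state` (integer in `1..K`, `NA` for unknown),
#'   carrying the model as attribute `"model"`.
#' @export
decode_states <- function(model, x,
                          include_uncovered = model$include_uncovered) {
  stopifnot(inherits(model, "methyl_hmm"))
  series <- as_observation_series(x, include_uncovered)
  series <- Filter(function(s) length(s$pos) > 0, series)
  out <- lapply(series, function(s) {
    f <- viterbi_cpp(s$meth, s$depth, .series_gaps(s), model$betas, model$pi,
                     model$d0, model$literal_eq1)$path
    rs <- reverse_series(s)
    r <- rev(viterbi_cpp(rs$meth, rs$depth, .series_gaps(rs), model$betas,
                         model$pi, model$d0, model$literal_eq1)$path)
    st <- ifelse(f == r, f, NA_integer_)
    data.frame(chrom = s$chrom, pos = s$pos, meth = s$meth,
               unmeth = s$depth - s$meth, state = as.integer(st),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("methyl_states", "data.frame"), model = model)
}

#' Model selection over state count and distance parameter
#'
#' Fits the HMM for every combination of `K_grid` and `d0_grid` and ranks the
#' fits by information criteria computed from the plain (unweighted) forward
#' log-likelihood: `AIC = 2p - 2 lnL`, `BIC = p ln(N) - 2 lnL` with
#' `p = K + (K - 1) + 1` free parameters (state means, initial probabilities,
#' distance parameter) and `N` the number of covered CpG sites.
#'
#' @param x a [methylome_table()] or list of observation series.
#' @param K_grid integer vector of state counts to try.
#' @param d0_grid numeric vector of distance parameters (bp) to try.
#' @param seed recorded and passed through to the fits.
#' @param ... further arguments to [methyl_hmm()].
#' @return A list of class `"methyl_hmm_select"`: `best` (the argmin-BIC
#'   fit), `table` (one row per combination: K, d0, p, N, logLik, AIC, BIC,
#'   converged).
#' @export
select_methyl_hmm <- function(x, K_grid = 2:5, d0_grid = 1250, seed = NULL,
                              ...) {
  stopifnot(length(K_grid) > 0, length(d0_grid) > 0)
  combos <- expand.grid(K = K_grid, d0 = d0_grid)
  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    K <- combos$K[i]; d0 <- combos$d0[i]
    fit <- tryCatch(methyl_hmm(x, K = K, d0 = d0, seed = seed, ...),
                    error = function(e) {
                      warning(sprintf("fit K=%d d0=%g failed: %s", K, d0,
                                      conditionMessage(e)))
                      NULL
                    })
    fits[[i]] <- fit
    if (is.null(fit)) next
    p <- 2 * K                      # K betas + (K-1) pi + 1 d0
    rows[[i]] <- data.frame(K = K, d0 = d0, p = p, N = fit$n_obs,
                            logLik = fit$logLik,
                            AIC = 2 * p - 2 * fit$logLik,
                            BIC = p * log(fit$n_obs) - 2 * fit$logLik,
                            converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("select_methyl_hmm: every fit failed")
  best_i <- which(!vapply(fits, is.null, logical(1)))[which.min(tab$BIC)]
  structure(list(best = fits[[best_i]], table = tab),
            class = "methyl_hmm_select")
}

#' @export
print.methyl_hmm_select <- function(x, ...) {
  cat("HMM model selection (argmin BIC)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("\nselected: K = %d, d0 = %g\n", x$best$K, x$best$d0))
  invisible(x)
}

#' Balanced random train/test loci
#'
#' Samples non-overlapping fixed-length loci with uniformly random start
#' positions, balanced across chromosome classes (for chicken: macro-,
#' intermediate and micro-chromosomes) and split evenly into a train and a
#' test set within each class.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param chrom_classes named character vector assigning each chromosome to a
#'   class; defaults to [chicken_chrom_classes()] on the names of
#'   `chrom_sizes`.
#' @param n_loci total number of loci; must be divisible by
#'   `2 * number of classes`.
#' @param locus_len locus length in bp.
#' @param seed integer seed for reproducible sampling.
#' @return A list with data frames `train` and `test` (columns `chrom`,
#'   `start`, `end`, `class`), disjoint and non-overlapping.
#' @export
make_train_test_loci <- function(chrom_sizes, chrom_classes = NULL,
                                 n_loci = 54, locus_len = 300000,
                                 seed = NULL) {
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  if (is.null(chrom_classes))
    chrom_classes <- chicken_chrom_classes(names(chrom_sizes))
  classes <- unique(chrom_classes[names(chrom_sizes)])
  if (n_loci %% (2 * length(classes)) != 0)
    stop(sprintf("n_loci = %d is not divisible by 2 x %d classes", n_loci,
                 length(classes)))
  quota <- n_loci / length(classes)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  picked <- list()
  for (cls in classes) {
    chroms <- names(chrom_sizes)[chrom_classes[names(chrom_sizes)] == cls]
    sizes <- chrom_sizes[chroms]
    capacity <- sum(pmax(floor(sizes / locus_len), 0))
    if (capacity < quota)
      stop(sprintf("chromosome class '%s' cannot hold %d non-overlapping %d-bp loci",
                   cls, quota, locus_len))
    got <- data.frame(chrom = character(), start = numeric(), end = numeric())
    attempts <- 0L
    while (nrow(got) < quota) {
      attempts <- attempts + 1L
      if (attempts > 10000L * quota)
        stop(sprintf("could not place loci for class '%s'", cls))
      w <- pmax(sizes - locus_len + 1, 0)
      if (all(w == 0))
        stop(sprintf("chromosome class '%s' has no room for %d-bp loci", cls,
                     locus_len))
      chrom <- sample(chroms, 1, prob = w)
      start <- floor(stats::runif(1, 1, chrom_sizes[chrom] - locus_len + 2))
      end <- start + locus_len - 1
      same <- got[got$chrom == chrom, , drop = FALSE]
      if (nrow(same) && any(start <= same$end & end >= same$start)) next
      got <- rbind(got, data.frame(chrom = chrom, start = start, end = end))
    }
    got$class <- cls
    picked[[cls]] <- got[sample.int(nrow(got)), , drop = FALSE]
  }
  train <- do.call(rbind, lapply(picked, function(g)
    g[seq_len(nrow(g) / 2), , drop = FALSE]))
  test <- do.call(rbind, lapply(picked, function(g)
    g[-seq_len(nrow(g) / 2), , drop = FALSE]))
  rownames(train) <- rownames(test) <- NULL
  list(train = train[order(train$chrom, train$start), ],
       test = test[order(test$chrom, test$start), ])
}

#' Default chicken chromosome classes
#'
#' Chicken chromosomes fall into three size classes; membership is not
#' standardized, so the shipped default assigns chr1-chr5 to the
#' macro-chromosomes, chr6-chr10 to the intermediate class and everything
#' else (including chrZ/chrW and scaffolds) to the micro-chromosomes.
#'
#' @param chroms character vector of chromosome names.
#' @return Named character vector of classes.
#' @export
chicken_chrom_classes <- function(chroms) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chroms)))
  cls <- ifelse(!is.na(num) & num <= 5, "macro",
                ifelse(!is.na(num) & num <= 10, "intermediate", "micro"))
  names(cls) <- chroms
  cls
}

#' Serialize a fitted model to JSON
#'
#' @param model a [methyl_hmm()] fit.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_methyl_hmm <- function(model, path) {
  stopifnot(inherits(model, "methyl_hmm"))
  obj <- list(K = model$K, betas = model$betas, pi = model$pi, d0 = model$d0,
              logLik = model$logLik, n_obs = model$n_obs,
              n_sites = model$n_sites, iterations = model$iterations,
              converged = model$converged,
              include_uncovered = model$include_uncovered,
              literal_eq1 = model$literal_eq1,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_methyl_hmm()].
#' @return A `"methyl_hmm"` object.
#' @export
read_methyl_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$K <- as.integer(obj$K)
  obj$weighted_loglik <- numeric(0)
  obj$call <- NULL
  structure(obj, class = "methyl_hmm")
}
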