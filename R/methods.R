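#' @export
print.methyl_hmm <- function(x, ...) {
  cat(sprintf("Distance-aware binomial HMM (K = %d states, d0 = %g bp)\n",
              x$K, x$d0))
  reg <- assign_regimes(x)
  for (k in seq_len(x$K))
    cat(sprintf("  state %d [%s]: beta = %.4f, pi = %.3f\n", k, reg[k],
                x$betas[k], x$pi[k]))
  cat(sprintf("  logLik %.2f on %d covered CpGs (%d sites); EM %s in %d iterations\n",
              x$logLik, x$n_obs, x$n_sites,
              if (isTRUE(x$converged)) "converged" else "did not converge",
              x$iterations))
  invisible(x)
}

#' @export
summary.methyl_hmm <- function(object, ...) {
  p <- 2 * object$K
  structure(list(model = object, regimes = assign_regimes(object), p = p,
                 AIC = 2 * p - 2 * object$logLik,
                 BIC = p * log(object$n_obs) - 2 * object$logLik),
            class = "summary.methyl_hmm")
}

#' @export
print.summary.methyl_hmm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  p = %d parameters; AIC = %.2f; BIC = %.2f\n", x$p, x$AIC,
              x$BIC))
  invisible(x)
}

#' @export
coef.methyl_hmm <- function(object, ...) {
  c(stats::setNames(object$betas, paste0("beta", seq_len(object$K))),
    stats::setNames(object$pi, paste0("pi", seq_len(object$K))),
    d0 = object$d0)
}

#' @export
logLik.methyl_hmm <- function(object, ...) {
  structure(object$logLik, df = 2 * object$K, nobs = object$n_obs,
            class = "logLik")
}

#' Decode or compute posteriors for new data
#'
#' `type = "states"` runs the bidirectional Viterbi reconciliation of
#' [decode_states()]; `type = "posterior"` returns the per-site posterior
#' state probabilities (plain forward-backward, forward direction).
#'
#' @param object a fitted [methyl_hmm()].
#' @param newdata a [methylome_table()] or list of observation series.
#' @param type `"states"` or `"posterior"`.
#' @param ... unused.
#' @return For `"states"`, a `"methyl_states"` data frame; for
#'   `"posterior"`, a numeric matrix with one row per site and K columns.
#' @export
predict.methyl_hmm <- function(object, newdata,
                               type = c("states", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "states") return(decode_states(object, newdata))
  series <- as_observation_series(newdata, object$include_uncovered)
  series <- Filter(function(s) length(s$pos) > 0, series)
  do.call(rbind, lapply(series, function(s)
    .fb(s, object$betas, object$pi, object$d0, rep(1, length(s$depth)),
        object$literal_eq1)$gamma))
}

#' Simulate methylomes from a fitted model
#'
#' Draws synthetic methylomes from the generative model of the fit (its
#' `betas`, `pi` and `d0`) using [simulate_methylome()].
#'
#' @param object a fitted [methyl_hmm()].
#' @param nsim number of methylomes.
#' @param seed integer seed; replicate i uses `seed + i - 1`.
#' @param chrom_lengths,mean_gap,mean_depth,max_depth passed to
#'   [simulate_methylome()].
#' @param ... unused.
#' @return A list of `nsim` simulation results (see [simulate_methylome()]).
#' @export
simulate.methyl_hmm <- function(object, nsim = 1, seed = NULL,
                                chrom_lengths = c(chr1 = 1e6),
                                mean_gap = 100, mean_depth = 3,
                                max_depth = 8, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_methylome(chrom_lengths = chrom_lengths, betas = object$betas,
                       d0 = object$d0, mean_gap = mean_gap,
                       mean_depth = mean_depth, max_depth = max_depth,
                       pi = object$pi,
                       seed = if (is.null(seed)) NULL else seed + i - 1))
}

#' Plot a fitted methylation HMM
#'
#' Left panel: stay and switch probabilities as a function of inter-CpG
#' distance (the distance kernel). Right panel: the state methylation means.
#'
#' @param x a fitted [methyl_hmm()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.methyl_hmm <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  d <- seq(0, 5 * x$d0, length.out = 200)
  e <- exp(-d / x$d0)
  stay <- 1 / x$K + (x$K - 1) / x$K * e
  sw <- (1 - e) / x$K
  graphics::plot(d, stay, type = "l", ylim = c(0, 1), xlab = "distance (bp)",
                 ylab = "transition probability",
                 main = sprintf("distance kernel (d0 = %g bp)", x$d0), ...)
  graphics::lines(d, sw, lty = 2)
  graphics::abline(v = x$d0, col = "grey70")
  graphics::legend("topright", c("stay", "switch (each)"), lty = 1:2,
                   bty = "n")
  reg <- assign_regimes(x)
  graphics::barplot(x$betas, names.arg = reg, ylim = c(0, 1),
                    ylab = "state mean methylation",
                    main = sprintf("K = %d regimes", x$K))
  invisible(x)
}

#' Pearson residuals under the decoded states
#'
#' For each covered CpG with a confidently decoded state (not unknown), the
#' Pearson residual of the methylated count under that state's binomial
#' emission: `(m - n beta) / sqrt(n beta (1 - beta))`. Uncovered or unknown
#' sites get `NA`.
#'
#' @param object a fitted [methyl_hmm()].
#' @param newdata a [methylome_table()] or decoded `"methyl_states"` frame.
#' @param ... unused.
#' @return Numeric vector, one entry per site.
#' @export
residuals.methyl_hmm <- function(object, newdata, ...) {
  st <- if (inherits(newdata, "methyl_states")) newdata
        else decode_states(object, newdata)
  n <- st$meth + st$unmeth
  b <- object$betas[st$state]
  out <- (st$meth - n * b) / sqrt(n * b * (1 - b))
  out[n == 0 | is.na(st$state)] <- NA_real_
  out
}
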