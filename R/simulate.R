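## Synthetic methylomes drawn from the exact generative counterpart of the
## segmentation model: CpG positions with geometric spacing, hidden regimes
## following the distance-decay Markov chain, truncated-Poisson read depth
## and binomial methylated counts. Defaults mirror sparse single-oocyte
## bisulfite data: three regimes at 5%/50%/85% methylation, a 1250-bp
## correlation length, ~100-bp CpG spacing and depth ~ Poisson(3) capped at
## the single-nucleus ceiling of 8 reads.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

.sim_positions <- function(len, mean_gap) {
  ## geometric gaps (support >= 1) with mean `mean_gap`
  n_guess <- max(ceiling(len / mean_gap * 1.3), 50)
  pos <- numeric(0)
  last <- 0
  repeat {
    gaps <- stats::rgeom(n_guess, prob = 1 / mean_gap) + 1
    new <- last + cumsum(gaps)
    pos <- c(pos, new[new <= len])
    if (length(new) == 0 || new[length(new)] > len) break
    last <- new[length(new)]
  }
  pos
}

.sim_states <- function(pos, K, pi, d0) {
  n <- length(pos)
  st <- integer(n)
  st[1] <- sample.int(K, 1, prob = pi)
  if (n == 1 || K == 1) return(pmax(st, 1))
  stay <- 1 / K + (K - 1) / K * exp(-diff(pos) / d0)
  u <- stats::runif(n - 1)
  jump <- sample.int(K - 1, n - 1, replace = TRUE)
  for (t in 2:n) {
    if (u[t - 1] < stay[t - 1]) st[t] <- st[t - 1]
    else {
      others <- seq_len(K)[-st[t - 1]]
      st[t] <- others[jump[t - 1]]
    }
  }
  st
}

.sim_depth <- function(n, mean_depth, max_depth) {
  d <- stats::rpois(n, mean_depth)
  while (any(bad <- d > max_depth))
    d[bad] <- stats::rpois(sum(bad), mean_depth)
  d
}

.true_segments <- function(chrom, pos, states, meth, depth, betas) {
  regimes <- assign_regimes(betas)
  r <- rle(states)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1
  out <- data.frame(chrom = chrom, start = pos[s], end = pos[e],
                    state = r$values, regime = regimes[r$values],
                    n_cpg = r$lengths, stringsAsFactors = FALSE)
  out$mean_meth <- vapply(seq_along(s), function(i) {
    rows <- s[i]:e[i]
    tot <- sum(depth[rows])
    if (tot > 0) sum(meth[rows]) / tot else NA_real_
  }, numeric(1))
  out
}

#' Simulate a methylome from the segmentation model
#'
#' Generates per-CpG methylation counts whose statistical structure matches
#' the model assumptions exactly: positions from cumulative geometric gaps,
#' hidden regimes from the distance-decay Markov chain (see
#' [transition_matrix()]), depth from a Poisson distribution truncated at
#' the single-nucleus ceiling, methylated counts Binomial(depth, beta of the
#' regime). Fully deterministic under `seed`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   The default, five 1-Mb chromosomes, yields about 50,000 CpGs.
#' @param betas regime mean methylation levels, strictly in (0, 1).
#' @param d0 distance parameter in bp.
#' @param mean_gap mean inter-CpG spacing in bp (geometric gaps, minimum 1).
#' @param mean_depth mean read depth (Poisson, truncated).
#' @param max_depth depth ceiling; draws above it are redrawn, so simulated
#'   tables pass [filter_coverage_artifacts()] untouched.
#' @param pi initial regime distribution (default uniform).
#' @param seed integer seed.
#' @param sample_id label of the generated table.
#' @return A list of class `"methylome_sim"`: `table` (a
#'   [methylome_table()]), `states` (data frame `chrom`, `pos`, `state` —
#'   the ground-truth path), `segments` (true regime runs with CpG counts
#'   and empirical means), `config` (the generator settings).
#' @examples
#' sim <- simulate_methylome(chrom_lengths = c(chrA = 1e5), seed = 1)
#' table(sim$states$state)
#' @export
simulate_methylome <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6,
                                                 chr3 = 1e6, chr4 = 1e6,
                                                 chr5 = 1e6),
                               betas = c(0.05, 0.50, 0.85), d0 = 1250,
                               mean_gap = 100, mean_depth = 3, max_depth = 8,
                               pi = NULL, seed = NULL, sample_id = "sim") {
  stopifnot(all(betas > 0), all(betas < 1), !is.unsorted(betas),
            d0 > 0, mean_gap > 0, mean_depth > 0, max_depth >= 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  K <- length(betas)
  if (is.null(pi)) pi <- rep(1 / K, K)
  .with_seed(seed, {
    per_chr <- lapply(names(chrom_lengths), function(ch) {
      pos <- .sim_positions(chrom_lengths[[ch]], mean_gap)
      if (length(pos) == 0) return(NULL)
      st <- .sim_states(pos, K, pi, d0)
      dp <- .sim_depth(length(pos), mean_depth, max_depth)
      m <- stats::rbinom(length(pos), dp, betas[st])
      list(chrom = ch, pos = pos, state = st, depth = dp, meth = m)
    })
    per_chr <- Filter(Negate(is.null), per_chr)
    tab <- methylome_table(
      chrom = unlist(lapply(per_chr, function(x) rep(x$chrom, length(x$pos)))),
      pos = unlist(lapply(per_chr, `[[`, "pos")),
      meth = unlist(lapply(per_chr, `[[`, "meth")),
      unmeth = unlist(lapply(per_chr, function(x) x$depth - x$meth)),
      sample_id = sample_id)
    states <- do.call(rbind, lapply(per_chr, function(x)
      data.frame(chrom = x$chrom, pos = x$pos, state = x$state,
                 stringsAsFactors = FALSE)))
    segs <- do.call(rbind, lapply(per_chr, function(x)
      .true_segments(x$chrom, x$pos, x$state, x$meth, x$depth, betas)))
    rownames(states) <- rownames(segs) <- NULL
    structure(list(table = tab, states = states, segments = segs,
                   config = list(chrom_lengths = chrom_lengths, betas = betas,
                                 d0 = d0, mean_gap = mean_gap,
                                 mean_depth = mean_depth,
                                 max_depth = max_depth, pi = pi,
                                 seed = seed)),
              class = "methylome_sim")
  })
}

#' Simulate related methylomes with planted sample-specific loci
#'
#' All samples share one hidden-state backbone (counts are drawn
#' independently per sample), except at the planted loci, where the focal
#' sample and the remaining samples are forced into opposite extreme
#' regimes:
#'
#' * `mode = "focal_hypo"`: focal sample hypomethylated (lowest regime),
#'   every other sample hypermethylated — with a collar of the opposite
#'   (hyper) regime in all samples around the window;
#' * `mode = "others_hypo"`: the reverse case, with a hypo collar.
#'
#' The collar makes each planted window decodable as a segment of its own
#' instead of merging into the flanking shared regime.
#'
#' @param n_samples number of samples (>= 2).
#' @param focal index of the focal sample.
#' @param specific_loci data frame with `chrom`, `start`, `end`, `mode`
#'   (`"focal_hypo"` or `"others_hypo"`); collared windows must not overlap.
#' @param collar_bp collar width in bp on each side (default 2000).
#' @param chrom_lengths,betas,d0,mean_gap,mean_depth,max_depth,pi,seed as in
#'   [simulate_methylome()].
#' @return A list of class `"methylome_multisim"`: `tables` (named list of
#'   [methylome_table()]s), `backbone_states`, `specific_loci` (the truth),
#'   `focal`, `config`.
#' @export
simulate_multisample <- function(n_samples = 4, focal = 1,
                                 specific_loci = NULL, collar_bp = 2000,
                                 chrom_lengths = c(chr1 = 1e6, chr2 = 1e6,
                                                   chr3 = 1e6, chr4 = 1e6,
                                                   chr5 = 1e6),
                                 betas = c(0.05, 0.50, 0.85), d0 = 1250,
                                 mean_gap = 100, mean_depth = 3,
                                 max_depth = 8, pi = NULL, seed = NULL) {
  stopifnot(n_samples >= 2, focal >= 1, focal <= n_samples)
  K <- length(betas)
  if (K < 2) stop("simulate_multisample needs at least two regimes")
  if (!is.null(specific_loci) && nrow(specific_loci)) {
    stopifnot(all(c("chrom", "start", "end", "mode") %in%
                    names(specific_loci)),
              all(specific_loci$mode %in% c("focal_hypo", "others_hypo")))
    ## collared windows must not overlap
    sl <- specific_loci[order(specific_loci$chrom, specific_loci$start), ]
    ext_s <- sl$start - collar_bp
    ext_e <- sl$end + collar_bp
    same <- sl$chrom[-1] == sl$chrom[-nrow(sl)]
    if (nrow(sl) > 1 && any(same & ext_s[-1] <= ext_e[-nrow(sl)]))
      stop("simulate_multisample: planted loci (incl. collars) overlap")
  }
  if (is.null(pi)) pi <- rep(1 / K, K)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  .with_seed(seed, {
    per_chr <- lapply(names(chrom_lengths), function(ch) {
      pos <- .sim_positions(chrom_lengths[[ch]], mean_gap)
      if (length(pos) == 0) return(NULL)
      list(chrom = ch, pos = pos, state = .sim_states(pos, K, pi, d0))
    })
    per_chr <- Filter(Negate(is.null), per_chr)
    names(per_chr) <- vapply(per_chr, `[[`, character(1), "chrom")

    hypo_state <- 1L
    hyper_state <- as.integer(K)
    state_sets <- lapply(seq_len(n_samples), function(s)
      lapply(per_chr, `[[`, "state"))
    if (!is.null(specific_loci) && nrow(specific_loci)) {
      for (i in seq_len(nrow(specific_loci))) {
        ch <- specific_loci$chrom[i]
        if (!ch %in% names(per_chr)) next
        pos <- per_chr[[ch]]$pos
        win <- pos >= specific_loci$start[i] & pos <= specific_loci$end[i]
        col <- !win & pos >= specific_loci$start[i] - collar_bp &
          pos <= specific_loci$end[i] + collar_bp
        f_hypo <- specific_loci$mode[i] == "focal_hypo"
        focal_state <- if (f_hypo) hypo_state else hyper_state
        other_state <- if (f_hypo) hyper_state else hypo_state
        ## collar: opposite of the focal window regime, shared by all samples
        collar_state <- if (f_hypo) hyper_state else hypo_state
        for (s in seq_len(n_samples)) {
          st <- state_sets[[s]][[ch]]
          st[win] <- if (s == focal) focal_state else other_state
          st[col] <- collar_state
          state_sets[[s]][[ch]] <- st
        }
      }
    }
    tables <- lapply(seq_len(n_samples), function(s) {
      parts <- lapply(names(per_chr), function(ch) {
        pos <- per_chr[[ch]]$pos
        st <- state_sets[[s]][[ch]]
        dp <- .sim_depth(length(pos), mean_depth, max_depth)
        m <- stats::rbinom(length(pos), dp, betas[st])
        data.frame(chrom = ch, pos = pos, meth = m, unmeth = dp - m,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, parts)
      methylome_table(df$chrom, df$pos, df$meth, df$unmeth,
                      sample_id = paste0("sample", s))
    })
    names(tables) <- paste0("sample", seq_len(n_samples))
    backbone_states <- do.call(rbind, lapply(per_chr, function(x)
      data.frame(chrom = x$chrom, pos = x$pos, state = x$state,
                 stringsAsFactors = FALSE)))
    rownames(backbone_states) <- NULL
    structure(list(tables = tables, backbone_states = backbone_states,
                   specific_loci = specific_loci, focal = focal,
                   config = list(chrom_lengths = chrom_lengths, betas = betas,
                                 d0 = d0, mean_gap = mean_gap,
                                 mean_depth = mean_depth,
                                 max_depth = max_depth, pi = pi, seed = seed,
                                 collar_bp = collar_bp)),
              class = "methylome_multisim")
  })
}

#' Write a simulated methylome to Bismark coverage format
#'
#' @param sim a [simulate_methylome()] result (or any
#'   [methylome_table()]).
#' @param prefix output prefix; writes `<prefix>.cov` and, for a simulation
#'   object, `<prefix>.truth.bed` (true segments) and
#'   `<prefix>.config.json`.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, prefix) {
  tab <- if (inherits(sim, "methylome_sim")) sim$table else sim
  depth <- tab$meth + tab$unmeth
  pct <- ifelse(depth > 0, 100 * tab$meth / depth, 0)
  cov_path <- paste0(prefix, ".cov")
  utils::write.table(
    data.frame(tab$chrom, tab$pos, tab$pos, pct, tab$meth, tab$unmeth),
    cov_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths <- cov_path
  if (inherits(sim, "methylome_sim")) {
    bed_path <- paste0(prefix, ".truth.bed")
    write_segments_bed(sim$segments, bed_path)
    json_path <- paste0(prefix, ".config.json")
    jsonlite::write_json(sim$config, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, bed_path, json_path)
  }
  invisible(paths)
}
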