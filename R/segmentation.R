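## From decoded per-CpG states to labelled genomic loci, and the locus-level
## analyses: methylation-regime assignment, hypomethylated-locus calling,
## cell-type-specific loci and permutation enrichment against features.

#' Map HMM states to methylation regimes
#'
#' States are in canonical ascending-beta order; with K = 3 they are labelled
#' hypo / intermediate / hyper. With other K the lowest state is `hypo`, the
#' highest `hyper`, and middle states are labelled `intermediate1`,
#' `intermediate2`, ...
#'
#' @param model a fitted [methyl_hmm()] (or a numeric vector of betas).
#' @return Character vector of regime labels, one per state.
#' @export
assign_regimes <- function(model) {
  K <- if (inherits(model, "methyl_hmm")) model$K else length(model)
  if (K == 1) return("hypo")
  if (K == 2) return(c("hypo", "hyper"))
  if (K == 3) return(c("hypo", "intermediate", "hyper"))
  c("hypo", paste0("intermediate", seq_len(K - 2)), "hyper")
}

#' Build segments from decoded states
#'
#' Collapses maximal runs of identical decoded states into genomic segments.
#' Unknown ("un") sites are skipped: they do not break a run when the states
#' flanking them agree, and they belong to no segment. A segment spans the
#' first to the last member CpG of its run. Runs supported by fewer than
#' `min_cpg` covered member CpGs are dropped (kept in the `"dropped"`
#' attribute).
#'
#' @param states a `"methyl_states"` data frame from [decode_states()].
#' @param min_cpg minimum covered CpGs supporting a segment (default 3).
#' @param model the fitted model (for regime labels); defaults to the model
#'   attached to `states`.
#' @return A data frame of class `"segment_table"`, sorted and
#'   non-overlapping, with columns `chrom`, `start`, `end`, `state`,
#'   `regime`, `n_cpg` (member sites), `n_cov` (covered member sites),
#'   `mean_meth` (count-weighted over covered members). Attributes:
#'   `"dropped"` (sub-threshold runs), `"n_un"` (unknown sites skipped).
#' @export
states_to_segments <- function(states, min_cpg = 3,
                               model = attr(states, "model")) {
  K_guess <- suppressWarnings(max(states$state, na.rm = TRUE))
  regimes <- if (!is.null(model)) assign_regimes(model)
             else if (is.finite(K_guess)) assign_regimes(rep(NA_real_, K_guess))
             else "hypo"
  build <- function(df) {
    keep <- !is.na(df$state)
    if (!any(keep)) return(NULL)
    d <- df[keep, , drop = FALSE]
    r <- rle(d$state)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    n <- d$meth + d$unmeth
    out <- lapply(seq_along(r$values), function(i) {
      rows <- idx_start[i]:idx_end[i]
      cov <- n[rows] > 0
      data.frame(chrom = d$chrom[1], start = d$pos[idx_start[i]],
                 end = d$pos[idx_end[i]], state = r$values[i],
                 regime = regimes[r$values[i]], n_cpg = length(rows),
                 n_cov = sum(cov),
                 mean_meth = if (any(cov))
                   sum(d$meth[rows][cov]) / sum(n[rows][cov]) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  segs <- do.call(rbind, lapply(split(states, states$chrom), build))
  n_un <- sum(is.na(states$state))
  if (is.null(segs)) {
    segs <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), state = integer(),
                       regime = character(), n_cpg = integer(),
                       n_cov = integer(), mean_meth = numeric(),
                       stringsAsFactors = FALSE)
    return(structure(segs, class = c("segment_table", "data.frame"),
                     dropped = segs, n_un = n_un))
  }
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  drop <- segs$n_cov < min_cpg
  structure(segs[!drop, , drop = FALSE],
            class = c("segment_table", "data.frame"),
            dropped = segs[drop, , drop = FALSE], n_un = n_un)
}

## Count-weighted methylation of intervals against a methylome table.
## Returns a data frame with meth, total, n_cov per interval.
.interval_counts <- function(table, chrom, start, end, min_depth = 1) {
  n <- length(chrom)
  meth <- total <- n_cov <- numeric(n)
  depth <- table$meth + table$unmeth
  keep <- depth >= min_depth
  tb <- table[keep, , drop = FALSE]
  depth <- depth[keep]
  by_chr <- split(seq_len(nrow(tb)), tb$chrom)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    rows <- by_chr[[ch]]
    if (is.null(rows)) next
    pos <- tb$pos[rows]
    cm <- c(0, cumsum(tb$meth[rows]))
    cn <- c(0, cumsum(depth[rows]))
    lo <- findInterval(start[i] - 1, pos)
    hi <- findInterval(end[i], pos)
    meth[i] <- cm[hi + 1] - cm[lo + 1]
    total[i] <- cn[hi + 1] - cn[lo + 1]
    n_cov[i] <- hi - lo
  }
  data.frame(meth = meth, total = total, n_cov = n_cov)
}

#' Call hypomethylated segments
#'
#' Retains segments whose count-weighted mean methylation in `table`
#' (methylated calls over total calls across covered CpGs inside the
#' interval) does not exceed `threshold`. Segments with no covered CpG in
#' `table` are excluded with a message.
#'
#' @param segments a `"segment_table"` (or any data frame with `chrom`,
#'   `start`, `end`).
#' @param table the [methylome_table()] to evaluate methylation in (possibly
#'   from a different sample than the segmentation).
#' @param threshold maximum mean methylation, inclusive (default 0.20).
#' @param min_depth minimum per-site depth for a CpG to count as covered.
#' @return The retained subset of `segments` with an added `sample_mean`
#'   column.
#' @export
call_hypomethylated <- function(segments, table, threshold = 0.20,
                                min_depth = 1) {
  if (nrow(segments) == 0) {
    segments$sample_mean <- numeric(0)
    return(segments)
  }
  ic <- .interval_counts(table, segments$chrom, segments$start, segments$end,
                         min_depth = min_depth)
  mean_meth <- ifelse(ic$total > 0, ic$meth / ic$total, NA_real_)
  uncov <- is.na(mean_meth)
  if (any(uncov))
    message(sprintf("call_hypomethylated: %d segment(s) with no covered CpG excluded",
                    sum(uncov)))
  segments$sample_mean <- mean_meth
  segments[!uncov & mean_meth <= threshold, , drop = FALSE]
}

#' Per-locus mean methylation across samples
#'
#' @param loci a data frame with `chrom`, `start`, `end`.
#' @param tables a named list of [methylome_table()] objects.
#' @param min_depth minimum per-site depth.
#' @return Numeric matrix, one row per locus, one column per sample; `NA`
#'   where a locus has no covered CpG in a sample.
#' @export
locus_sample_means <- function(loci, tables, min_depth = 1) {
  if (is.null(names(tables)))
    names(tables) <- paste0("sample", seq_along(tables))
  out <- vapply(tables, function(tb) {
    ic <- .interval_counts(tb, loci$chrom, loci$start, loci$end,
                           min_depth = min_depth)
    ifelse(ic$total > 0, ic$meth / ic$total, NA_real_)
  }, numeric(nrow(loci)))
  out <- matrix(out, nrow = nrow(loci),
                dimnames = list(NULL, names(tables)))
  out
}

#' Call cell-type-specific loci
#'
#' A locus is specific to the focal sample if it is hypomethylated (mean
#' methylation at or below `threshold`) in the focal sample while above the
#' threshold in every other sample, or the reverse: above the threshold in
#' the focal sample while hypomethylated in all others. Loci missing data
#' in any sample are never flagged (counted in a message).
#'
#' @param loci a data frame with `chrom`, `start`, `end`.
#' @param sample_means matrix from [locus_sample_means()] (rows = loci).
#' @param focal column name or index of the focal sample.
#' @param threshold hypomethylation threshold, inclusive (default 0.20).
#' @return `loci` with a logical `specific` column.
#' @export
call_specific_loci <- function(loci, sample_means, focal, threshold = 0.20) {
  stopifnot(nrow(sample_means) == nrow(loci), ncol(sample_means) >= 2)
  if (is.character(focal)) focal <- match(focal, colnames(sample_means))
  f <- sample_means[, focal]
  o <- sample_means[, -focal, drop = FALSE]
  has_na <- is.na(f) | apply(o, 1, anyNA)
  if (any(has_na))
    message(sprintf("call_specific_loci: %d locus/loci with missing sample data not flagged",
                    sum(has_na)))
  f_hypo <- f <= threshold
  all_o_hypo <- apply(o <= threshold, 1, all)
  none_o_hypo <- apply(o > threshold, 1, all)
  flag <- (f_hypo & none_o_hypo) | (!f_hypo & all_o_hypo)
  flag[has_na] <- FALSE
  loci$specific <- flag
  loci
}

## number of feature intervals overlapped (>= 1 bp) by any query interval
.count_features_hit <- function(f_by_chr, q_chrom, q_start, q_end) {
  hits <- 0L
  for (ch in names(f_by_chr)) {
    f <- f_by_chr[[ch]]
    qi <- which(q_chrom == ch)
    if (!length(qi)) next
    qs <- q_start[qi]; qe <- q_end[qi]
    ## feature j overlaps some query iff any(qs <= f$end[j] & qe >= f$start[j])
    hit <- logical(nrow(f))
    for (i in seq_along(qs))
      hit <- hit | (qs[i] <= f$end & qe[i] >= f$start)
    hits <- hits + sum(hit)
  }
  hits
}

#' Permutation enrichment of loci over genomic features
#'
#' Counts how many feature intervals are overlapped by at least 1 bp by any
#' locus, and compares this to a null distribution obtained by re-placing
#' the loci uniformly at random within their own chromosomes (lengths
#' preserved; overlaps among placed intervals allowed), `n_perm` times.
#'
#' @param loci data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @param features data frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @param chrom_sizes named numeric vector of chromosome lengths; must cover
#'   every chromosome carrying a locus.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for reproducible placement.
#' @param same_chrom keep each placed locus on its own chromosome (default
#'   `TRUE`); if `FALSE`, chromosomes are drawn with probability
#'   proportional to their placeable length.
#' @return A list of class `"enrichment_test"`: `observed`, `null_mean`,
#'   `null_sd`, `z` (`NA` when the null sd is 0), `n_perm`, `seed`,
#'   `n_features`, `n_loci`, `null` (the permutation counts).
#' @export
feature_enrichment <- function(loci, features, chrom_sizes, n_perm = 1000,
                               seed = NULL, same_chrom = TRUE) {
  f_by_chr <- split(features[c("start", "end")], features$chrom)
  obs <- .count_features_hit(f_by_chr, loci$chrom, loci$start, loci$end)
  n_loci <- nrow(loci)
  if (n_loci == 0) {
    return(structure(list(observed = 0L, null_mean = 0, null_sd = 0,
                          z = NA_real_, n_perm = n_perm, seed = seed,
                          n_features = nrow(features), n_loci = 0L,
                          null = rep(0, n_perm)),
                     class = "enrichment_test"))
  }
  lens <- loci$end - loci$start + 1
  if (any(!loci$chrom %in% names(chrom_sizes)))
    stop("feature_enrichment: chrom_sizes missing a locus chromosome")
  room <- chrom_sizes[loci$chrom] - lens + 1
  if (any(room < 1))
    stop("feature_enrichment: locus longer than its chromosome")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    if (same_chrom) {
      chrom <- loci$chrom
      rm_ <- room
    } else {
      w <- pmax(chrom_sizes - max(lens) + 1, 0)
      chrom <- sample(names(chrom_sizes), n_loci, replace = TRUE, prob = w)
      rm_ <- chrom_sizes[chrom] - lens + 1
      if (any(rm_ < 1)) { null[p] <- NA; next }
    }
    start <- floor(stats::runif(n_loci, 1, rm_ + 1))
    null[p] <- .count_features_hit(f_by_chr, chrom, start, start + lens - 1)
  }
  null <- null[!is.na(null)]
  m <- mean(null); s <- stats::sd(null)
  structure(list(observed = obs, null_mean = m, null_sd = s,
                 z = if (is.na(s) || s == 0) NA_real_ else (obs - m) / s,
                 n_perm = length(null), seed = seed,
                 n_features = nrow(features), n_loci = n_loci, null = null),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("feature enrichment: observed %d vs %.1f +/- %.1f expected at random (%d permutations)\n",
              x$observed, x$null_mean, x$null_sd, x$n_perm))
  if (is.na(x$z)) cat("  z undefined (null sd = 0)\n")
  else cat(sprintf("  z = %.2f\n", x$z))
  invisible(x)
}
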