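## Descriptive methylome statistics: global level, per-feature profiles,
## fixed-width bins, between-sample rank correlation, tandem-repeat
## methylation via bisulfite-converted reference variants.

#' Global CpG methylation level
#'
#' Count-weighted by default: total methylated calls over total calls across
#' sites with depth at least `min_depth`. `per_site = TRUE` instead averages
#' the per-site methylated fractions (each covered CpG weighted equally).
#'
#' @param table a [methylome_table()].
#' @param min_depth minimum depth for a site to contribute (default 1).
#' @param per_site average per-site fractions instead of pooling counts.
#' @return Fraction in `[0, 1]`.
#' @examples
#' mt <- methylome_table("chr1", c(100, 200), meth = c(1, 3), unmeth = c(1, 1))
#' global_methylation(mt)  # 4/6
#' @export
global_methylation <- function(table, min_depth = 1, per_site = FALSE) {
  depth <- cpg_depth(table)
  keep <- depth >= max(min_depth, 1)
  if (!any(keep)) stop("global_methylation: no covered sites")
  if (per_site) return(mean(table$meth[keep] / depth[keep]))
  sum(table$meth[keep]) / sum(depth[keep])
}

#' Per-feature methylation
#'
#' Count-weighted mean methylation of each feature interval over the CpGs it
#' contains; intervals without a covered CpG are reported as `NA`. The
#' result carries a distribution summary (histogram over `[0, 1]` plus the
#' fractions below 40% and above 60%, the split at which hypo- and
#' hypermethylated loci separate) as attribute `"summary"`, suitable for
#' spotting the bimodality typical of promoters and CpG islands.
#'
#' @param table a [methylome_table()].
#' @param features data frame with `chrom`, `start`, `end` (1-based
#'   inclusive, e.g. from [read_bed()]).
#' @param min_depth minimum per-site depth (default 1).
#' @return `features` with added columns `n_cpg` (covered CpGs) and
#'   `mean_meth`.
#' @export
feature_methylation <- function(table, features, min_depth = 1) {
  ic <- .interval_counts(table, features$chrom, features$start, features$end,
                         min_depth = min_depth)
  features$n_cpg <- ic$n_cov
  features$mean_meth <- ifelse(ic$total > 0, ic$meth / ic$total, NA_real_)
  structure(features,
            summary = methylation_distribution(features$mean_meth))
}

#' Summary of a methylation-level distribution
#'
#' @param x numeric vector of methylation fractions (NAs dropped).
#' @param breaks histogram breaks over `[0, 1]`.
#' @return A list: `hist` (a [graphics::hist()] object, not plotted), `n`,
#'   `frac_hypo` (share < 0.40), `frac_hyper` (share > 0.60).
#' @export
methylation_distribution <- function(x, breaks = seq(0, 1, by = 0.05)) {
  x <- x[!is.na(x)]
  list(hist = if (length(x)) graphics::hist(x, breaks = breaks, plot = FALSE)
              else NULL,
       n = length(x),
       frac_hypo = if (length(x)) mean(x < 0.40) else NA_real_,
       frac_hyper = if (length(x)) mean(x > 0.60) else NA_real_)
}

#' Methylation of fixed-width genomic bins
#'
#' Tiles every chromosome from coordinate 1 in windows of `bin_size` bp
#' (window b covers positions `(b-1) * bin_size + 1` to `b * bin_size`) and
#' reports the count-weighted mean methylation per bin. Bins supported by
#' fewer than `min_cpg` covered CpGs keep their counts but have `mean_meth`
#' set to `NA` (missing), so total counts are conserved across the output.
#'
#' @param table a [methylome_table()].
#' @param bin_size window size in bp (default 5000).
#' @param min_cpg minimum covered CpGs for a bin to get a mean (default 3).
#' @param min_depth minimum per-site depth (default 1).
#' @return Data frame with `chrom`, `bin_start`, `bin_end`, `n_cpg`, `meth`,
#'   `unmeth`, `mean_meth`; one row per bin that contains at least one
#'   qualifying CpG.
#' @export
bin_methylation <- function(table, bin_size = 5000, min_cpg = 3,
                            min_depth = 1) {
  stopifnot(bin_size >= 1)
  depth <- cpg_depth(table)
  tb <- table[depth >= max(min_depth, 1), , drop = FALSE]
  if (nrow(tb) == 0)
    return(data.frame(chrom = character(), bin_start = numeric(),
                      bin_end = numeric(), n_cpg = integer(),
                      meth = numeric(), unmeth = numeric(),
                      mean_meth = numeric(), stringsAsFactors = FALSE))
  bin <- (tb$pos - 1) %/% bin_size
  key <- paste(tb$chrom, formatC(bin, width = 12, flag = "0"), sep = "\r")
  meth <- rowsum(tb$meth, key)          # rowsum sorts by key; zero-padding
  unmeth <- rowsum(tb$unmeth, key)      # makes that numeric bin order
  n_cpg <- rowsum(rep(1L, nrow(tb)), key)
  parts <- strsplit(rownames(meth), "\r", fixed = TRUE)
  b <- as.numeric(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    bin_start = b * bin_size + 1,
                    bin_end = (b + 1) * bin_size,
                    n_cpg = as.integer(n_cpg),
                    meth = as.numeric(meth),
                    unmeth = as.numeric(unmeth),
                    stringsAsFactors = FALSE)
  total <- out$meth + out$unmeth
  out$mean_meth <- ifelse(out$n_cpg >= min_cpg & total > 0,
                          out$meth / total, NA_real_)
  out <- out[order(out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank correlation of binned methylation between two samples
#'
#' Spearman correlation over the bins that are non-missing in both samples
#' (ties receive average ranks).
#'
#' @param bins_a,bins_b outputs of [bin_methylation()] on two samples (same
#'   `bin_size`).
#' @return A list with `rho` and `n_shared_bins`.
#' @export
correlate_samples <- function(bins_a, bins_b) {
  m <- merge(bins_a[c("chrom", "bin_start", "mean_meth")],
             bins_b[c("chrom", "bin_start", "mean_meth")],
             by = c("chrom", "bin_start"), suffixes = c("_a", "_b"))
  m <- m[!is.na(m$mean_meth_a) & !is.na(m$mean_meth_b), , drop = FALSE]
  if (nrow(m) < 3)
    stop("correlate_samples: fewer than 3 shared non-missing bins")
  list(rho = stats::cor(m$mean_meth_a, m$mean_meth_b, method = "spearman"),
       n_shared_bins = nrow(m))
}

.check_dna <- function(x) {
  s <- strsplit(toupper(x), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence contains non-ACGT symbols")
  s
}

.revcomp_str <- function(x)
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")

## Conversion of a tandem monomer, always written against the top strand.
## The monomer context is circular (the repeat is tandem, so the last base
## is followed by the first). Top strand: unmethylated cytosines read as T.
## Bottom strand: its cytosines pair with top-strand guanines, so bottom
## conversion reads as G -> A against the top strand; a bottom cytosine is
## in CpG context exactly when the top-strand G is preceded by C.
.convert_top <- function(s, methylated) {
  nxt <- c(s[-1], s[1])
  conv <- s == "C" & !(methylated & nxt == "G")
  s[conv] <- "T"
  paste(s, collapse = "")
}

.convert_bottom <- function(s, methylated) {
  prv <- c(s[length(s)], s[-length(s)])
  conv <- s == "G" & !(methylated & prv == "C")
  s[conv] <- "A"
  paste(s, collapse = "")
}

#' Bisulfite-converted reference variants of a tandem repeat monomer
#'
#' Builds the four reference sequences a read from a non-directional
#' bisulfite library can match: top and bottom strand, each in a fully
#' methylated variant (only CpG-context cytosines survive conversion) and a
#' fully unmethylated variant (every cytosine converts). All variants are
#' written against the top strand, so top-strand conversion reads as C to T
#' and bottom-strand conversion as G to A. CpG context is evaluated
#' circularly, since the monomer occurs in tandem.
#'
#' @param monomer DNA string over A/C/G/T.
#' @return An object of class `"repeat_reference"`: a list with `monomer`
#'   and `variants` (named character vector `top_methylated`,
#'   `top_unmethylated`, `bottom_methylated`, `bottom_unmethylated`).
#' @examples
#' build_repeat_references("ACGTCG")$variants
#' @export
build_repeat_references <- function(monomer) {
  s <- .check_dna(monomer)
  variants <- c(top_methylated = .convert_top(s, TRUE),
                top_unmethylated = .convert_top(s, FALSE),
                bottom_methylated = .convert_bottom(s, TRUE),
                bottom_unmethylated = .convert_bottom(s, FALSE))
  structure(list(monomer = paste(s, collapse = ""), variants = variants),
            class = "repeat_reference")
}

## best ungapped match fraction of read against the tandem extension of ref
.tandem_score <- function(read, ref) {
  L <- nchar(ref)
  reps <- ceiling(nchar(read) / L) + 1
  tandem <- strsplit(strrep(ref, reps), "")[[1]]
  r <- strsplit(read, "")[[1]]
  n <- length(r)
  best <- 0
  for (off in seq_len(L)) {
    sc <- sum(r == tandem[off:(off + n - 1)]) / n
    if (sc > best) best <- sc
  }
  best
}

#' Classify reads as methylated or unmethylated repeat copies
#'
#' Scores each read (and its reverse complement, since a bottom-strand read
#' arrives in its own orientation) against the four converted reference
#' variants by its best ungapped match over the tandem concatenation of the
#' monomer, and assigns it to the methylated or unmethylated pool according
#' to the better of the strand scores on each side. Reads scoring below
#' `min_score` on every variant, or tying between the pools (as happens for
#' CpG-free monomers, whose variant pairs coincide), stay unassigned.
#'
#' @param reads character vector of read sequences.
#' @param refs a [build_repeat_references()] object.
#' @param min_score minimum match fraction for assignment (default 0.9).
#' @return A list: `methylated`, `unmethylated`, `unassigned` (counts),
#'   `fraction` (`methylated / (methylated + unmethylated)`, `NA` if no read
#'   was assigned) and `assignments` (per-read data frame with both scores
#'   and the pool).
#' @export
classify_repeat_reads <- function(reads, refs, min_score = 0.9) {
  stopifnot(inherits(refs, "repeat_reference"))
  v <- refs$variants
  score <- function(rds, keys) max(vapply(v[keys], function(ref)
    max(vapply(rds, .tandem_score, numeric(1), ref = ref)), numeric(1)))
  res <- lapply(reads, function(rd) {
    rds <- unique(c(toupper(rd), .revcomp_str(toupper(rd))))
    sm <- score(rds, c("top_methylated", "bottom_methylated"))
    su <- score(rds, c("top_unmethylated", "bottom_unmethylated"))
    pool <- if (max(sm, su) < min_score || isTRUE(all.equal(sm, su))) "unassigned"
            else if (sm > su) "methylated" else "unmethylated"
    data.frame(score_methylated = sm, score_unmethylated = su, pool = pool,
               stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, res)
  nm <- sum(asg$pool == "methylated")
  nu <- sum(asg$pool == "unmethylated")
  list(methylated = nm, unmethylated = nu,
       unassigned = sum(asg$pool == "unassigned"),
       fraction = if (nm + nu > 0) nm / (nm + nu) else NA_real_,
       assignments = asg)
}

#' Compare global methylation levels between two groups of samples
#'
#' A plain two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-sample
#' global methylation levels, e.g. to compare two developmental stages.
#'
#' @param x,y numeric vectors of per-sample global methylation fractions.
#' @return An object of class `"htest"` from [stats::wilcox.test()].
#' @export
compare_global_levels <- function(x, y) {
  stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
}

#' Read sequences from a FASTA file
#'
#' Minimal FASTA reader for repeat monomers and read sets (plain or gzip).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("read_fasta: no FASTA headers in '", path, "'")
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}
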