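## Bismark file readers, strand merging, single-cell coverage QC, BED output.
## All parsing is plain tab-separated text; gzip is handled transparently by
## the connection layer.

.open_text <- function(path) gzfile(path, "rt")

.check_fields <- function(path, n_expected) {
  con <- .open_text(path)
  on.exit(close(con))
  nf <- utils::count.fields(con, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0) return(invisible(0L))
  bad <- which(nf != n_expected)
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': expected %d tab-separated fields, found %d",
                 bad[1], path, n_expected, nf[bad[1]]))
  invisible(length(nf))
}

.read_tsv <- function(path, col_classes) {
  con <- .open_text(path)
  on.exit(close(con))
  utils::read.table(con, sep = "\t", quote = "", comment.char = "",
                    colClasses = col_classes, stringsAsFactors = FALSE)
}

.stop_bad_numeric <- function(x, path, what) {
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': non-numeric %s field",
                 bad[1], path, what))
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column `.cov` / `.cov.gz` format written by
#' `bismark2bedGraph`/`coverage2cytosine`: chromosome, start, end (1-based,
#' start == end for a CpG), methylation percentage, count methylated, count
#' unmethylated. The percentage column is ignored and recomputed from the
#' counts. Unsorted input is sorted on load with a notice; duplicated
#' positions are an error unless `dedup = "sum"`.
#'
#' @param path file path (plain or gzip).
#' @param dedup `"error"` (default) or `"sum"`: how to treat repeated
#'   `(chrom, pos)` lines.
#' @param sample_id label for the resulting table; defaults to the file name.
#' @return A [methylome_table()].
#' @export
read_bismark_cov <- function(path, dedup = c("error", "sum"),
                             sample_id = NULL) {
  dedup <- match.arg(dedup)
  if (is.null(sample_id))
    sample_id <- sub("\\.(cov|txt)(\\.gz)?$", "", basename(path))
  n <- .check_fields(path, 6L)
  if (n == 0L)
    return(methylome_table(character(), numeric(), numeric(), numeric(),
                           sample_id = sample_id))
  df <- .read_tsv(path, c("character", "numeric", "numeric", "numeric",
                          "numeric", "numeric"))
  .stop_bad_numeric(df[[2]], path, "position")
  .stop_bad_numeric(df[[5]], path, "methylated-count")
  .stop_bad_numeric(df[[6]], path, "unmethylated-count")
  out <- data.frame(chrom = df[[1]], pos = df[[2]], meth = df[[5]],
                    unmeth = df[[6]], stringsAsFactors = FALSE)
  o <- order(out$chrom, out$pos)
  if (!identical(o, seq_len(nrow(out))))
    message("read_bismark_cov: input not sorted by (chrom, pos); sorting")
  out <- out[o, , drop = FALSE]
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    if (dedup == "error")
      stop("read_bismark_cov: duplicated position ",
           key[anyDuplicated(key)], " (use dedup = \"sum\" to merge)")
    out <- .aggregate_counts(out)
  }
  methylome_table(out$chrom, out$pos, out$meth, out$unmeth,
                  sample_id = sample_id)
}

.aggregate_counts <- function(df) {
  key <- paste(df$chrom, df$pos)
  meth <- rowsum(df$meth, key, reorder = FALSE)
  unmeth <- rowsum(df$unmeth, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(chrom = df$chrom[first], pos = df$pos[first],
             meth = as.numeric(meth), unmeth = as.numeric(unmeth),
             stringsAsFactors = FALSE)
}

#' Read a Bismark cytosine (CX / CpG) report
#'
#' Parses the 7-column per-cytosine report (chromosome, position, strand,
#' count methylated, count unmethylated, context, trinucleotide). Only
#' CpG-context rows are retained; by default the two strands of each CpG
#' dinucleotide are merged onto the plus-strand coordinate with
#' [merge_cpg_strands()]. Zero-coverage rows are kept unless
#' `drop_uncovered = TRUE`.
#'
#' @param path file path (plain or gzip).
#' @param merge_strands merge symmetric-strand records (default `TRUE`).
#' @param drop_uncovered drop rows with depth 0 (default `FALSE`).
#' @param sample_id label for the resulting table.
#' @return A [methylome_table()]. When `merge_strands = FALSE` the table
#'   carries an extra `strand` column.
#' @export
read_cx_report <- function(path, merge_strands = TRUE, drop_uncovered = FALSE,
                           sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(txt|CX_report\\.txt)(\\.gz)?$", "", basename(path))
  n <- .check_fields(path, 7L)
  empty <- methylome_table(character(), numeric(), numeric(), numeric(),
                           sample_id = sample_id)
  if (n == 0L) return(empty)
  df <- .read_tsv(path, c("character", "numeric", "character", "numeric",
                          "numeric", "character", "character"))
  .stop_bad_numeric(df[[2]], path, "position")
  keep <- df[[6]] == "CpG"
  if (!any(keep)) {
    warning("read_cx_report: no CpG-context rows in '", path, "'")
    return(empty)
  }
  df <- df[keep, , drop = FALSE]
  if (drop_uncovered) df <- df[df[[4]] + df[[5]] > 0, , drop = FALSE]
  out <- data.frame(chrom = df[[1]], pos = df[[2]], strand = df[[3]],
                    meth = df[[4]], unmeth = df[[5]], stringsAsFactors = FALSE)
  if (merge_strands) return(merge_cpg_strands(out, sample_id = sample_id))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("methylome_table", "data.frame"),
            sample_id = sample_id)
}

#' Merge symmetric CpG strand records
#'
#' A CpG dinucleotide carries a methylatable cytosine on both strands: the
#' minus-strand cytosine at position `p` pairs with the plus-strand cytosine
#' at `p - 1`. This maps every minus-strand record onto its plus-strand
#' coordinate and sums the counts, yielding exactly one record per
#' dinucleotide. Total methylated and unmethylated counts are conserved.
#'
#' @param x a data frame with columns `chrom`, `pos`, `meth`, `unmeth` and
#'   optionally `strand` (records without a strand column are taken as plus).
#' @param sample_id label for the resulting table.
#' @return A [methylome_table()] on plus-strand coordinates.
#' @export
merge_cpg_strands <- function(x, sample_id = attr(x, "sample_id") %||% "sample") {
  if (nrow(x) == 0)
    return(methylome_table(character(), numeric(), numeric(), numeric(),
                           sample_id = sample_id))
  strand <- if ("strand" %in% names(x)) x$strand else rep("+", nrow(x))
  pos <- ifelse(strand == "-", x$pos - 1, x$pos)
  df <- data.frame(chrom = x$chrom, pos = pos, meth = x$meth,
                   unmeth = x$unmeth, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  df <- .aggregate_counts(df)
  methylome_table(df$chrom, df$pos, df$meth, df$unmeth, sample_id = sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter single-cell coverage artifacts
#'
#' In one diplotene nucleus each chromosome is present as four chromatids and
#' each bisulfite-converted strand is sequenced independently, so at most
#' 4 x 2 = 8 unique reads can legitimately cover a CpG. Sites covered more
#' deeply are artifacts or somatic contamination and are removed.
#'
#' @param x a [methylome_table()].
#' @param max_depth maximum legitimate depth (default 8; depth equal to
#'   `max_depth` is kept).
#' @return A list with `table` (the filtered table) and `artifact_fraction`
#'   (removed sites as a fraction of sites with depth >= 1).
#' @examples
#' mt <- methylome_table("chr1", 1:5 * 100, meth = c(1, 4, 8, 9, 12),
#'                       unmeth = 0)
#' filter_coverage_artifacts(mt)$artifact_fraction  # 2/5
#' @export
filter_coverage_artifacts <- function(x, max_depth = 8) {
  stopifnot(max_depth >= 1)
  depth <- cpg_depth(x)
  drop <- depth > max_depth
  n_cov <- sum(depth >= 1)
  frac <- if (n_cov > 0) sum(drop) / n_cov else 0
  list(table = x[!drop, , drop = FALSE], artifact_fraction = frac)
}

#' Write segments as BED6
#'
#' Converts 1-based inclusive segment intervals to 0-based half-open BED,
#' with the regime label as the name field and `round(100 * mean_meth)` as
#' the score.
#'
#' @param segments a segment table from [states_to_segments()] (columns
#'   `chrom`, `start`, `end`, `regime`, `mean_meth`).
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_segments_bed <- function(segments, path) {
  o <- order(segments$chrom, segments$start)
  segments <- segments[o, , drop = FALSE]
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1,
                    end = segments$end,
                    name = segments$regime,
                    score = round(100 * segments$mean_meth),
                    strand = rep(".", nrow(segments)),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic features
#'
#' Reads BED3+ into a feature table with 1-based inclusive coordinates
#' (`start = BED start + 1`, `end = BED end`), the representation used
#' throughout the package.
#'
#' @param path BED file path (plain or gzip).
#' @param set_name label for the feature set; defaults to the file name.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`; carries a `set_name`
#'   attribute.
#' @export
read_bed <- function(path, set_name = NULL) {
  if (is.null(set_name)) set_name <- sub("\\.bed(\\.gz)?$", "", basename(path))
  con <- .open_text(path)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, sep = "\t", quote = "", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, set_name = set_name))
  }
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]) + 1,
                    end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (ncol(df) >= 5) out$score <- df[[5]]
  if (ncol(df) >= 6) out$strand <- as.character(df[[6]])
  if (any(out$start > out$end))
    stop("read_bed: interval with start > end in '", path, "'")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, set_name = set_name)
}
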