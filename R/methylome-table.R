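#' Per-CpG methylome table
#'
#' The basic container of the package: one row per CpG dinucleotide with the
#' number of methylated and unmethylated calls observed at that position.
#' Coordinates are 1-based (the Bismark coverage convention) and refer to the
#' cytosine on the plus strand of the CpG; rows are kept sorted by
#' `(chrom, pos)` and duplicate positions are an error.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (>= 1).
#' @param meth,unmeth non-negative integer counts of methylated and
#'   unmethylated calls. `meth + unmeth` is the read depth of the site; zero
#'   is allowed (an uncovered CpG, as written by Bismark cytosine reports).
#' @param sample_id label attached to the table.
#' @return A data frame of class `"methylome_table"` with columns `chrom`,
#'   `pos`, `meth`, `unmeth` and a `sample_id` attribute.
#' @examples
#' mt <- methylome_table("chr1", c(100, 250), meth = c(2, 0), unmeth = c(2, 3))
#' cpg_depth(mt)
#' @export
methylome_table <- function(chrom, pos, meth, unmeth, sample_id = "sample") {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   meth = as.numeric(meth), unmeth = as.numeric(unmeth),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyNA(df)) stop("methylome_table: NA values are not allowed")
    if (any(df$pos < 1)) stop("methylome_table: positions must be >= 1")
    if (any(df$meth < 0) || any(df$unmeth < 0))
      stop("methylome_table: counts must be non-negative")
    o <- order(df$chrom, df$pos)
    df <- df[o, , drop = FALSE]
    key <- paste(df$chrom, df$pos)
    if (anyDuplicated(key))
      stop("methylome_table: duplicate position ", key[anyDuplicated(key)])
  }
  rownames(df) <- NULL
  structure(df, class = c("methylome_table", "data.frame"),
            sample_id = sample_id)
}

#' @export
`[.methylome_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- class(x)
    attr(out, "sample_id") <- attr(x, "sample_id")
  }
  out
}

#' Read depth per CpG site
#'
#' @param x a [methylome_table()].
#' @return Numeric vector `meth + unmeth`.
#' @export
cpg_depth <- function(x) x$meth + x$unmeth

#' @export
print.methylome_table <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("methylome_table '%s': %d CpG sites on %d chromosome(s)\n",
              attr(x, "sample_id"), n, length(unique(x$chrom))))
  if (n) {
    cov <- cpg_depth(x) > 0
    cat(sprintf("  covered sites: %d (%.1f%%), mean depth %.2f\n",
                sum(cov), 100 * mean(cov), mean(cpg_depth(x))))
    if (any(cov))
      cat(sprintf("  global methylation (count-weighted): %.1f%%\n",
                  100 * sum(x$meth) / sum(x$meth + x$unmeth)))
    print(utils::head(as.data.frame(x), 6))
    if (n > 6) cat("  ...", n - 6, "more rows\n")
  }
  invisible(x)
}
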