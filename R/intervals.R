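#' Genomic intervals (1-based, inclusive)
#'
#' All coordinates inside the package are 1-based and inclusive at both ends,
#' the convention in which mapping results such as "chr1:93,846,273 to
#' 93,867,646" are reported. Conversion to 0-based half-open happens only at
#' the BED file boundary ([write_bed()], [read_bed()]).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive endpoints, `start <= end`.
#' @return An object of class `genomic_interval`: a list with elements
#'   `chrom`, `start`, `end`.
#' @examples
#' iv <- genomic_interval("chr1", 93846273, 93867646)
#' interval_length(iv)  # 21374 bp, i.e. 21.4 kb
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1) {
    stop("interval start must be >= 1 (coordinates are 1-based inclusive)")
  }
  if (start > end) stop("interval start must be <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' Interval length in base pairs
#'
#' Length under the 1-based inclusive convention: `end - start + 1`.
#'
#' @param x A `genomic_interval`.
#' @return Numeric length in bp.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s bp)\n",
              x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              format(interval_length(x), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%.0f-%.0f", x$chrom, x$start, x$end)
}

# intersection of two intervals on the same chromosome; NULL if empty
intersect_interval <- function(a, b) {
  if (a$chrom != b$chrom) return(NULL)
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (s > e) return(NULL)
  genomic_interval(a$chrom, s, e)
}

contains_position <- function(iv, chrom, pos) {
  iv$chrom == chrom & pos >= iv$start & pos <= iv$end
}
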