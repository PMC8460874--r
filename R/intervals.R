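#' Genomic intervals: the coordinate currency
#'
#' All coordinates in this package are 1-based and inclusive on both ends, the
#' GTF/SAM convention: an interval \code{start..end} has length
#' \code{end - start + 1}. BED input (0-based, half-open) is converted at the
#' I/O boundary and never circulates internally.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 1-based inclusive; \code{end >= start}.
#' @param strand one of \code{"+"}, \code{"-"}, \code{"*"} (unstranded),
#'   recycled to length.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} and class \code{"genomic_interval"}.
#' @examples
#' gi <- genomic_interval("chr8", 6624896, 6625037, "+")
#' gi_length(gi)  # 142
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- rep_len(as.character(strand), n)
  if (anyNA(start) || anyNA(end)) stop("interval coordinates must be integers")
  if (any(start < 1L)) stop("interval start must be >= 1 (1-based coordinates)")
  if (any(end < start)) stop("interval end must be >= start")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  structure(data.frame(chrom = chrom, start = start, end = end,
                       strand = strand, stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' Interval length on inclusive coordinates
#' @param x a genomic_interval (or any data.frame with start/end columns).
#' @return integer vector, \code{end - start + 1}.
#' @export
gi_length <- function(x) as.integer(x$end) - as.integer(x$start) + 1L

#' Do two intervals overlap by at least one base?
#' @param a,b data.frames with chrom/start/end columns (recycled pairwise).
#' @return logical vector.
#' @export
gi_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start <= b$end & b$start <= a$end
}

## internal: interval data.frame -> GRanges (strand '*' kept)
gi_to_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start, x$end),
                         strand = strand)
}

#' Convert BED (0-based half-open) coordinates to internal 1-based inclusive
#' @param bed_start,bed_end numeric vectors as printed in a BED file.
#' @return list with components \code{start}, \code{end} (1-based inclusive).
#' @export
bed_to_internal <- function(bed_start, bed_end) {
  list(start = as.integer(bed_start) + 1L, end = as.integer(bed_end))
}

#' Convert internal 1-based inclusive coordinates to BED
#' @param start,end internal coordinates.
#' @return list with components \code{bed_start}, \code{bed_end}.
#' @export
internal_to_bed <- function(start, end) {
  list(bed_start = as.integer(start) - 1L, bed_end = as.integer(end))
}

#' Opposite strand
#' @param strand character vector over {+,-,*}.
#' @return character vector; '*' maps to '*'.
#' @export
flip_strand <- function(strand) {
  out <- strand
  out[strand == "+"] <- "-"
  out[strand == "-"] <- "+"
  out
}
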