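#' Genomic intervals (1-based, inclusive)
#'
#' All coordinates inside the package are 1-based and inclusive on both
#' ends, the convention under which a region printed as
#' \code{Chr1:212,499,519-213,348,230} has length 848,712 nt.  Only BED
#' input/output converts to and from the 0-based half-open convention.
#'
#' @param chrom Chromosome name (character).
#' @param start 1-based inclusive start position(s).
#' @param end 1-based inclusive end position(s); must satisfy
#'   \code{end >= start}.
#' @return A data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, one row per interval.
#' @examples
#' iv <- genomic_interval("Chr1", 212499519, 213348230)
#' interval_length(iv)  # 848712
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop_allseq("interval coordinates must be non-missing numbers")
  if (any(start < 1))
    stop_allseq("invalid interval: start < 1 (start=%s)", start[start < 1][1])
  if (any(end < start))
    stop_allseq("invalid interval: end < start (%s:%s-%s)",
                chrom[end < start][1], start[end < start][1], end[end < start][1])
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Inclusive length of a genomic interval
#'
#' @param iv A data.frame with \code{start} and \code{end} columns
#'   (1-based inclusive), e.g. from [genomic_interval()].
#' @return Integer vector of lengths, \code{end - start + 1}.
#' @export
interval_length <- function(iv) {
  if (any(iv$end < iv$start))
    stop_allseq("invalid interval: end < start")
  as.numeric(iv$end) - as.numeric(iv$start) + 1
}

# internal <-> BED coordinate conversion (BED is 0-based half-open)
to_bed_coords <- function(start, end) list(start = start - 1, end = end)
from_bed_coords <- function(start, end) list(start = start + 1, end = end)

# data.frame of intervals -> GRanges (shared helper for overlap machinery)
as_gr <- function(df, start = "start", end = "end", chrom = "chrom") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]], end = df[[end]]))
}
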