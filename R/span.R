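#' Compute mate-pair spans and the intra/inter partition
#'
#' For same-chromosome (intra) pairs the span is the outer distance
#' covered by the pair, inclusive of both read extremities:
#' \code{max(end1, end2) - min(start1, start2) + 1}.  Pairs whose mates
#' map to different chromosomes are classed inter-chromosomal
#' (translocation candidates) and carry no span.
#'
#' @param pairs data.frame of aligned pairs as returned by
#'   [read_pairs()] (only the MP fraction is meaningful here).
#' @return data.frame with columns \code{pair_id, chrom1, chrom2,
#'   outer_start, outer_end, span, locus_class} (\code{"INTRA"} or
#'   \code{"INTER"}); attribute \code{partition} = c(n_intra, n_inter).
#' @export
compute_spans <- function(pairs) {
  intra <- pairs$chrom1 == pairs$chrom2
  read1_left <- pairs$start1 <= pairs$start2
  outer_start <- ifelse(intra, pmin(pairs$start1, pairs$start2), NA_real_)
  outer_end <- ifelse(intra, pmax(pairs$end1, pairs$end2), NA_real_)
  out <- data.frame(
    pair_id = pairs$pair_id,
    chrom1 = pairs$chrom1, chrom2 = pairs$chrom2,
    outer_start = outer_start, outer_end = outer_end,
    # innermost edges: end of the leftmost read, start of the rightmost
    inner_left_end = ifelse(intra,
                            ifelse(read1_left, pairs$end1, pairs$end2),
                            NA_real_),
    inner_right_start = ifelse(intra,
                               ifelse(read1_left, pairs$start2, pairs$start1),
                               NA_real_),
    span = ifelse(intra, outer_end - outer_start + 1, NA_real_),
    locus_class = ifelse(intra, "INTRA", "INTER"),
    stringsAsFactors = FALSE)
  attr(out, "partition") <- c(n_intra = sum(intra), n_inter = sum(!intra))
  out
}

#' Fit span-discordance thresholds from intra-chromosomal spans
#'
#' Summarises the span distribution by its quartiles (linear
#' interpolation on the sorted sample, the "type 7" estimator) and
#' derives the boxplot-style outlier thresholds
#' \code{Q1 - 1.5*IQR} and \code{Q3 + 1.5*IQR}.  Spans below the lower
#' threshold support insertions, spans above the upper threshold
#' support deletions.
#'
#' @param spans Numeric vector of spans (bp); at least 4 values.
#' @return An object of class \code{span_stats} with elements
#'   \code{q1, median, q3, iqr, lower_threshold, upper_threshold,
#'   n_spans}.
#' @examples
#' fit_span_thresholds(c(5700, 5700, 6000, 6300, 6300))
#' @export
fit_span_thresholds <- function(spans) {
  spans <- spans[!is.na(spans)]
  if (length(spans) < 4)
    stop_allseq("insufficient data: need at least 4 spans, got %d",
                length(spans))
  q <- unname(quantile(spans, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  structure(list(q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 lower_threshold = q[1] - 1.5 * iqr,
                 upper_threshold = q[3] + 1.5 * iqr,
                 n_spans = length(spans), fixed = FALSE),
            class = "span_stats")
}

#' Supply fixed span thresholds instead of fitting them
#'
#' Builds a \code{span_stats} object around externally chosen
#' discordance thresholds (e.g. the 4,800 / 7,200 bp pair used for a
#' ~6 kb library with 0.6 kb IQR), for use when thresholds should be
#' reproduced rather than re-fitted.
#'
#' @param lower,upper Lower/upper discordance thresholds (bp).
#' @param median Library median span (bp); defaults to the midpoint.
#' @return A \code{span_stats} object; its quartiles are back-computed
#'   from the thresholds under the 1.5*IQR rule.
#' @export
fixed_span_thresholds <- function(lower, upper, median = (lower + upper) / 2) {
  if (upper < lower) stop_allseq("upper threshold must be >= lower")
  # lower = q1 - 1.5 iqr, upper = q3 + 1.5 iqr, iqr = q3 - q1
  iqr <- (upper - lower) / 4
  structure(list(q1 = lower + 1.5 * iqr, median = median,
                 q3 = upper - 1.5 * iqr, iqr = iqr,
                 lower_threshold = lower, upper_threshold = upper,
                 n_spans = NA_integer_, fixed = TRUE),
            class = "span_stats")
}

#' @export
print.span_stats <- function(x, ...) {
  cat(sprintf("span_stats (%s)\n",
              if (isTRUE(x$fixed)) "fixed thresholds"
              else sprintf("fitted from %d spans", x$n_spans)))
  cat(sprintf("  Q1 %s  median %s  Q3 %s  IQR %s\n",
              format(x$q1, big.mark = ","), format(x$median, big.mark = ","),
              format(x$q3, big.mark = ","), format(x$iqr, big.mark = ",")))
  cat(sprintf("  discordance thresholds: < %s (insertion) / > %s (deletion)\n",
              format(x$lower_threshold, big.mark = ","),
              format(x$upper_threshold, big.mark = ",")))
  invisible(x)
}

#' @method coef span_stats
#' @export
coef.span_stats <- function(object, ...) {
  c(q1 = object$q1, median = object$median, q3 = object$q3, iqr = object$iqr,
    lower_threshold = object$lower_threshold,
    upper_threshold = object$upper_threshold)
}

#' Classify mate pairs by span against fitted thresholds
#'
#' A pair whose span exceeds the upper threshold supports a deletion
#' (the mates are farther apart on the reference than the library
#' fragment); a span below the lower threshold supports an insertion.
#' Spans equal to a threshold are normal (strict inequalities).
#'
#' @param mps data.frame from [compute_spans()].
#' @param stats A \code{span_stats} object.
#' @return \code{mps} with an added \code{mp_class} column
#'   (\code{NORMAL}, \code{DELETION_SUPPORT}, \code{INSERTION_SUPPORT},
#'   \code{INTERCHROM}).
#' @export
classify_pairs <- function(mps, stats) {
  cls <- ifelse(mps$locus_class == "INTER", "INTERCHROM",
         ifelse(mps$span > stats$upper_threshold, "DELETION_SUPPORT",
         ifelse(mps$span < stats$lower_threshold, "INSERTION_SUPPORT",
                "NORMAL")))
  mps$mp_class <- cls
  mps
}

#' Library QC summary: intra/inter partition and span categories
#'
#' @param mps data.frame from [compute_spans()] (optionally already
#'   classified).
#' @param stats A \code{span_stats} object.
#' @return A list (class \code{allseq_qc}) with \code{n_total, n_intra,
#'   n_inter, intra_percent, n_normal, n_below_lower, n_above_upper}
#'   and the thresholds; the three span categories partition
#'   \code{n_intra} exactly.
#' @export
summarize_library <- function(mps, stats) {
  intra <- mps$locus_class == "INTRA"
  span <- mps$span[intra]
  n_intra <- sum(intra); n_inter <- sum(!intra)
  n_total <- n_intra + n_inter
  out <- list(
    n_total = n_total, n_intra = n_intra, n_inter = n_inter,
    intra_percent = if (n_total) round_half_up(100 * n_intra / n_total) else 0,
    n_below_lower = sum(span < stats$lower_threshold),
    n_normal = sum(span >= stats$lower_threshold &
                   span <= stats$upper_threshold),
    n_above_upper = sum(span > stats$upper_threshold),
    lower_threshold = stats$lower_threshold,
    upper_threshold = stats$upper_threshold)
  class(out) <- "allseq_qc"
  out
}

#' @export
print.allseq_qc <- function(x, ...) {
  cat(sprintf("mate pairs: %s total = %s intra (%d%%) + %s inter\n",
              format(x$n_total, big.mark = ","),
              format(x$n_intra, big.mark = ","), x$intra_percent,
              format(x$n_inter, big.mark = ",")))
  cat(sprintf("intra spans: %s normal [%s, %s], %s below, %s above\n",
              format(x$n_normal, big.mark = ","),
              format(x$lower_threshold, big.mark = ","),
              format(x$upper_threshold, big.mark = ","),
              format(x$n_below_lower, big.mark = ","),
              format(x$n_above_upper, big.mark = ",")))
  invisible(x)
}
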