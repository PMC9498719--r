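# reciprocal overlap fraction between two sets of inclusive intervals;
# returns, for each row of `hits`, min(ov/len_q, ov/len_s)
reciprocal_fraction <- function(qs, qe, ss, se) {
  ov <- pmin(qe, se) - pmax(qs, ss) + 1
  ov <- pmax(ov, 0)
  pmin(ov / (qe - qs + 1), ov / (se - ss + 1))
}

#' Label focal calls as sample-specific or shared
#'
#' A focal call is SHARED when any same-type call in any reference
#' sample matches it at reciprocal overlap at least \code{ro} (each
#' interval covering at least that fraction of the other, the standard
#' SV-matching criterion); otherwise it is SPECIFIC to the focal
#' sample.
#'
#' @param focal [sv_callset()] for the sample of interest.
#' @param references A single [sv_callset()] or a list of them, one per
#'   reference sample.
#' @param ro Reciprocal-overlap fraction in (0, 1]; default 0.5.
#' @return Object of class \code{sv_comparison}: list with
#'   \code{labels} (per focal call), \code{n_specific}, \code{n_shared},
#'   \code{percent_specific} (rounded half-up), \code{ro}.
#' @export
compare_samples <- function(focal, references, ro = 0.5) {
  if (!is.list(references) || is.data.frame(references))
    references <- list(references)
  if (ro <= 0 || ro > 1) stop_allseq("ro must be in (0, 1]")
  shared <- rep(FALSE, nrow(focal))
  if (nrow(focal)) {
    fgr <- as_gr(focal)
    for (ref in references) {
      if (!nrow(ref)) next
      rgr <- as_gr(ref)
      h <- GenomicRanges::findOverlaps(fgr, rgr, ignore.strand = TRUE)
      if (!length(h)) next
      qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
      ok <- focal$sv_type[qi] == ref$sv_type[si] &
        reciprocal_fraction(focal$start[qi], focal$end[qi],
                            ref$start[si], ref$end[si]) >= ro
      shared[unique(qi[ok])] <- TRUE
    }
  }
  labels <- ifelse(shared, "SHARED", "SPECIFIC")
  n_specific <- sum(!shared)
  out <- list(focal_sample = if (nrow(focal)) focal$sample_id[1] else NA,
              labels = labels, n_specific = n_specific,
              n_shared = sum(shared),
              percent_specific = if (nrow(focal))
                round_half_up(100 * n_specific / nrow(focal)) else NA,
              ro = ro)
  class(out) <- "sv_comparison"
  out
}

#' @export
print.sv_comparison <- function(x, ...) {
  n <- x$n_specific + x$n_shared
  cat(sprintf(
    "%d focal calls: %d specific (%s%%), %d shared (reciprocal overlap >= %g)\n",
    n, x$n_specific,
    if (is.na(x$percent_specific)) "NA" else x$percent_specific,
    x$n_shared, x$ro))
  invisible(x)
}

#' Bin calls by size
#'
#' Bins are half-open on the right, \code{[e_i, e_{i+1})}; calls
#' smaller than the first edge fall into an explicit underflow bin.
#' Percentages are rounded half-up to integers.
#'
#' @param calls An [sv_callset()] (or any data.frame with a \code{size}
#'   column).
#' @param edges Strictly increasing bin edges in bp; default
#'   \code{c(10e3, 50e3, 100e3, Inf)} giving bins 10-50 kb, 50-100 kb
#'   and >100 kb.
#' @return data.frame (class \code{size_bin_summary}) with columns
#'   \code{bin, lower, upper, count, percent}.
#' @export
bin_by_size <- function(calls, edges = c(10e3, 50e3, 100e3, Inf)) {
  if (is.unsorted(edges, strictly = TRUE))
    stop_allseq("bin edges must be strictly increasing")
  sizes <- calls$size
  full_edges <- c(0, edges)
  idx <- findInterval(sizes, full_edges, rightmost.closed = FALSE)
  labels <- c(sprintf("<%s", format(edges[1], big.mark = ",",
                                    scientific = FALSE)),
              vapply(seq_len(length(edges) - 1), function(i) {
                if (is.infinite(edges[i + 1]))
                  sprintf(">=%s", format(edges[i], big.mark = ",",
                                         scientific = FALSE))
                else sprintf("[%s,%s)",
                             format(edges[i], big.mark = ",", scientific = FALSE),
                             format(edges[i + 1], big.mark = ",",
                                    scientific = FALSE))
              }, character(1)))
  counts <- tabulate(idx, nbins = length(labels))
  total <- length(sizes)
  out <- data.frame(
    bin = labels,
    lower = full_edges[seq_along(labels)],
    upper = c(edges),
    count = counts,
    percent = if (total) round_half_up(100 * counts / total) else
      rep(0, length(labels)),
    stringsAsFactors = FALSE)
  class(out) <- c("size_bin_summary", "data.frame")
  out
}

#' Genes affected by each call
#'
#' A gene is affected by a call when their intervals intersect
#' (1-based inclusive coordinates; any overlap, full or partial).
#'
#' @param calls An [sv_callset()].
#' @param genes data.frame from [read_gene_models()].
#' @return A list, one character vector of gene ids per call.
#' @export
gene_overlap <- function(calls, genes) {
  res <- rep(list(character(0)), nrow(calls))
  if (!nrow(calls) || !nrow(genes)) return(res)
  h <- GenomicRanges::findOverlaps(as_gr(calls), as_gr(genes),
                                   ignore.strand = TRUE)
  if (length(h)) {
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    for (i in unique(qi)) res[[i]] <- genes$gene_id[si[qi == i]]
  }
  res
}

#' Per-chromosome distribution of calls and gene status changes
#'
#' @param calls An [sv_callset()].
#' @param gene_changes Optional data.frame from [expression_status()];
#'   requires \code{genes} to locate each gene.
#' @param genes Optional data.frame from [read_gene_models()].
#' @param chrom_lengths Named numeric vector (see
#'   [read_chrom_lengths()]); all call chromosomes must be present.
#' @return data.frame with one row per chromosome: \code{chrom, length,
#'   n_del, n_ins, n_loss, n_gain}; attribute \code{positions} holds a
#'   long table (chrom, pos, what) for plotting.
#' @export
chromosome_distribution <- function(calls, gene_changes = NULL, genes = NULL,
                                    chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) stop_allseq("chrom_lengths is required")
  unknown <- setdiff(unique(calls$chrom), names(chrom_lengths))
  if (length(unknown))
    stop_allseq("call on unknown chromosome: %s", unknown[1])
  chroms <- names(chrom_lengths)
  cnt <- function(what_chrom) tabulate(match(what_chrom, chroms),
                                       nbins = length(chroms))
  pos <- data.frame(chrom = calls$chrom, pos = calls$start,
                    what = calls$sv_type, stringsAsFactors = FALSE)
  n_loss <- n_gain <- rep(0L, length(chroms))
  if (!is.null(gene_changes) && nrow(gene_changes)) {
    if (is.null(genes)) stop_allseq("genes required to place gene_changes")
    gi <- match(gene_changes$gene_id, genes$gene_id)
    placed <- !is.na(gi)
    gc2 <- cbind(gene_changes[placed, , drop = FALSE],
                 chrom = genes$chrom[gi[placed]],
                 pos = genes$start[gi[placed]])
    gc2 <- gc2[gc2$status %in% c("LOSS", "GAIN"), , drop = FALSE]
    unknown <- setdiff(unique(gc2$chrom), chroms)
    if (length(unknown))
      stop_allseq("gene on unknown chromosome: %s", unknown[1])
    n_loss <- cnt(gc2$chrom[gc2$status == "LOSS"])
    n_gain <- cnt(gc2$chrom[gc2$status == "GAIN"])
    pos <- rbind(pos, data.frame(chrom = gc2$chrom, pos = gc2$pos,
                                 what = gc2$status, stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = chroms, length = as.numeric(chrom_lengths),
                    n_del = cnt(calls$chrom[calls$sv_type == "DEL"]),
                    n_ins = cnt(calls$chrom[calls$sv_type == "INS"]),
                    n_loss = n_loss, n_gain = n_gain,
                    stringsAsFactors = FALSE)
  attr(out, "positions") <- pos
  out
}
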