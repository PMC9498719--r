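#' Caller configuration
#'
#' @param min_size Minimum reported InDel size (bp); default 1,000 —
#'   the method targets large InDels only.
#' @param min_support Minimum clustered discordant pairs per call
#'   (default 3; suppresses singleton mapping artifacts at ~1.4x
#'   mate-pair depth while staying sensitive).
#' @param cluster_window Linkage window (bp) for merging discordant
#'   pairs; default \code{NULL} = the library median span.
#' @param min_mapq Mapping-quality floor used upstream (recorded for
#'   provenance).
#' @param fixed_thresholds Optional numeric \code{c(lower, upper)} in bp
#'   (e.g. \code{c(4800, 7200)}) to use instead of fitting thresholds
#'   from the data.
#' @return A \code{caller_config} list.
#' @export
caller_config <- function(min_size = 1000, min_support = 3,
                          cluster_window = NULL, min_mapq = 30,
                          fixed_thresholds = NULL) {
  check_pos(min_size, "min_size"); check_pos(min_support, "min_support")
  if (!is.null(cluster_window)) check_pos(cluster_window, "cluster_window")
  if (!is.null(fixed_thresholds) && length(fixed_thresholds) != 2)
    stop_allseq("fixed_thresholds must be c(lower, upper)")
  structure(list(min_size = min_size, min_support = as.integer(min_support),
                 cluster_window = cluster_window, min_mapq = min_mapq,
                 fixed_thresholds = fixed_thresholds),
            class = "caller_config")
}

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# single-linkage components: pairs linked when their outer intervals share
# >= 1 bp and both start and end positions differ by <= window
linkage_components <- function(start, end, window) {
  n <- length(start)
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  parent <- uf_new(n)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && s[j] - s[i] <= window) {
      if (s[j] <= e[i] && abs(e[j] - e[i]) <= window) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp <- match(roots, unique(roots))
  comp[order(o)]  # back to input order
}

#' Cluster discordant mate pairs into InDel calls
#'
#' Same-class, same-chromosome discordant pairs are merged by single
#' linkage (linked when their outer intervals overlap and their
#' endpoints agree within \code{cluster_window}).  Clusters with at
#' least \code{min_support} pairs become calls.  The size estimate is
#' the excess of the mean cluster span over the library median
#' (deletions) or its deficit (insertions); calls smaller than
#' \code{min_size} are dropped.  The deletion interval is the region
#' between the innermost read edges: \code{[max(left-read ends) + 1,
#' min(right-read starts) - 1]}, clipped to stay non-empty.
#'
#' @param classified data.frame from [classify_pairs()].
#' @param stats A \code{span_stats} object.
#' @param cfg A [caller_config()].
#' @param sample_id Sample label stamped on the calls.
#' @return An [sv_callset()] sorted by (chrom, start).
#' @export
cluster_calls <- function(classified, stats, cfg = caller_config(),
                          sample_id = "sample") {
  window <- cfg$cluster_window %||% stats$median
  disc <- classified[classified$mp_class %in%
                       c("DELETION_SUPPORT", "INSERTION_SUPPORT"), ,
                     drop = FALSE]
  out <- list()
  for (cls in unique(disc$mp_class)) {
    sub_c <- disc[disc$mp_class == cls, , drop = FALSE]
    for (chrom in unique(sub_c$chrom1)) {
      sub <- sub_c[sub_c$chrom1 == chrom, , drop = FALSE]
      comp <- linkage_components(sub$outer_start, sub$outer_end, window)
      for (k in unique(comp)) {
        members <- sub[comp == k, , drop = FALSE]
        if (nrow(members) < cfg$min_support) next
        mean_span <- mean(members$span)
        size <- if (cls == "DELETION_SUPPORT") mean_span - stats$median
                else stats$median - mean_span
        if (size < cfg$min_size) next
        left <- max(members$inner_left_end) + 1
        right <- min(members$inner_right_start) - 1
        if (right < left) left <- right <- floor((left + right) / 2)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id,
          sv_type = if (cls == "DELETION_SUPPORT") "DEL" else "INS",
          chrom = chrom, start = left, end = right, size = size,
          support = nrow(members), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(sv_callset())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  do.call(sv_callset, df)
}

#' Call large InDels from aligned mate pairs
#'
#' End-to-end caller: computes spans and the intra/inter partition,
#' fits (or fixes) the quartile/IQR discordance thresholds, classifies
#' pairs, clusters discordant pairs into calls, and attaches the QC
#' summary and inter-chromosomal (translocation candidate) table.
#'
#' @param pairs data.frame of aligned pairs from [read_pairs()] or the
#'   simulator; only rows with \code{fraction == "MP"} are used when a
#'   \code{fraction} column is present.
#' @param cfg A [caller_config()].
#' @param sample_id Sample label.
#' @return An [sv_callset()] with attributes \code{span_stats},
#'   \code{qc}, \code{classified} and \code{translocations}.
#' @examples
#' pairs <- simulate_reads(sim_config(genome_length = 2e5, seed = 7),
#'                         output = "pairs")$pairs
#' calls <- call_indels(pairs, caller_config())
#' attr(calls, "span_stats")
#' @export
call_indels <- function(pairs, cfg = caller_config(), sample_id = "sample") {
  if ("fraction" %in% names(pairs))
    pairs <- pairs[pairs$fraction == "MP", , drop = FALSE]
  mps <- compute_spans(pairs)
  stats <- if (!is.null(cfg$fixed_thresholds))
    fixed_span_thresholds(cfg$fixed_thresholds[1], cfg$fixed_thresholds[2],
                          median = median(mps$span, na.rm = TRUE))
  else fit_span_thresholds(mps$span)
  classified <- classify_pairs(mps, stats)
  calls <- cluster_calls(classified, stats, cfg, sample_id = sample_id)
  attr(calls, "span_stats") <- stats
  attr(calls, "qc") <- summarize_library(mps, stats)
  attr(calls, "classified") <- classified
  attr(calls, "translocations") <-
    classified[classified$locus_class == "INTER",
               c("pair_id", "chrom1", "chrom2"), drop = FALSE]
  attr(calls, "config") <- cfg
  calls
}
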