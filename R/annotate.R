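#' Transcription loss/gain between two samples from RPKM tables
#'
#' Uses a two-threshold (hysteresis) presence/absence rule rather than
#' differential-expression testing: a gene has LOST transcription in
#' the focal sample when it is expressed in the reference
#' (\code{rpkm >= on_threshold}) and silent in the focal sample
#' (\code{rpkm < off_threshold}); GAIN is the symmetric case; all other
#' genes are UNCHANGED.  Output is sorted by absolute RPKM difference,
#' descending, so the head of the table is the "top n most changed"
#' selection.
#'
#' @param expr Long-format expression table from [read_expression()].
#' @param ref_sample,focal_sample Sample ids to compare (e.g. primary
#'   cells vs a cell line).
#' @param on_threshold RPKM at or above which a gene counts as
#'   expressed (default 1.0).
#' @param off_threshold RPKM below which a gene counts as silent
#'   (default 0.1; must be < on_threshold).
#' @return data.frame with columns \code{gene_id, status, rpkm_ref,
#'   rpkm_focal}, status in \{LOSS, GAIN, UNCHANGED\}.
#' @export
expression_status <- function(expr, ref_sample, focal_sample,
                              on_threshold = 1.0, off_threshold = 0.1) {
  if (off_threshold >= on_threshold)
    stop_allseq("off_threshold must be < on_threshold")
  if (any(expr$rpkm < 0)) stop_allseq("rpkm values must be non-negative")
  genes <- unique(expr$gene_id)
  take <- function(sample) {
    sub <- expr[expr$sample_id == sample, , drop = FALSE]
    v <- setNames(sub$rpkm, sub$gene_id)[genes]
    if (anyNA(v)) {
      warning(sprintf("%d gene(s) missing in sample '%s'; treated as 0",
                      sum(is.na(v)), sample), call. = FALSE)
      v[is.na(v)] <- 0
    }
    unname(v)
  }
  ref <- take(ref_sample); focal <- take(focal_sample)
  status <- ifelse(ref >= on_threshold & focal < off_threshold, "LOSS",
            ifelse(focal >= on_threshold & ref < off_threshold, "GAIN",
                   "UNCHANGED"))
  out <- data.frame(gene_id = genes, status = status,
                    rpkm_ref = ref, rpkm_focal = focal,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rpkm_ref - out$rpkm_focal)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag deletions that fuse topologically associated domains
#'
#' A deletion whose two endpoints lie in different TADs removes the
#' intervening boundary (or boundaries), fusing the flanking domains —
#' a mechanism by which a structural variant can rewire
#' enhancer-promoter contacts and alter transcription.  TAD boundaries
#' are taken as the midpoints between consecutive TAD intervals on a
#' chromosome; \code{removed_boundaries} counts boundaries strictly
#' inside the deletion.
#'
#' @param deletions An [sv_callset()] (only DEL rows are annotated;
#'   others get \code{fused = NA}).
#' @param tads data.frame of non-overlapping TAD intervals from
#'   [read_tads()], sorted per chromosome.
#' @return data.frame: one row per input call with \code{chrom, start,
#'   end, left_tad_start, left_tad_end, right_tad_start, right_tad_end,
#'   fused, removed_boundaries, note} (\code{note = "unassigned"} when
#'   an endpoint falls in no TAD).
#' @export
tad_fusion_flags <- function(deletions, tads) {
  n <- nrow(deletions)
  out <- data.frame(chrom = deletions$chrom, start = deletions$start,
                    end = deletions$end,
                    left_tad_start = NA_real_, left_tad_end = NA_real_,
                    right_tad_start = NA_real_, right_tad_end = NA_real_,
                    fused = rep(NA, n), removed_boundaries = NA_integer_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (deletions$sv_type[i] != "DEL") { out$note[i] <- "not a deletion"; next }
    tsub <- tads[tads$chrom == deletions$chrom[i], , drop = FALSE]
    tsub <- tsub[order(tsub$start), , drop = FALSE]
    s <- deletions$start[i]; e <- deletions$end[i]
    left <- which(tsub$start <= s & tsub$end >= s)
    right <- which(tsub$start <= e & tsub$end >= e)
    if (length(left)) {
      out$left_tad_start[i] <- tsub$start[left[1]]
      out$left_tad_end[i] <- tsub$end[left[1]]
    }
    if (length(right)) {
      out$right_tad_start[i] <- tsub$start[right[1]]
      out$right_tad_end[i] <- tsub$end[right[1]]
    }
    if (nrow(tsub) >= 2) {
      bounds <- (tsub$end[-nrow(tsub)] + tsub$start[-1]) / 2
      out$removed_boundaries[i] <- sum(bounds > s & bounds < e)
    } else out$removed_boundaries[i] <- 0L
    if (!length(left) || !length(right)) {
      out$fused[i] <- FALSE
      out$note[i] <- "unassigned"
    } else {
      out$fused[i] <- left[1] != right[1]
    }
  }
  out
}
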