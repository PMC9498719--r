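#' Construct a structural-variant call set
#'
#' An \code{sv_callset} is a data.frame of deletion/insertion calls with
#' columns \code{sample_id, sv_type, chrom, start, end, size, support}
#' (coordinates 1-based inclusive; for deletions the interval is the
#' estimated deleted region, for insertions the insertion point with its
#' uncertainty).
#'
#' @param sample_id,sv_type,chrom,start,end,size,support Call fields
#'   (recycled as usual).
#' @return An object of class \code{sv_callset} (a data.frame).
#' @export
sv_callset <- function(sample_id = character(), sv_type = character(),
                       chrom = character(), start = numeric(),
                       end = numeric(), size = numeric(),
                       support = integer()) {
  if (length(sv_type) && !all(sv_type %in% c("DEL", "INS")))
    stop_allseq("sv_type must be 'DEL' or 'INS'")
  df <- data.frame(sample_id = as.character(sample_id),
                   sv_type = as.character(sv_type),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   size = as.numeric(size), support = as.integer(support),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end < df$start))
    stop_allseq("invalid call interval: end < start")
  class(df) <- c("sv_callset", "data.frame")
  df
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset: %d calls (%d DEL, %d INS) in %d sample(s)\n",
              nrow(x), sum(x$sv_type == "DEL"), sum(x$sv_type == "INS"),
              length(unique(x$sample_id))))
  if (nrow(x)) {
    cat(sprintf("size range: %s-%s bp; support range: %s-%s pairs\n",
                format(min(x$size), big.mark = ","),
                format(max(x$size), big.mark = ","),
                min(x$support), max(x$support)))
    print.data.frame(head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat(sprintf("... and %d more calls\n", nrow(x) - 10))
  }
  invisible(x)
}

#' @method summary sv_callset
#' @export
summary.sv_callset <- function(object, ...) {
  by_type <- table(factor(object$sv_type, levels = c("DEL", "INS")))
  out <- list(n = nrow(object), by_type = by_type,
              size_summary = if (nrow(object)) summary(object$size) else NULL,
              by_chrom = if (nrow(object)) table(object$chrom) else NULL)
  class(out) <- "summary.sv_callset"
  out
}

#' @export
print.summary.sv_callset <- function(x, ...) {
  cat(sprintf("Call set: %d calls (DEL %d, INS %d)\n",
              x$n, x$by_type[["DEL"]], x$by_type[["INS"]]))
  if (!is.null(x$size_summary)) {
    cat("Size (bp):\n"); print(x$size_summary)
    cat("Per chromosome:\n"); print(x$by_chrom)
  }
  invisible(x)
}

#' @method plot sv_callset
#' @export
plot.sv_callset <- function(x, ...) {
  if (!nrow(x)) { plot.new(); title("empty call set"); return(invisible(x)) }
  graphics::hist(log10(x$size), breaks = 30,
                 xlab = "log10 size (bp)", main = "InDel call sizes", ...)
  invisible(x)
}

check_sorted_calls <- function(calls) {
  o <- order(calls$chrom, calls$start)
  if (!identical(o, seq_len(nrow(calls))))
    stop_allseq(paste("calls must be sorted by (chrom, start) before writing;",
                      "sort with calls[order(calls$chrom, calls$start), ]"))
}

#' Write structural-variant calls to BED or VCF
#'
#' BED output is 0-based half-open; the call type, size, support and
#' sample ride in the name field so that a round-trip through
#' [read_calls()] reproduces the call set exactly.  VCF 4.2 output uses
#' symbolic alleles \code{<DEL>}/\code{<INS>} with \code{END},
#' \code{SVTYPE}, \code{SVLEN} (negative for deletions) and
#' \code{SUPPORT} INFO fields.
#'
#' @param calls An [sv_callset()] sorted by (chrom, start).
#' @param path Output file.
#' @param format \code{"BED"} or \code{"VCF"}.
#' @return \code{path}, invisibly.
#' @export
write_calls <- function(calls, path, format = c("BED", "VCF")) {
  format <- match.arg(format)
  check_sorted_calls(calls)
  if (format == "BED") write_calls_bed(calls, path) else write_calls_vcf(calls, path)
  invisible(path)
}

write_calls_bed <- function(calls, path) {
  if (!nrow(calls)) { writeLines(character(0), path); return(invisible(path)) }
  name <- sprintf("%s;SIZE=%s;SUPPORT=%d;SAMPLE=%s", calls$sv_type,
                  format(calls$size, scientific = FALSE, trim = TRUE),
                  calls$support, calls$sample_id)
  gr <- as_gr(calls)
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$score <- calls$support
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

vcf_header_lines <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=allseq-%s", as.character(packageVersion("allseq"))),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant (negative for deletions)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting mate-pair count\">",
    sprintf("##allseq_samples=%s", paste(unique(sample_ids), collapse = ",")),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

write_calls_vcf <- function(calls, path) {
  header <- vcf_header_lines(calls$sample_id)
  if (!nrow(calls)) { writeLines(header, path); return(invisible(path)) }
  is_del <- calls$sv_type == "DEL"
  pos <- ifelse(is_del, pmax(calls$start - 1, 1), calls$start)
  svlen <- ifelse(is_del, -calls$size, calls$size)
  info <- sprintf("SVTYPE=%s;END=%s;SVLEN=%s;SUPPORT=%d",
                  calls$sv_type,
                  format(calls$end, scientific = FALSE, trim = TRUE),
                  format(svlen, scientific = FALSE, trim = TRUE),
                  calls$support)
  recs <- sprintf("%s\t%s\t%s\tN\t<%s>\t.\tPASS\t%s",
                  calls$chrom,
                  format(pos, scientific = FALSE, trim = TRUE),
                  sprintf("%s_%s_%d", calls$sample_id, calls$sv_type,
                          seq_len(nrow(calls))),
                  calls$sv_type, info)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read structural-variant calls written by [write_calls()]
#'
#' @param path BED or VCF file.
#' @param format \code{"BED"} or \code{"VCF"}; guessed from the extension
#'   when missing.
#' @param sample_id Sample label for formats that carry none (BED stores
#'   it in the name field, so this is a fallback only).
#' @return An [sv_callset()] in 1-based inclusive coordinates.
#' @export
read_calls <- function(path, format = NULL, sample_id = "sample") {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "vcf") "VCF" else "BED"
  if (format == "BED") read_calls_bed(path, sample_id) else read_calls_vcf(path)
}

read_calls_bed <- function(path, sample_id) {
  if (length(readLines(path)) == 0) return(sv_callset())
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) return(sv_callset())
  nm <- S4Vectors::mcols(gr)$name
  part <- strsplit(nm, ";", fixed = TRUE)
  get_tag <- function(p, tag, default) {
    hit <- grep(paste0("^", tag, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", tag, "="), "", hit[1]) else default
  }
  sv_callset(
    sample_id = vapply(part, get_tag, "", tag = "SAMPLE", default = sample_id),
    sv_type = vapply(part, `[`, "", 1L),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),  # rtracklayer already converts to 1-based
    end = GenomicRanges::end(gr),
    size = as.numeric(vapply(part, get_tag, "", tag = "SIZE", default = "NA")),
    support = as.integer(as.numeric(
      vapply(part, get_tag, "", tag = "SUPPORT", default = "0"))))
}

read_calls_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (!nrow(vcf)) return(sv_callset())
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  svtype <- as.character(info$SVTYPE)
  endpos <- as.numeric(info$END)
  svlen <- as.numeric(info$SVLEN)
  is_del <- svtype == "DEL"
  # DEL: START reconstructed from END and SVLEN (POS is the base before the
  # deleted interval and may have been clipped at 1)
  start <- ifelse(is_del, endpos + svlen + 1, GenomicRanges::start(rr))
  samples <- sub("_(DEL|INS)_\\d+$", "", names(rr))
  sv_callset(sample_id = samples, sv_type = svtype,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             start = start, end = endpos, size = abs(svlen),
             support = as.integer(info$SUPPORT))
}
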