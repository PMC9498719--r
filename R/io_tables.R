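#' Read a long-format expression table
#'
#' Expects a TSV with header \code{gene_id, sample_id, rpkm} (one row per
#' gene and sample).  RPKM values must be non-negative.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{gene_id, sample_id, rpkm}.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "sample_id", "rpkm")
  if (!all(need %in% names(df)))
    stop_allseq("expression table must have columns: %s",
                paste(need, collapse = ", "))
  df$rpkm <- as.numeric(df$rpkm)
  if (anyNA(df$rpkm) || any(df$rpkm < 0))
    stop_allseq("rpkm values must be non-negative numbers")
  df[need]
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 is parsed with rtracklayer; records of type \code{gene} are kept
#' (all records if none is typed \code{gene}).  BED names become gene ids.
#'
#' @param path GFF3 (.gff/.gff3) or BED file.
#' @return data.frame with columns \code{gene_id, chrom, start, end,
#'   strand} (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("gff", "gff3")) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3") {
    type <- as.character(S4Vectors::mcols(gr)$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$Name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  } else {
    ids <- S4Vectors::mcols(gr)$name %||% paste0("gene", seq_along(gr))
  }
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read TAD intervals from BED
#'
#' @param path BED file of topologically associated domains.
#' @return data.frame with \code{chrom, start, end} (1-based inclusive),
#'   sorted by (chrom, start).
#' @export
read_tads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Read a primer-pair table
#'
#' TSV with header \code{name, forward, reverse, max_product}.
#'
#' @param path TSV file.
#' @return data.frame of primer pairs (see [primer_pair()]).
#' @export
read_primers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "forward", "reverse", "max_product")
  if (!all(need %in% names(df)))
    stop_allseq("primer table must have columns: %s", paste(need, collapse = ", "))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    primer_pair(df$name[i], df$forward[i], df$reverse[i], df$max_product[i])))
}

#' Read chromosome lengths from a FASTA index (.fai) or FASTA
#'
#' @param path samtools-style .fai (TSV: name, length, ...) or a FASTA
#'   file, in which case lengths are taken from the sequences.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_lengths <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("fa", "fasta", "fna")) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(setNames(as.numeric(Biostrings::width(seqs)),
                    sub("\\s.*$", "", names(seqs))))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
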