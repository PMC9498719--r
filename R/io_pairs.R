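#' Read aligned read pairs from SAM/BAM or the TSV pair dialect
#'
#' Accepts coordinate alignments either as SAM/BAM (paired records) or as
#' the package's plain-text pair dialect: a header line followed by
#' tab-separated columns \code{pair_id, chrom1, start1, end1, strand1,
#' chrom2, start2, end2}.  Optional trailing columns \code{strand2},
#' \code{mapq} and \code{fraction} (\code{MP}/\code{SG}) are honoured when
#' present; absent, \code{mapq} defaults to 60 and \code{fraction} to
#' \code{"MP"}.
#'
#' Pairs with either mate unmapped, orphan (unpaired) records, and pairs
#' with \code{mapq < min_mapq} are dropped and counted; the counts are
#' attached as the \code{"drop_counts"} attribute of the result.
#'
#' @param path SAM, BAM or TSV file.
#' @param min_mapq Minimum mapping quality for both mates (default 30, a
#'   proxy for unique mapping).
#' @param fraction Default library fraction label for alignment files that
#'   carry none.
#' @return data.frame with columns \code{pair_id, chrom1, start1, end1,
#'   strand1, chrom2, start2, end2, strand2, mapq, fraction}; attribute
#'   \code{drop_counts} = c(mapq, unmapped_or_orphan).
#' @export
read_pairs <- function(path, min_mapq = 30, fraction = "MP") {
  if (!file.exists(path)) stop_allseq("pair file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    read_pairs_bam(path, min_mapq = min_mapq, fraction = fraction)
  } else {
    read_pairs_tsv(path, min_mapq = min_mapq, fraction = fraction)
  }
}

pair_cols <- c("pair_id", "chrom1", "start1", "end1", "strand1",
               "chrom2", "start2", "end2")

empty_pairs <- function() {
  data.frame(pair_id = character(), chrom1 = character(), start1 = numeric(),
             end1 = numeric(), strand1 = character(), chrom2 = character(),
             start2 = numeric(), end2 = numeric(), strand2 = character(),
             mapq = numeric(), fraction = character(), stringsAsFactors = FALSE)
}

read_pairs_tsv <- function(path, min_mapq = 30, fraction = "MP") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    out <- empty_pairs()
    attr(out, "drop_counts") <- c(mapq = 0L, unmapped_or_orphan = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 8 || !identical(header[1:8], pair_cols))
    stop_allseq("pair TSV header must start with: %s",
                paste(pair_cols, collapse = ", "))
  body <- fields[-1]
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad))
    stop_allseq("malformed pair record at line %d: expected %d fields, got %d",
                bad[1] + 1L, length(header), nf[bad[1]])
  if (length(body) == 0) {
    out <- empty_pairs()
    attr(out, "drop_counts") <- c(mapq = 0L, unmapped_or_orphan = 0L)
    return(out)
  }
  m <- do.call(rbind, body)
  colnames(m) <- header
  df <- data.frame(
    pair_id = m[, "pair_id"],
    chrom1 = m[, "chrom1"], start1 = as.numeric(m[, "start1"]),
    end1 = as.numeric(m[, "end1"]), strand1 = m[, "strand1"],
    chrom2 = m[, "chrom2"], start2 = as.numeric(m[, "start2"]),
    end2 = as.numeric(m[, "end2"]),
    strand2 = if ("strand2" %in% header) m[, "strand2"] else "-",
    mapq = if ("mapq" %in% header) as.numeric(m[, "mapq"]) else 60,
    fraction = if ("fraction" %in% header) m[, "fraction"] else fraction,
    stringsAsFactors = FALSE)
  if (anyNA(df$start1) || anyNA(df$end1) || anyNA(df$start2) || anyNA(df$end2))
    stop_allseq("malformed pair record: non-numeric coordinate in %s", path)
  keep <- df$mapq >= min_mapq
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(mapq = sum(!keep), unmapped_or_orphan = 0L)
  out
}

read_pairs_bam <- function(path, min_mapq = 30, fraction = "MP") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  # count records that can never form a proper pair: unmapped or mate-unmapped
  flg0 <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  all_flags <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(what = "flag", flag = flg0))[[1]]$flag
  unmapped <- sum(bitwAnd(all_flags, 4L) > 0 | bitwAnd(all_flags, 8L) > 0)

  ga <- GenomicAlignments::readGAlignmentPairs(
    path, param = Rsamtools::ScanBamParam(what = "mapq", flag = flg0))
  n_paired_reads <- 2L * length(ga)
  orphan <- length(all_flags) - unmapped - n_paired_reads
  if (length(ga) == 0) {
    out <- empty_pairs()
    attr(out, "drop_counts") <- c(mapq = 0L,
                                  unmapped_or_orphan = unmapped + max(orphan, 0L))
    return(out)
  }
  first <- GenomicAlignments::first(ga)
  second <- GenomicAlignments::second(ga)
  mapq <- pmin(S4Vectors::mcols(first)$mapq, S4Vectors::mcols(second)$mapq)
  mapq[is.na(mapq)] <- 0
  df <- data.frame(
    pair_id = names(ga) %||% as.character(seq_along(ga)),
    chrom1 = as.character(GenomicAlignments::seqnames(first)),
    start1 = GenomicRanges::start(first), end1 = GenomicRanges::end(first),
    strand1 = as.character(GenomicAlignments::strand(first)),
    chrom2 = as.character(GenomicAlignments::seqnames(second)),
    start2 = GenomicRanges::start(second), end2 = GenomicRanges::end(second),
    strand2 = as.character(GenomicAlignments::strand(second)),
    mapq = as.numeric(mapq),
    fraction = fraction, stringsAsFactors = FALSE)
  keep <- df$mapq >= min_mapq
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(mapq = sum(!keep),
                                unmapped_or_orphan = unmapped + max(orphan, 0L))
  out
}
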