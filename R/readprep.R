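#' Junction scan configuration
#'
#' In an All-seq library the circularisation junction carries the Tn5
#' adapter: reads containing it are mate-pair (MP) reads whose two
#' genomic flanks come from the two ends of a long (~6 kb) fragment,
#' while adapter-free reads are shotgun (SG) reads.  The adapter
#' sequence is library-specific and therefore has no default.
#'
#' @param adapter_seq Adapter sequence (A/C/G/T, non-empty).
#' @param max_mismatches Maximum Hamming mismatches allowed in an
#'   adapter occurrence (no indels; default 0).
#' @param min_flank Minimum length of each genomic flank for a split
#'   read to be emitted as an MP pair (default 20 bp).
#' @param scan_revcomp Also scan the reverse complement of the adapter
#'   (default TRUE; libraries are unoriented).
#' @return A \code{junction_config} list.
#' @export
junction_config <- function(adapter_seq, max_mismatches = 0L,
                            min_flank = 20L, scan_revcomp = TRUE) {
  if (missing(adapter_seq) || !nzchar(adapter_seq) ||
      grepl("[^ACGT]", toupper(adapter_seq)))
    stop_allseq("adapter_seq is required and must be a non-empty A/C/G/T string")
  if (min_flank < 1) stop_allseq("min_flank must be >= 1")
  if (max_mismatches < 0) stop_allseq("max_mismatches must be >= 0")
  structure(list(adapter_seq = toupper(adapter_seq),
                 max_mismatches = as.integer(max_mismatches),
                 min_flank = as.integer(min_flank),
                 scan_revcomp = isTRUE(scan_revcomp)),
            class = "junction_config")
}

# candidate adapter occurrences in one orientation; returns data.frame
# (start 1-based, mismatches) for all starts with <= max_mismatches
adapter_candidates <- function(seq, pattern, max_mm) {
  m <- Biostrings::matchPattern(pattern, seq, max.mismatch = max_mm,
                                with.indels = FALSE)
  if (!length(m)) return(data.frame(start = integer(), mm = integer()))
  starts <- BiocGenerics::start(m)
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), seq,
                                    starting.at = starts, with.indels = FALSE)
  data.frame(start = starts, mm = as.integer(mm))
}

#' Locate the adapter junction within a read
#'
#' Scans for the best adapter occurrence (fewest mismatches; leftmost on
#' ties) in the read, in both orientations when
#' \code{cfg$scan_revcomp}; on an orientation tie the forward hit wins.
#'
#' @param read_seq A character string or \code{DNAString}.
#' @param cfg A [junction_config()].
#' @return \code{NULL} if no occurrence within \code{max_mismatches}
#'   (including when the adapter is longer than the read); otherwise a
#'   list with \code{pos} (0-based offset of the occurrence start),
#'   \code{mismatches}, \code{strand} ("+" or "-") and \code{n_sites}
#'   (number of distinct candidate occurrence starts).
#' @export
scan_junction <- function(read_seq, cfg) {
  seq <- if (is(read_seq, "DNAString")) read_seq
         else Biostrings::DNAString(toupper(as.character(read_seq)))
  m <- nchar(cfg$adapter_seq)
  if (m > length(seq)) return(NULL)
  fwd <- adapter_candidates(seq, cfg$adapter_seq, cfg$max_mismatches)
  fwd$strand <- if (nrow(fwd)) "+" else character(0)
  cand <- fwd
  if (cfg$scan_revcomp) {
    rc_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cfg$adapter_seq)))
    if (rc_seq != cfg$adapter_seq) {
      rc <- adapter_candidates(seq, rc_seq, cfg$max_mismatches)
      rc$strand <- if (nrow(rc)) "-" else character(0)
      cand <- rbind(cand, rc)
    }
  }
  if (!nrow(cand)) return(NULL)
  # same start in both orientations: keep the lower-mismatch (then "+") hit
  cand <- cand[order(cand$start, cand$mm, cand$strand != "+"), , drop = FALSE]
  cand <- cand[!duplicated(cand$start), , drop = FALSE]
  best <- cand[order(cand$mm, cand$start, cand$strand != "+"), , drop = FALSE][1, ]
  list(pos = best$start - 1L, mismatches = best$mm, strand = best$strand,
       n_sites = length(unique(cand$start)))
}

validate_fastq_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop_allseq("malformed FASTQ %s: %d lines is not a multiple of 4",
                path, length(lines))
  n <- length(lines) / 4
  if (n > 0) {
    hdr <- lines[seq(1, length(lines), by = 4)]
    sep <- lines[seq(3, length(lines), by = 4)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
    if (length(bad))
      stop_allseq("malformed FASTQ %s at record %d", path, bad[1])
  }
  invisible(n)
}

#' Split All-seq reads into mate-pair and shotgun fractions
#'
#' Reads containing the adapter junction are cut at it: the two genomic
#' flanks (each at least \code{cfg$min_flank} bases) become an MP read
#' pair with qualities preserved; junction-free reads pass through as
#' SG reads.  Reads whose flank is too short, and reads with more than
#' one distinct junction site (re-circularisation chimeras), are
#' discarded and counted.
#'
#' @param fastq_in Path to a FASTQ file, or a
#'   \code{QualityScaledDNAStringSet}.
#' @param cfg A [junction_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   \code{<prefix>_MP_1.fastq}, \code{<prefix>_MP_2.fastq} and
#'   \code{<prefix>_SG.fastq}.
#' @return A list with \code{mp1}, \code{mp2}, \code{sg}
#'   (QualityScaledDNAStringSet), \code{counts} (named: n_mp, n_sg,
#'   n_discarded; one count per input read) and \code{discards}
#'   (named: short_flank, multi_junction).
#' @export
split_reads <- function(fastq_in, cfg, out_prefix = NULL) {
  if (is.character(fastq_in)) {
    validate_fastq_lines(fastq_in)
    reads <- if (file.size(fastq_in) == 0)
      Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0)))
    else suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq_in))
    # (the reader warns about dropping its own internal metadata columns)
  } else reads <- fastq_in
  n <- length(reads)
  quals <- methods::as(Biostrings::quality(reads), "BStringSet")
  # strip the quality container (kept separately in `quals`); the
  # constructor warns about dropping it, which is exactly what we want
  seqs <- suppressWarnings(Biostrings::DNAStringSet(reads))
  ids <- names(reads) %||% as.character(seq_len(n))

  hit_pos <- rep(NA_integer_, n)
  n_sites <- integer(n)
  if (n > 0) {
    scans <- lapply(seq_len(n), function(i) scan_junction(seqs[[i]], cfg))
    has <- !vapply(scans, is.null, logical(1))
    hit_pos[has] <- vapply(scans[has], `[[`, integer(1), "pos")
    n_sites[has] <- vapply(scans[has], `[[`, integer(1), "n_sites")
  }
  m <- nchar(cfg$adapter_seq)
  is_sg <- is.na(hit_pos)
  multi <- !is_sg & n_sites > 1
  j <- hit_pos  # 0-based: flank1 = [1, j], flank2 = [j+m+1, len]
  len <- Biostrings::width(seqs)
  short <- !is_sg & !multi & (j < cfg$min_flank | (len - j - m) < cfg$min_flank)
  is_mp <- !is_sg & !multi & !short

  qsets <- function(idx, from, to) {
    x <- setNames(Biostrings::subseq(seqs[idx], start = from, end = to),
                  ids[idx])
    S4Vectors::mcols(x) <- NULL  # constructor warns on stray metadata
    Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(Biostrings::subseq(quals[idx], start = from,
                                                     end = to)))
  }
  mp_idx <- which(is_mp)
  mp1 <- qsets(mp_idx, rep(1L, length(mp_idx)), j[mp_idx])
  mp2 <- qsets(mp_idx, j[mp_idx] + m + 1L, len[mp_idx])
  sg_idx <- which(is_sg)
  sg <- qsets(sg_idx, rep(1L, length(sg_idx)), len[sg_idx])

  out <- list(mp1 = mp1, mp2 = mp2, sg = sg,
              counts = c(n_mp = length(mp_idx), n_sg = length(sg_idx),
                         n_discarded = sum(short) + sum(multi)),
              discards = c(short_flank = sum(short),
                           multi_junction = sum(multi)))
  if (!is.null(out_prefix)) {
    Biostrings::writeQualityScaledXStringSet(mp1, paste0(out_prefix, "_MP_1.fastq"))
    Biostrings::writeQualityScaledXStringSet(mp2, paste0(out_prefix, "_MP_2.fastq"))
    Biostrings::writeQualityScaledXStringSet(sg, paste0(out_prefix, "_SG.fastq"))
  }
  out
}
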