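#' Primer pair
#'
#' @param name Label for the pair.
#' @param forward,reverse Primer sequences 5'->3' (A/C/G/T, length >= 15).
#' @param max_product Amplifiable product-size ceiling in bp (short
#'   extension times imply short amplicons; default 3,000).
#' @return One-row data.frame with columns \code{name, forward, reverse,
#'   max_product}.
#' @export
primer_pair <- function(name, forward, reverse, max_product = 3000) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stop_allseq("primer shorter than 15 nt: %s", p)
    if (grepl("[^ACGT]", p)) stop_allseq("primer must be A/C/G/T: %s", p)
  }
  if (max_product <= nchar(forward) + nchar(reverse))
    stop_allseq("max_product must exceed the summed primer lengths")
  data.frame(name = name, forward = forward, reverse = reverse,
             max_product = as.numeric(max_product), stringsAsFactors = FALSE)
}

#' Find primer binding sites in a genome
#'
#' Scans every chromosome for occurrences of the primer on the forward
#' strand and of its reverse complement (a reverse-strand site), with
#' up to \code{max_mismatches} mismatches (no indels).  Positions are
#' the 1-based coordinate of the primer's 5' end: for a forward-strand
#' site the leftmost matched base, for a reverse-strand site the
#' rightmost.
#'
#' @param genome \code{DNAStringSet} (or path to a FASTA file).
#' @param primer Primer sequence 5'->3'.
#' @param max_mismatches Allowed mismatches (default 0).
#' @return data.frame with columns \code{chrom, position, strand}.
#' @export
find_primer_sites <- function(genome, primer, max_mismatches = 0) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  primer <- toupper(primer)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  out <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    fwd <- Biostrings::matchPattern(primer, subject,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
    if (length(fwd))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, position = as.numeric(BiocGenerics::start(fwd)), strand = "+",
        stringsAsFactors = FALSE)
    rev <- Biostrings::matchPattern(rc, subject,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
    if (length(rev))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, position = as.numeric(BiocGenerics::end(rev)), strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), position = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$position), , drop = FALSE]
}

#' Predict the PCR outcome for a primer pair on one genome
#'
#' A product forms when a forward-strand site of the forward primer
#' and a reverse-strand site of the reverse primer face each other on
#' the same chromosome; the product size is the inclusive 5'-to-5'
#' distance.  A band is predicted when such a product exists and is no
#' longer than \code{max_product}; when several site combinations
#' exist, the smallest product is reported (shorter amplicons
#' outcompete longer ones).
#'
#' @param genome \code{DNAStringSet} (or FASTA path) of the sample
#'   genome, with any variants already applied.
#' @param pair One-row data.frame from [primer_pair()].
#' @param max_mismatches Allowed mismatches per primer site (default 0).
#' @param sample_id Label carried into the result.
#' @return data.frame (one row): \code{sample_id, band, product_size,
#'   site_status} with site_status one of \code{BOTH_SITES,
#'   MISSING_SITE, TOO_LONG}.
#' @export
predict_product <- function(genome, pair, max_mismatches = 0,
                            sample_id = "sample") {
  fwd <- find_primer_sites(genome, pair$forward, max_mismatches)
  rev <- find_primer_sites(genome, pair$reverse, max_mismatches)
  f <- fwd[fwd$strand == "+", , drop = FALSE]
  r <- rev[rev$strand == "-", , drop = FALSE]
  best <- Inf
  for (chrom in intersect(unique(f$chrom), unique(r$chrom))) {
    fp <- f$position[f$chrom == chrom]
    rp <- r$position[r$chrom == chrom]
    min_len <- nchar(pair$forward) + nchar(pair$reverse)
    for (p in fp) {
      # facing reverse site far enough downstream to fit both primers
      cand <- rp[rp - p + 1 >= min_len]
      if (length(cand)) best <- min(best, min(cand) - p + 1)
    }
  }
  if (is.infinite(best)) {
    status <- "MISSING_SITE"; size <- NA_real_; band <- FALSE
  } else if (best > pair$max_product) {
    status <- "TOO_LONG"; size <- best; band <- FALSE
  } else {
    status <- "BOTH_SITES"; size <- best; band <- TRUE
  }
  data.frame(sample_id = sample_id, band = band, product_size = size,
             site_status = status, stringsAsFactors = FALSE)
}

#' Predict PCR outcomes across a sample panel
#'
#' @param genomes Named list of \code{DNAStringSet} genomes (or FASTA
#'   paths), one per sample.
#' @param primers data.frame of primer pairs from [read_primers()] /
#'   [primer_pair()].
#' @param max_mismatches Allowed mismatches per site.
#' @return data.frame with one row per (primer pair, sample).
#' @export
predict_panel <- function(genomes, primers, max_mismatches = 0) {
  out <- list()
  for (i in seq_len(nrow(primers)))
    for (s in names(genomes)) {
      row <- predict_product(genomes[[s]], primers[i, , drop = FALSE],
                             max_mismatches, sample_id = s)
      row <- cbind(primer = primers$name[i], row, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- row
    }
  do.call(rbind, out)
}
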