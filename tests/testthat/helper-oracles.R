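# Independent brute-force oracles: deliberately naive implementations used
# to cross-check the package's vectorised / linkage-based code paths.

# quartile by explicit linear interpolation on the sorted sample
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive single-linkage closure over the pairwise link matrix
oracle_single_linkage <- function(start, end, window) {
  n <- length(start)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    overlap <- min(end[i], end[j]) >= max(start[i], start[j])
    link[i, j] <- overlap && abs(start[i] - start[j]) <= window &&
      abs(end[i] - end[j]) <= window
  }
  # transitive closure to fixpoint
  repeat {
    nxt <- link | (link %*% link > 0)
    if (identical(nxt, link)) break
    link <- nxt
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[link[i, ]] <- cur
    }
  }
  comp
}

# scan every offset of `read` for `adapter` within max_mm Hamming mismatches
oracle_adapter_scan <- function(read, adapter, max_mm) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(adapter, "")[[1]]),
                                     collapse = ""))
  hits <- data.frame(start = integer(), mm = integer(), strand = character())
  for (pat in unique(c(adapter, rc))) {
    m <- nchar(pat)
    strand <- if (pat == adapter) "+" else "-"
    if (m > nchar(read)) next
    for (s in 1:(nchar(read) - m + 1)) {
      win <- substring(read, s, s + m - 1)
      mm <- sum(strsplit(win, "")[[1]] != strsplit(pat, "")[[1]])
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(start = s, mm = mm, strand = strand))
    }
  }
  hits
}

# all exact/mismatched primer sites by sliding window
oracle_primer_scan <- function(seq_str, primer, max_mm) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(primer, "")[[1]]),
                                     collapse = ""))
  m <- nchar(primer)
  out <- data.frame(position = numeric(), strand = character())
  for (s in seq_len(nchar(seq_str) - m + 1)) {
    win <- substring(seq_str, s, s + m - 1)
    if (sum(strsplit(win, "")[[1]] != strsplit(primer, "")[[1]]) <= max_mm)
      out <- rbind(out, data.frame(position = s, strand = "+"))
    if (sum(strsplit(win, "")[[1]] != strsplit(rc, "")[[1]]) <= max_mm)
      out <- rbind(out, data.frame(position = s + m - 1, strand = "-"))
  }
  out
}

# build an aligned pair row (TSV dialect fields)
make_pair <- function(id, chrom1, s1, e1, chrom2 = chrom1, s2, e2,
                      strand1 = "+", strand2 = "-", mapq = 60,
                      fraction = "MP") {
  data.frame(pair_id = id, chrom1 = chrom1, start1 = s1, end1 = e1,
             strand1 = strand1, chrom2 = chrom2, start2 = s2, end2 = e2,
             strand2 = strand2, mapq = mapq, fraction = fraction,
             stringsAsFactors = FALSE)
}

# pairs supporting a library with given span, placed around `center`
support_pairs <- function(n, chrom, left_start, span, read_len = 150,
                          jitter = 0, prefix = "p") {
  rows <- lapply(seq_len(n), function(i) {
    off <- if (jitter > 0) sample(0:jitter, 1) else 0
    s1 <- left_start + off
    make_pair(paste0(prefix, i), chrom, s1, s1 + read_len - 1,
              chrom, s1 + span - read_len, s1 + span - 1)
  })
  do.call(rbind, rows)
}

# random call set for comparison tests
random_calls <- function(n, chrom = "chr1", max_pos = 1e6,
                         size_range = c(2e3, 50e3), sample_id = "s") {
  size <- round(runif(n, size_range[1], size_range[2]))
  start <- round(runif(n, 1, max_pos - max(size)))
  df <- data.frame(sample_id = sample_id, sv_type = "DEL", chrom = chrom,
                   start = start, end = start + size - 1, size = size,
                   support = 5L)
  df <- df[order(df$chrom, df$start), ]
  do.call(sv_callset, df)
}
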