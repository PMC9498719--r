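#' Simulation configuration for All-seq libraries
#'
#' Defaults emulate the library the method was designed around: mate
#' pairs whose spans concentrate near 6 kb with an interquartile range
#' of 0.6 kb, shotgun fragments near 330 bp (85\% within +/- 50 bp),
#' 150 bp reads, mate-pair depth 1.43x and shotgun depth 37.83x.
#' Depth here is sequence (read-base) depth: the number of mate pairs
#' is \code{mp_depth * genome_length / (2 * read_length)} and the
#' number of shotgun fragments \code{sg_depth * genome_length /
#' sg_size_mean}.  Spans are drawn from a normal distribution with
#' sigma = IQR / 1.349 (the normal-theory conversion); the family
#' itself is a modelling choice, not a measured fact.
#'
#' @param genome_length Total genome length in bp (default 1e6),
#'   split equally across chromosomes.
#' @param n_chromosomes Number of chromosomes (default 1).
#' @param mp_span_median Median mate-pair span in bp (default 6,000).
#' @param mp_span_iqr Interquartile range of spans in bp (default 600).
#' @param sg_size_mean Mean shotgun fragment size in bp (default 330).
#' @param sg_size_sd Shotgun size standard deviation (default 35,
#'   placing ~85\% of fragments within +/- 50 bp of the mean).
#' @param read_length Read length in bp (default 150).
#' @param mp_depth Mate-pair sequence depth (default 1.43).
#' @param sg_depth Shotgun sequence depth (default 37.83).
#' @param adapter_seq Junction adapter used when emitting raw reads
#'   (default: the 19 bp Tn5 mosaic-end sequence).
#' @param error_rate Per-base substitution rate in raw reads
#'   (default 0, error-free).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(genome_length = 1e6, n_chromosomes = 1,
                       mp_span_median = 6000, mp_span_iqr = 600,
                       sg_size_mean = 330, sg_size_sd = 35,
                       read_length = 150, mp_depth = 1.43,
                       sg_depth = 37.83,
                       adapter_seq = "AGATGTGTATAAGAGACAG",
                       error_rate = 0, seed = 1L) {
  for (nm in c("genome_length", "n_chromosomes", "mp_span_median",
               "mp_span_iqr", "sg_size_mean", "sg_size_sd", "read_length"))
    check_pos(get(nm), nm)
  structure(list(genome_length = genome_length,
                 n_chromosomes = as.integer(n_chromosomes),
                 mp_span_median = mp_span_median, mp_span_iqr = mp_span_iqr,
                 sg_size_mean = sg_size_mean, sg_size_sd = sg_size_sd,
                 read_length = as.integer(read_length),
                 mp_depth = mp_depth, sg_depth = sg_depth,
                 adapter_seq = toupper(adapter_seq),
                 error_rate = error_rate, seed = seed),
            class = "sim_config")
}

sim_chrom_lengths <- function(cfg) {
  per <- floor(cfg$genome_length / cfg$n_chromosomes)
  setNames(rep(per, cfg$n_chromosomes),
           paste0("chr", seq_len(cfg$n_chromosomes)))
}

#' Generate a random genome
#'
#' Uniform-random A/C/G/T sequence per chromosome, reproducible from
#' the configured seed.
#'
#' @param cfg A [sim_config()].
#' @return A named \code{DNAStringSet}.
#' @export
make_genome <- function(cfg) {
  lens <- sim_chrom_lengths(cfg)
  with_seed(cfg$seed, {
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(setNames(seqs, names(lens)))
  })
}

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Draw a random non-overlapping truth set of variants
#'
#' Variants are placed uniformly with at least \code{min_gap} bp
#' between them (and to chromosome ends), so that distinct events stay
#' distinct at mate-pair resolution.
#'
#' @param chrom_lengths Named lengths (reference genome).
#' @param n_del,n_ins Numbers of deletions / insertions.
#' @param del_size_range,ins_size_range Size ranges in bp.
#' @param min_gap Minimum distance between variants and to chromosome
#'   ends (default 10,000 bp).
#' @param seed Optional RNG seed.
#' @return data.frame with columns \code{sv_type, chrom, start, end,
#'   size} (1-based inclusive; insertions are points with
#'   \code{end = start}).
#' @export
random_variants <- function(chrom_lengths, n_del = 20, n_ins = 0,
                            del_size_range = c(10e3, 200e3),
                            ins_size_range = c(2e3, 10e3),
                            min_gap = 10e3, seed = NULL) {
  with_seed(seed, {
    sizes <- c(round(runif(n_del, del_size_range[1], del_size_range[2])),
               round(runif(n_ins, ins_size_range[1], ins_size_range[2])))
    types <- c(rep("DEL", n_del), rep("INS", n_ins))
    placed <- list()
    occupied <- lapply(names(chrom_lengths), function(x)
      data.frame(start = numeric(), end = numeric()))
    names(occupied) <- names(chrom_lengths)
    for (i in seq_along(sizes)) {
      span_needed <- if (types[i] == "DEL") sizes[i] else 1
      for (attempt in 1:1000) {
        chrom <- sample(names(chrom_lengths), 1,
                        prob = chrom_lengths / sum(chrom_lengths))
        L <- chrom_lengths[[chrom]]
        if (L < span_needed + 2 * min_gap) next
        s <- floor(runif(1, min_gap + 1, L - span_needed - min_gap))
        e <- s + span_needed - 1
        occ <- occupied[[chrom]]
        if (nrow(occ) && any(s - min_gap <= occ$end & e + min_gap >= occ$start))
          next
        occupied[[chrom]] <- rbind(occ, data.frame(start = s, end = e))
        placed[[i]] <- data.frame(sv_type = types[i], chrom = chrom,
                                  start = s, end = e, size = sizes[i],
                                  stringsAsFactors = FALSE)
        break
      }
      if (is.null(placed[[i]]))
        stop_allseq("could not place variant %d after 1000 attempts", i)
    }
    out <- do.call(rbind, placed)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

check_variants <- function(variants, chrom_lengths) {
  for (chrom in unique(variants$chrom)) {
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    v <- v[order(v$start), , drop = FALSE]
    if (!chrom %in% names(chrom_lengths))
      stop_allseq("variant on unknown chromosome %s", chrom)
    if (any(v$start < 1 | v$end > chrom_lengths[[chrom]]))
      stop_allseq("variant out of bounds on %s", chrom)
    if (nrow(v) > 1) {
      olap <- which(v$start[-1] <= v$end[-nrow(v)])
      if (length(olap))
        stop_allseq("overlapping variants on %s: %s:%s-%s and %s:%s-%s",
                    chrom, chrom, v$start[olap[1]], v$end[olap[1]],
                    chrom, v$start[olap[1] + 1], v$end[olap[1] + 1])
    }
  }
  invisible(TRUE)
}

# block map of one altered chromosome: data.frame(alt_start, alt_end,
# ref_start, ref_end, type) with type "M" (copied) or "I" (inserted)
build_block_map <- function(chrom_len, v) {
  v <- v[order(v$start), , drop = FALSE]
  blocks <- list(); cur_ref <- 1; cur_alt <- 1
  add <- function(blocks, rs, re, type) {
    len <- if (type == "I") re else re - rs + 1
    if (len <= 0) return(blocks)
    b <- data.frame(alt_start = cur_alt, alt_end = cur_alt + len - 1,
                    ref_start = if (type == "M") rs else NA_real_,
                    ref_end = if (type == "M") re else NA_real_,
                    type = type, stringsAsFactors = FALSE)
    cur_alt <<- cur_alt + len
    c(blocks, list(b))
  }
  for (i in seq_len(nrow(v))) {
    if (v$sv_type[i] == "DEL") {
      blocks <- add(blocks, cur_ref, v$start[i] - 1, "M")
      cur_ref <- v$end[i] + 1
    } else {  # insertion after position start
      blocks <- add(blocks, cur_ref, v$start[i], "M")
      blocks <- add(blocks, NA, v$size[i], "I")
      cur_ref <- v$start[i] + 1
    }
  }
  blocks <- add(blocks, cur_ref, chrom_len, "M")
  do.call(rbind, blocks)
}

#' Apply a variant set to a genome
#'
#' Deletions remove their inclusive interval; insertions add random
#' sequence immediately after their point.  Returns the altered genome
#' together with an exact block-level coordinate map between altered
#' and reference coordinates.
#'
#' @param genome Named \code{DNAStringSet}, or a named numeric vector
#'   of chromosome lengths for coordinate-only use (no sequence).
#' @param variants data.frame as from [random_variants()].
#' @param seed Optional RNG seed for the inserted sequence.
#' @return List (class \code{allseq_truth}) with \code{genome} (altered
#'   \code{DNAStringSet} or NULL), \code{truth} (the variant table),
#'   \code{map} (per-chromosome block map), \code{ref_lengths} and
#'   \code{alt_lengths}.
#' @export
apply_variants <- function(genome, variants, seed = NULL) {
  has_seq <- methods::is(genome, "DNAStringSet")
  ref_lengths <- if (has_seq)
    setNames(as.numeric(Biostrings::width(genome)), names(genome))
  else genome
  check_variants(variants, ref_lengths)
  maps <- lapply(names(ref_lengths), function(chrom)
    build_block_map(ref_lengths[[chrom]],
                    variants[variants$chrom == chrom, , drop = FALSE]))
  names(maps) <- names(ref_lengths)
  alt_lengths <- vapply(maps, function(m)
    if (nrow(m)) max(m$alt_end) else 0, numeric(1))
  alt_genome <- NULL
  if (has_seq) {
    alt_genome <- with_seed(seed, {
      seqs <- vapply(names(ref_lengths), function(chrom) {
        m <- maps[[chrom]]
        pieces <- vapply(seq_len(nrow(m)), function(i) {
          if (m$type[i] == "M")
            as.character(Biostrings::subseq(genome[[chrom]],
                                            m$ref_start[i], m$ref_end[i]))
          else random_dna(m$alt_end[i] - m$alt_start[i] + 1)
        }, character(1))
        paste(pieces, collapse = "")
      }, character(1))
      Biostrings::DNAStringSet(seqs)
    })
  }
  structure(list(genome = alt_genome, truth = variants, map = maps,
                 ref_lengths = ref_lengths, alt_lengths = alt_lengths),
            class = "allseq_truth")
}

# map altered-coordinate intervals back to reference coordinates;
# returns data.frame(ref_start, ref_end) with NA where the interval
# crosses a block boundary or lies in inserted sequence
map_alt_to_ref <- function(map, a1, a2) {
  idx <- findInterval(a1, map$alt_start)
  ok <- idx >= 1 & a2 <= map$alt_end[pmin(idx, nrow(map))] &
    map$type[pmin(idx, nrow(map))] == "M"
  rs <- ifelse(ok, map$ref_start[idx] + (a1 - map$alt_start[idx]), NA_real_)
  data.frame(ref_start = rs, ref_end = ifelse(ok, rs + (a2 - a1), NA_real_))
}

#' Simulate All-seq reads
#'
#' Draws mate-pair fragments (spans ~ Normal(median, IQR/1.349)) and
#' shotgun fragments from the altered genome, and reports them either
#' as already-aligned pair coordinates on the reference (the TSV pair
#' dialect; decouples caller tests from any aligner) or as raw
#' junction-bearing FASTQ reads, or both.  In raw reads the mate-pair
#' junction is represented as (fragment tail, adapter, fragment head),
#' so splitting at the adapter recovers the two genomic flanks.
#' Truth labels ride in the read/pair names (\code{id:index:fraction}).
#'
#' Fragments that would exceed the chromosome are resampled (counted);
#' mate-pair reads whose placement crosses a variant junction on the
#' reference (unalignable reads) are dropped from the pair table and
#' counted as \code{n_unmappable}.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional \code{allseq_truth} from [apply_variants()];
#'   when NULL, reads are simulated from an unaltered genome.
#' @param genome Optional \code{DNAStringSet}; required for
#'   \code{output != "pairs"} when \code{truth} carries no sequence.
#'   Defaults to [make_genome()] when sequence is needed.
#' @param output \code{"pairs"} (aligned-pair TSV data.frame),
#'   \code{"fastq"} (raw reads) or \code{"both"}.
#' @return List with \code{pairs} (data.frame in the TSV pair dialect
#'   with \code{strand2, mapq, fraction} columns), \code{reads}
#'   (\code{QualityScaledDNAStringSet} of raw reads or NULL),
#'   \code{counts} (n_mp, n_sg, n_resampled, n_unmappable) and
#'   \code{mp_labels} (per raw MP read: junction position truth).
#' @export
simulate_reads <- function(cfg, truth = NULL, genome = NULL,
                           output = c("pairs", "fastq", "both")) {
  output <- match.arg(output)
  need_seq <- output != "pairs"
  if (is.null(truth)) {
    ref_lengths <- if (!is.null(genome))
      setNames(as.numeric(Biostrings::width(genome)), names(genome))
    else sim_chrom_lengths(cfg)
    empty <- data.frame(sv_type = character(), chrom = character(),
                        start = numeric(), end = numeric(), size = numeric())
    if (need_seq && is.null(genome)) genome <- make_genome(cfg)
    truth <- apply_variants(genome %||% ref_lengths, empty)
  }
  alt_genome <- truth$genome
  if (need_seq && is.null(alt_genome))
    stop_allseq("raw-read output needs sequence: build truth from a DNAStringSet")
  rl <- cfg$read_length
  sd_span <- cfg$mp_span_iqr / 1.349
  alt_lengths <- truth$alt_lengths

  with_seed(cfg$seed, {
    n_mp <- round(cfg$mp_depth * sum(truth$ref_lengths) / (2 * rl))
    n_sg <- if (need_seq)
      round(cfg$sg_depth * sum(truth$ref_lengths) / cfg$sg_size_mean)
    else 0L
    # mate-pair fragments
    chroms <- sample(names(alt_lengths), n_mp, replace = TRUE,
                     prob = alt_lengths / sum(alt_lengths))
    spans <- round(rnorm(n_mp, cfg$mp_span_median, sd_span))
    n_resampled <- 0L
    bad <- which(spans < 2 * rl + 1 | spans > alt_lengths[chroms])
    while (length(bad)) {
      n_resampled <- n_resampled + length(bad)
      spans[bad] <- round(rnorm(length(bad), cfg$mp_span_median, sd_span))
      bad <- bad[spans[bad] < 2 * rl + 1 | spans[bad] > alt_lengths[chroms[bad]]]
    }
    g <- floor(runif(n_mp, 1, alt_lengths[chroms] - spans + 1))
    # read1 = fragment head, read2 = fragment tail (altered coordinates)
    r1 <- map_by_chrom(truth$map, chroms, g, g + rl - 1)
    r2 <- map_by_chrom(truth$map, chroms, g + spans - rl, g + spans - 1)
    mappable <- !is.na(r1$ref_start) & !is.na(r2$ref_start)
    pair_id <- sprintf("mp%06d", seq_len(n_mp))
    pairs <- data.frame(
      pair_id = pair_id[mappable],
      chrom1 = chroms[mappable],
      start1 = r1$ref_start[mappable], end1 = r1$ref_end[mappable],
      strand1 = "+",
      chrom2 = chroms[mappable],
      start2 = r2$ref_start[mappable], end2 = r2$ref_end[mappable],
      strand2 = "-", mapq = 60, fraction = "MP",
      stringsAsFactors = FALSE)
    rownames(pairs) <- NULL

    reads <- NULL; mp_labels <- NULL
    if (need_seq) {
      # raw MP read: fragment tail + adapter + fragment head
      heads <- extract_windows(alt_genome, chroms, g, g + rl - 1)
      tails <- extract_windows(alt_genome, chroms, g + spans - rl,
                               g + spans - 1)
      mp_seqs <- paste0(tails, cfg$adapter_seq, heads)
      mp_names <- paste0(pair_id, ":", seq_len(n_mp), ":MP")
      # shotgun fragments: junction-free
      sg_sizes <- pmax(round(rnorm(n_sg, cfg$sg_size_mean, cfg$sg_size_sd)),
                       2 * rl)
      sg_chroms <- sample(names(alt_lengths), n_sg, replace = TRUE,
                          prob = alt_lengths / sum(alt_lengths))
      sg_sizes <- pmin(sg_sizes, alt_lengths[sg_chroms])
      sg_g <- floor(runif(n_sg, 1, alt_lengths[sg_chroms] - sg_sizes + 1))
      sg_seqs <- extract_windows(alt_genome, sg_chroms, sg_g,
                                 sg_g + sg_sizes - 1)
      sg_names <- paste0(sprintf("sg%06d", seq_len(n_sg)), ":",
                         seq_len(n_sg), ":SG")
      all_seqs <- c(mp_seqs, sg_seqs)
      if (cfg$error_rate > 0) all_seqs <- add_errors(all_seqs, cfg$error_rate)
      dss <- Biostrings::DNAStringSet(setNames(all_seqs,
                                               c(mp_names, sg_names)))
      quals <- Biostrings::PhredQuality(
        Biostrings::BStringSet(vapply(Biostrings::width(dss), function(w)
          strrep("I", w), character(1))))
      reads <- Biostrings::QualityScaledDNAStringSet(dss, quals)
      mp_labels <- data.frame(read_id = mp_names, junction_pos = rl,
                              stringsAsFactors = FALSE)
    }
    list(pairs = pairs, reads = reads,
         counts = c(n_mp = n_mp, n_sg = n_sg, n_resampled = n_resampled,
                    n_unmappable = sum(!mappable)),
         mp_labels = mp_labels, truth = truth$truth,
         chrom_lengths = truth$ref_lengths)
  })
}

# vectorised alt->ref mapping across chromosomes
map_by_chrom <- function(maps, chroms, a1, a2) {
  rs <- re <- rep(NA_real_, length(chroms))
  for (chrom in unique(chroms)) {
    i <- chroms == chrom
    m <- map_alt_to_ref(maps[[chrom]], a1[i], a2[i])
    rs[i] <- m$ref_start; re[i] <- m$ref_end
  }
  data.frame(ref_start = rs, ref_end = re)
}

extract_windows <- function(genome, chroms, from, to) {
  out <- character(length(chroms))
  for (chrom in unique(chroms)) {
    i <- which(chroms == chrom)
    v <- Biostrings::Views(genome[[chrom]], start = from[i], end = to[i])
    out[i] <- as.character(v)
  }
  out
}

add_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated pairs in the TSV pair dialect
#'
#' @param pairs data.frame from [simulate_reads()].
#' @param path Output TSV.
#' @return \code{path}, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  cols <- c(pair_cols, "strand2", "mapq", "fraction")
  keep <- intersect(cols, names(pairs))
  write.table(pairs[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Score calls against an implanted truth set
#'
#' A truth deletion is recovered when a DEL call matches it at
#' reciprocal overlap at least \code{ro}; a truth insertion when an
#' INS call's midpoint lies within \code{ins_window} (default: the
#' library median span) of the insertion point.  Precision is the
#' fraction of calls matching some truth variant; with no calls it is
#' reported as NA.
#'
#' @param calls An [sv_callset()].
#' @param truth Truth table (\code{sv_type, chrom, start, end, size}),
#'   e.g. from [random_variants()].
#' @param ro Reciprocal-overlap fraction for deletions (default 0.5).
#' @param ins_window Insertion breakpoint tolerance in bp (default
#'   6,000).
#' @return List (class \code{sv_evaluation}): \code{precision},
#'   \code{recall}, \code{n_calls}, \code{n_truth}, and a per-variant
#'   \code{matches} table.
#' @export
evaluate_calls <- function(calls, truth, ro = 0.5, ins_window = 6000) {
  truth_matched <- rep(FALSE, nrow(truth))
  call_matched <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    same <- which(calls$sv_type == truth$sv_type[i] &
                  calls$chrom == truth$chrom[i])
    if (!length(same)) next
    if (truth$sv_type[i] == "DEL") {
      rf <- reciprocal_fraction(calls$start[same], calls$end[same],
                                truth$start[i], truth$end[i])
      hit <- same[rf >= ro]
    } else {
      mid <- (calls$start[same] + calls$end[same]) / 2
      hit <- same[abs(mid - truth$start[i]) <= ins_window]
    }
    if (length(hit)) { truth_matched[i] <- TRUE; call_matched[hit] <- TRUE }
  }
  out <- list(
    precision = if (nrow(calls)) sum(call_matched) / nrow(calls) else NA_real_,
    recall = if (nrow(truth)) sum(truth_matched) / nrow(truth) else NA_real_,
    n_calls = nrow(calls), n_truth = nrow(truth),
    matches = cbind(truth, recovered = truth_matched))
  class(out) <- "sv_evaluation"
  out
}

#' @export
print.sv_evaluation <- function(x, ...) {
  cat(sprintf("%d calls vs %d truth variants: precision %s, recall %s\n",
              x$n_calls, x$n_truth,
              format(x$precision, digits = 3), format(x$recall, digits = 3)))
  invisible(x)
}
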