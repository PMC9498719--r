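adapter <- "AGATGTGTATAAGAGACAG"

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

write_fastq <- function(seqs, path, ids = NULL) {
  ids <- ids %||% paste0("r", seq_along(seqs))
  con <- file(path, "w")
  for (i in seq_along(seqs))
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 strrep("I", nchar(seqs[i]))), con)
  close(con)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scan_junction finds the best adapter occurrence", {
  cfg <- junction_config(adapter, max_mismatches = 0)
  set.seed(7)

  # constructed identity: X + adapter + Y
  x <- rand_dna(37); y <- rand_dna(44)
  hit <- scan_junction(paste0(x, adapter, y), cfg)
  expect_identical(hit$pos, 37L)
  expect_identical(hit$strand, "+")

  # no occurrence within 1 mismatch -> absent
  cfg1 <- junction_config("TTTTTTTTTTTTTTTTTTT", max_mismatches = 1)
  expect_null(scan_junction(paste0(x, adapter, y), cfg1))

  # two exact occurrences -> leftmost
  r2 <- paste0(rand_dna(10), adapter, rand_dna(11), adapter, rand_dna(20))
  expect_identical(scan_junction(r2, cfg)$pos, 10L)
  expect_identical(scan_junction(r2, cfg)$n_sites, 2L)

  # adapter longer than the read -> absent, not an error
  expect_null(scan_junction("ACGT", cfg))

  # reverse-complement occurrence is found and labelled
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(adapter)))
  hit_rc <- scan_junction(paste0(x, rc, y), cfg)
  expect_identical(hit_rc$pos, 37L)
  expect_identical(hit_rc$strand, "-")
})

test_that("scan_junction agrees with a brute-force offset scan", {
  set.seed(11)
  cfg <- junction_config(adapter, max_mismatches = 1)
  for (i in 1:25) {
    read <- rand_dna(120)
    # half the time, implant a (possibly mutated) adapter copy
    if (i %% 2 == 0) {
      pos <- sample(1:(120 - nchar(adapter)), 1)
      ad <- strsplit(adapter, "")[[1]]
      if (i %% 4 == 0) ad[sample(length(ad), 1)] <- "A"
      substr(read, pos, pos + nchar(adapter) - 1) <- paste(ad, collapse = "")
    }
    hits <- oracle_adapter_scan(read, adapter, 1)
    got <- scan_junction(read, cfg)
    if (nrow(hits) == 0) {
      expect_null(got)
    } else {
      best <- hits[order(hits$mm, hits$start, hits$strand != "+"), ][1, ]
      expect_identical(got$pos, best$start - 1L)
      expect_identical(got$mismatches, best$mm)
    }
  }
})

test_that("split_reads partitions reads and preserves base content", {
  set.seed(23)
  cfg <- junction_config(adapter, max_mismatches = 0, min_flank = 20)
  n_mp <- 50; n_sg <- 50
  mp_seqs <- replicate(n_mp, paste0(rand_dna(150), adapter, rand_dna(150)))
  sg_seqs <- replicate(n_sg, rand_dna(330))
  tf <- tempfile(fileext = ".fastq")
  write_fastq(c(mp_seqs, sg_seqs), tf,
              ids = c(paste0("mp", 1:n_mp), paste0("sg", 1:n_sg)))
  res <- split_reads(tf, cfg)

  expect_equal(unname(res$counts), c(n_mp, n_sg, 0))
  expect_equal(sum(res$counts), n_mp + n_sg)
  # labels recovered perfectly on error-free reads with exact matching
  expect_setequal(names(res$mp1), paste0("mp", 1:n_mp))
  expect_setequal(names(res$sg), paste0("sg", 1:n_sg))

  # base-content conservation: flank1 + adapter + flank2 == original read
  rebuilt <- paste0(as.character(res$mp1), adapter, as.character(res$mp2))
  expect_identical(unname(rebuilt),
                   unname(mp_seqs[match(names(res$mp1), paste0("mp", 1:n_mp))]))
  # qualities survive with matching widths
  expect_identical(Biostrings::width(Biostrings::quality(res$mp1)),
                   Biostrings::width(res$mp1))
})

test_that("short flanks and multi-junction reads are discarded and counted", {
  cfg <- junction_config(adapter, min_flank = 20)
  set.seed(31)
  short <- paste0(rand_dna(5), adapter, rand_dna(150))    # left flank 5 < 20
  multi <- paste0(rand_dna(30), adapter, rand_dna(30), adapter, rand_dna(30))
  ok <- paste0(rand_dna(40), adapter, rand_dna(40))
  tf <- write_fastq(c(short, multi, ok), tempfile(fileext = ".fastq"))
  res <- split_reads(tf, cfg)
  expect_identical(unname(res$counts), c(1L, 0L, 2L))
  expect_identical(unname(res$discards),
                   c(1L, 1L))
})

test_that("empty and malformed FASTQ are handled", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  res <- split_reads(empty, junction_config(adapter))
  expect_identical(unname(res$counts), c(0L, 0L, 0L))

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "not-a-header", "ACGT", "+",
               "IIII"), bad)
  expect_error(split_reads(bad, junction_config(adapter)), "record 2")
})

test_that("splitting simulator output recovers the truth labels exactly", {
  cfg <- sim_config(genome_length = 5e4, sg_depth = 2, mp_depth = 0.5,
                    seed = 5)
  sim <- simulate_reads(cfg, output = "both")
  jcfg <- junction_config(cfg$adapter_seq, max_mismatches = 0,
                          min_flank = 20)
  tf <- tempfile(fileext = ".fastq")
  Biostrings::writeQualityScaledXStringSet(sim$reads, tf)
  res <- split_reads(tf, jcfg)
  truth_mp <- grepl(":MP$", names(sim$reads))
  # 100% split accuracy at zero mismatches on error-free reads
  expect_identical(unname(res$counts["n_mp"]), sum(truth_mp))
  expect_identical(unname(res$counts["n_sg"]), sum(!truth_mp))
  expect_true(all(grepl(":MP$", names(res$mp1))))
  expect_true(all(grepl(":SG$", names(res$sg))))
})
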