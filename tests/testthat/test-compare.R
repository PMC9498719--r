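test_that("sample specificity reproduces the 87-of-971 arithmetic", {
  # 971 focal deletions > 10 kb of which 884 are matched in a reference:
  # 87 specific, 9% after round-half-up
  set.seed(19)
  n <- 971; matched <- 884
  start <- seq(1, by = 40e3, length.out = n)
  size <- 20e3
  focal <- sv_callset(sample_id = "cellline", sv_type = "DEL",
                      chrom = "chr1", start = start,
                      end = start + size - 1, size = size, support = 5L)
  ref <- focal[seq_len(matched), ]
  ref$sample_id <- "breedA"
  class(ref) <- class(focal)
  cmp <- compare_samples(focal, list(ref), ro = 0.5)
  expect_equal(cmp$n_specific, n - matched)
  expect_identical(cmp$percent_specific, 9)
})

test_that("reciprocal overlap governs shared/specific labels", {
  one <- sv_callset("a", "DEL", "chr1", 10000, 19999, 10000, 5L)
  same <- sv_callset("b", "DEL", "chr1", 10000, 19999, 10000, 5L)
  expect_identical(compare_samples(one, same, ro = 0.5)$labels, "SHARED")

  # 40% reciprocal overlap misses an ro = 0.5 cutoff
  shifted <- sv_callset("b", "DEL", "chr1", 16000, 25999, 10000, 5L)
  ov <- (19999 - 16000 + 1) / 10000
  expect_lt(ov, 0.5)
  expect_identical(compare_samples(one, shifted, ro = 0.5)$labels, "SPECIFIC")
  expect_identical(compare_samples(one, shifted, ro = 0.4)$labels, "SHARED")

  # type mismatch never matches
  ins <- sv_callset("b", "INS", "chr1", 10000, 19999, 10000, 5L)
  expect_identical(compare_samples(one, ins, ro = 0.5)$labels, "SPECIFIC")
})

test_that("reference sample order never changes the labels", {
  set.seed(29)
  focal <- random_calls(40, sample_id = "focal")
  refs <- list(random_calls(30, sample_id = "r1"),
               random_calls(30, sample_id = "r2"),
               random_calls(30, sample_id = "r3"))
  a <- compare_samples(focal, refs, ro = 0.5)
  b <- compare_samples(focal, rev(refs), ro = 0.5)
  expect_identical(a$labels, b$labels)
})

test_that("size binning reproduces the printed 75/11/14 percentages", {
  sizes <- c(runif(65, 10e3, 50e3 - 1), runif(10, 50e3, 100e3 - 1),
             runif(12, 100e3, 5e6))
  calls <- data.frame(size = sizes)
  b <- bin_by_size(calls)
  expect_equal(b$count, c(0, 65, 10, 12))
  expect_equal(b$percent, c(0, 75, 11, 14))
  expect_true(abs(sum(b$percent) - 100) <= 1)
})

test_that("size bins are half-open with an explicit underflow bin", {
  b <- bin_by_size(data.frame(size = c(10000, 49999, 50000)))
  expect_equal(b$count, c(0, 2, 1, 0))
  b2 <- bin_by_size(data.frame(size = 5000))
  expect_equal(b2$count, c(1, 0, 0, 0))
  expect_equal(b2$percent[1], 100)
  expect_error(bin_by_size(data.frame(size = 1), edges = c(5, 5, 10)),
               "strictly increasing")
})

test_that("binning percentages sum to 100 +/- 1 on random inputs", {
  set.seed(59)
  for (i in 1:20) {
    calls <- data.frame(size = runif(sample(1:200, 1), 1e3, 2e5))
    b <- bin_by_size(calls)
    expect_identical(sum(b$count), nrow(calls))
    expect_true(abs(sum(b$percent) - 100) <= 1)
  }
})

test_that("gene overlap matches brute-force interval intersection", {
  set.seed(61)
  genes <- data.frame(
    gene_id = paste0("g", 1:100), chrom = sample(c("chr1", "chr2"), 100, TRUE),
    start = sample.int(1e6, 100), strand = "+")
  genes$end <- genes$start + sample(500:20000, 100, TRUE)
  calls <- random_calls(10, chrom = "chr1")
  calls$chrom[1:3] <- "chr2"
  got <- gene_overlap(calls, genes)
  for (i in seq_len(nrow(calls))) {
    want <- genes$gene_id[genes$chrom == calls$chrom[i] &
                          genes$start <= calls$end[i] &
                          genes$end >= calls$start[i]]
    expect_setequal(got[[i]], want)
  }
  # boundary: a deletion ending 1 bp before a gene does not touch it
  g1 <- data.frame(gene_id = "g", chrom = "chr1", start = 5000, end = 6000,
                   strand = "+")
  del_before <- sv_callset("s", "DEL", "chr1", 1000, 4999, 4000, 3L)
  del_touch <- sv_callset("s", "DEL", "chr1", 1000, 5000, 4001, 3L)
  expect_identical(gene_overlap(del_before, g1)[[1]], character(0))
  expect_identical(gene_overlap(del_touch, g1)[[1]], "g")
})

test_that("expression status applies the hysteresis loss/gain rule", {
  expr <- data.frame(
    gene_id = rep(c("CD163", "g2", "g3", "g4"), each = 2),
    sample_id = rep(c("PAM", "line"), 4),
    rpkm = c(50, 0,   0, 30,   5, 5,   0.5, 0.05))
  st <- expression_status(expr, "PAM", "line")
  stat <- setNames(st$status, st$gene_id)
  expect_identical(unname(stat["CD163"]), "LOSS")
  expect_identical(unname(stat["g2"]), "GAIN")
  expect_identical(unname(stat["g3"]), "UNCHANGED")
  expect_identical(unname(stat["g4"]), "UNCHANGED")  # sub-threshold change
  # sorted by |difference| descending
  expect_identical(st$gene_id[1], "CD163")

  # LOSS/GAIN duality under sample swap
  sw <- expression_status(expr, "line", "PAM")
  swapped <- setNames(sw$status, sw$gene_id)
  expect_identical(unname(swapped["CD163"]), "GAIN")
  expect_identical(unname(swapped["g2"]), "LOSS")

  expect_error(expression_status(
    data.frame(gene_id = "g", sample_id = "a", rpkm = -1), "a", "b"),
    "non-negative")
  expect_warning(
    expression_status(rbind(expr, data.frame(gene_id = "g5",
                                             sample_id = "PAM", rpkm = 9)),
                      "PAM", "line"),
    "treated as 0")
})

test_that("TAD fusion flags count removed boundaries correctly", {
  tads <- data.frame(chrom = "chr1",
                     start = c(1, 100001, 200001, 300001),
                     end = c(100000, 200000, 300000, 400000))
  mk_del <- function(s, e) sv_callset("s", "DEL", "chr1", s, e, e - s + 1, 3L)

  inside <- tad_fusion_flags(mk_del(10000, 50000), tads)
  expect_false(inside$fused)
  expect_identical(inside$removed_boundaries, 0L)

  crossing <- tad_fusion_flags(mk_del(90000, 150000), tads)
  expect_true(crossing$fused)
  expect_identical(crossing$removed_boundaries, 1L)

  spanning3 <- tad_fusion_flags(mk_del(90000, 250000), tads)
  expect_true(spanning3$fused)
  expect_identical(spanning3$removed_boundaries, 2L)

  # endpoint outside any TAD -> unassigned, not fused
  gap_tads <- data.frame(chrom = "chr1", start = c(1, 300000),
                         end = c(100000, 400000))
  unas <- tad_fusion_flags(mk_del(50000, 200000), gap_tads)
  expect_false(unas$fused)
  expect_identical(unas$note, "unassigned")
})

test_that("removed boundary counts match brute force on random fixtures", {
  set.seed(67)
  for (i in 1:15) {
    n_tad <- sample(3:12, 1)
    bounds <- sort(sample.int(1e6, n_tad + 1))
    tads <- data.frame(chrom = "chr1", start = head(bounds, -1) + 1,
                       end = tail(bounds, -1))
    tads$start[1] <- 1
    s <- sample.int(9e5, 1); e <- s + sample.int(99999, 1)
    del <- sv_callset("s", "DEL", "chr1", s, e, e - s + 1, 3L)
    got <- tad_fusion_flags(del, tads)
    mids <- (tads$end[-nrow(tads)] + tads$start[-1]) / 2
    expect_identical(got$removed_boundaries, sum(mids > s & mids < e))
  }
})

test_that("chromosome distribution tabulates calls and gene changes", {
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  calls <- sv_callset(sample_id = "s", sv_type = c("DEL", "DEL", "INS"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(1000, 5000, 2000),
                      end = c(3000, 9000, 2000),
                      size = c(2001, 4001, 1500), support = 3L)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                      start = c(100, 200), end = c(500, 600), strand = "+")
  gc <- data.frame(gene_id = c("g1", "g2"),
                   status = c("LOSS", "GAIN"),
                   rpkm_ref = c(10, 0), rpkm_focal = c(0, 10))
  d <- chromosome_distribution(calls, gc, genes, lens)
  expect_equal(d$n_del, c(2, 0))
  expect_equal(d$n_ins, c(0, 1))
  expect_equal(d$n_loss, c(1, 0))
  expect_equal(d$n_gain, c(0, 1))

  empty <- chromosome_distribution(sv_callset(), chrom_lengths = lens)
  expect_true(all(empty$n_del == 0) && all(empty$n_ins == 0))

  bad <- calls; bad$chrom[1] <- "chrX"
  expect_error(chromosome_distribution(bad, chrom_lengths = lens), "chrX")
})
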