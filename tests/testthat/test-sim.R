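test_that("genome generation is seed-deterministic with uniform bases", {
  cfg <- sim_config(genome_length = 1e5, seed = 42)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  cfg2 <- sim_config(genome_length = 1e6, seed = 43)
  g <- make_genome(cfg2)
  gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.5), 0.01)    # binomial bound at n = 1e6

  cfg3 <- sim_config(genome_length = 1e6, n_chromosomes = 2, seed = 44)
  g3 <- make_genome(cfg3)
  expect_identical(names(g3), c("chr1", "chr2"))
  expect_identical(Biostrings::width(g3), c(500000L, 500000L))
})

test_that("apply_variants conserves length exactly", {
  cfg <- sim_config(genome_length = 2e6, seed = 45)
  g <- make_genome(cfg)

  del <- data.frame(sv_type = "DEL", chrom = "chr1", start = 500001,
                    end = 500000 + 848712, size = 848712)
  res <- apply_variants(g, del)
  expect_identical(Biostrings::width(res$genome)[1], 2000000L - 848712L)

  ins <- data.frame(sv_type = "INS", chrom = "chr1", start = 1000,
                    end = 1000, size = 2000)
  res2 <- apply_variants(g, ins, seed = 9)
  expect_identical(Biostrings::width(res2$genome)[1], 2000000L + 2000L)

  none <- apply_variants(g, del[0, ])
  expect_identical(as.character(none$genome), as.character(g))

  # random variant sets: bookkeeping identity on every draw
  lens <- c(chr1 = 2e6)
  for (seed in 1:5) {
    v <- random_variants(lens, n_del = 5, n_ins = 3,
                         del_size_range = c(2e3, 50e3), seed = seed)
    r <- apply_variants(lens, v)
    expect_equal(unname(r$alt_lengths),
                 2e6 - sum(v$size[v$sv_type == "DEL"]) +
                   sum(v$size[v$sv_type == "INS"]))
  }
})

test_that("overlapping variants are rejected with the offending pair", {
  v <- data.frame(sv_type = c("DEL", "DEL"), chrom = "chr1",
                  start = c(1000, 1500), end = c(2000, 2500),
                  size = c(1001, 1001))
  expect_error(apply_variants(c(chr1 = 1e5), v), "overlapping")
})

test_that("the coordinate map is exact around a deletion", {
  lens <- c(chr1 = 1e6)
  del <- data.frame(sv_type = "DEL", chrom = "chr1", start = 100001,
                    end = 200000, size = 100000)
  truth <- apply_variants(lens, del)
  m <- truth$map$chr1
  # before the deletion: identity; after: shifted by the deletion size
  expect_equal(allseq:::map_alt_to_ref(m, 50, 80)$ref_start, 50)
  expect_equal(allseq:::map_alt_to_ref(m, 100001, 100100)$ref_start, 200001)
  # interval crossing the junction is unmappable
  expect_true(is.na(allseq:::map_alt_to_ref(m, 99950, 100050)$ref_start))
})

test_that("simulated spans match the configured library distribution", {
  cfg <- sim_config(genome_length = 1e7, mp_depth = 0.9, seed = 46)
  sim <- simulate_reads(cfg, output = "pairs")
  sp <- compute_spans(sim$pairs)
  expect_gt(nrow(sim$pairs), 10000)
  med <- median(sp$span)
  iqr <- unname(diff(quantile(sp$span, c(0.25, 0.75))))
  expect_true(med >= 5900 && med <= 6100)
  expect_true(iqr >= 540 && iqr <= 660)
  expect_true(all(sp$locus_class == "INTRA"))
})

test_that("simulation output is reproducible from the seed", {
  cfg <- sim_config(genome_length = 1e5, mp_depth = 1.43, sg_depth = 3,
                    seed = 47)
  a <- simulate_reads(cfg, output = "both")
  b <- simulate_reads(cfg, output = "both")
  expect_identical(a$pairs, b$pairs)
  expect_identical(as.character(a$reads), as.character(b$reads))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  Biostrings::writeQualityScaledXStringSet(a$reads, f1)
  Biostrings::writeQualityScaledXStringSet(b$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("pairs straddling an implanted deletion show inflated spans", {
  lens <- c(chr1 = 2e6)
  del <- data.frame(sv_type = "DEL", chrom = "chr1", start = 1000001,
                    end = 1100000, size = 100000)
  cfg <- sim_config(genome_length = 2e6, mp_depth = 3, seed = 48)
  sim <- simulate_reads(cfg, truth = apply_variants(lens, del),
                        output = "pairs")
  sp <- compute_spans(sim$pairs)
  straddle <- sp$outer_start < 1000001 & sp$outer_end > 1100000
  expect_gt(sum(straddle), 5)
  expect_true(all(abs(sp$span[straddle] - (100000 + 6000)) < 4000))
  expect_true(median(sp$span[!straddle]) < 7000)
})

test_that("truth evaluation scores calls against implanted variants", {
  truth <- data.frame(sv_type = c("DEL", "DEL"), chrom = "chr1",
                      start = c(10000, 200000), end = c(30000, 260000),
                      size = c(20001, 60001))
  exact <- sv_callset(sample_id = "s", sv_type = "DEL", chrom = "chr1",
                      start = truth$start, end = truth$end,
                      size = truth$size, support = 5L)
  ev <- evaluate_calls(exact, truth, ro = 0.5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  none <- evaluate_calls(sv_callset(), truth, ro = 0.5)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  # half-matching fixture: one of two truths recovered, one stray call
  half <- sv_callset(sample_id = "s", sv_type = "DEL", chrom = "chr1",
                     start = c(10000, 500000), end = c(30000, 520000),
                     size = c(20001, 20001), support = 5L)
  ev2 <- evaluate_calls(half, truth, ro = 0.5)
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$recall, 0.5)
  expect_identical(ev2$matches$recovered, c(TRUE, FALSE))
})
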