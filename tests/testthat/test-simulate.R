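# synthetic panel generation and mock-community read simulation

test_that("panels are deterministic under seed and carry well-formed tags", {
  p1 <- generate_panel(5, 2000, strain_groups = c(2, 1, 1, 1), seed = 7)
  p2 <- generate_panel(5, 2000, strain_groups = c(2, 1, 1, 1), seed = 7)
  expect_identical(p1, p2)
  expect_true(all(grepl("^[A-Z]{3}_[A-Z]{3}_S[0-9]+$", p1$tag)))
  expect_false(anyDuplicated(p1$tag) > 0)
  expect_true(all(p1$length == 2000))
  # sibling strains share genus+species prefix
  expect_equal(substr(p1$tag[1], 1, 7), substr(p1$tag[2], 1, 7))
  expect_error(generate_panel(4, 1000, strain_groups = c(2, 1)), "sum")
  expect_error(generate_panel(2, 1000, mutation_rate = 0.5), "mutation_rate")
})

test_that("strain divergence matches the binomial expectation and keeps unique n-grams", {
  p <- generate_panel(2, 100000, strain_groups = 2L, mutation_rate = 0.001,
                      repeat_fraction = 0, seed = 13)
  a <- strsplit(p$sequence[1], "")[[1]]
  b <- strsplit(p$sequence[2], "")[[1]]
  mism <- sum(a != b)
  # every accepted mutation changes the base, so mismatches ~ Binomial(1e5, 0.001)
  expect_gt(mism, 100 - 3 * sqrt(100))
  expect_lt(mism, 100 + 3 * sqrt(100))
  m <- build_model(p, n = 12)
  per_tag <- m$membership[m$index[m == 1L], on = "ngram"][, .N, by = tag]
  expect_true(all(p$tag %in% per_tag$tag))   # both strains keep unique n-grams
})

test_that("repeat_fraction steers the repeat ratio", {
  p0 <- generate_panel(2, 50000, repeat_fraction = 0, seed = 17)
  pr <- build_profile(p0, n = 12)
  expect_true(all(pr$genomes$repeat_ratio < 1))   # random collisions only

  p4 <- generate_panel(2, 50000, repeat_fraction = 0.4, seed = 17)
  pr4 <- build_profile(p4, n = 12)
  expect_true(all(pr4$genomes$repeat_ratio > 25))
  expect_true(all(pr4$genomes$repeat_ratio < 60))
})

test_that("staggered abundances stay in range and sum to 100", {
  a <- staggered_abundances(50, seed = 19)
  expect_equal(sum(a), 100, tolerance = 1e-9)
  expect_true(all(a >= 0.1 - 1e-12 & a <= 10 + 1e-12))
  expect_identical(a, staggered_abundances(50, seed = 19))
})

test_that("error-free forward reads are exact substrings; same seed, same reads", {
  p <- generate_panel(3, 3000, seed = 23)
  spec <- community_spec(data.frame(tag = p$tag, abundance = c(20, 30, 50)),
                         total_reads = 300, sub_rate_start = 0, sub_rate_end = 0,
                         ins_rate = 0, del_rate = 0, strand = FALSE, seed = 29)
  reads <- simulate_reads(p, spec)
  expect_equal(nrow(reads), 300)
  for (i in sample.int(nrow(reads), 20)) {
    g <- p$sequence[match(reads$tag[i], p$tag)]
    expect_true(grepl(reads$sequence[i], g, fixed = TRUE))
  }
  reads2 <- simulate_reads(p, spec)
  expect_identical(reads$sequence, reads2$sequence)

  # with error rate 0 and strand off, every read n-gram is in the full model
  m <- build_model(p, n = 12)
  grams <- unique(unlist(lapply(reads$sequence[1:50], function(r)
    extract_ngrams(r, 12)$distinct)))
  expect_true(all(grams %in% m$index$ngram))
})

test_that("read counts follow the abundance(xlength) weights within binomial noise", {
  p <- generate_panel(2, 4000, seed = 31)
  spec <- community_spec(data.frame(tag = p$tag, abundance = c(50, 50)),
                         total_reads = 10000, seed = 37)
  reads <- simulate_reads(p, spec)
  counts <- table(reads$tag)
  expect_true(all(abs(counts - 5000) < 3 * sqrt(10000 * 0.25)))

  # abundance-only weighting with unequal genome lengths still splits 50/50
  p2 <- genome_panel(name = c("a a", "b b"),
                     sequence = c(p$sequence[1], substr(p$sequence[2], 1, 1000)),
                     tag = p$tag)
  spec2 <- community_spec(data.frame(tag = p2$tag, abundance = c(50, 50)),
                          total_reads = 10000, weight_by_length = FALSE, seed = 41)
  c2 <- table(simulate_reads(p2, spec2)$tag)
  expect_true(all(abs(c2 - 5000) < 3 * sqrt(10000 * 0.25)))
})

test_that("empirical substitution rate matches the configured ramp within 3 sigma", {
  p <- generate_panel(1, 20000, strain_groups = 1L, seed = 43)
  spec <- community_spec(data.frame(tag = p$tag, abundance = 100),
                         total_reads = 5000, ins_rate = 0, del_rate = 0,
                         strand = FALSE, seed = 47)
  reads <- simulate_reads(p, spec)
  g <- p$sequence[1]
  # recover each read's origin by matching its first error-free anchor is
  # fragile; instead simulate with known starts by regenerating:
  # compare read to the genome window with fewest mismatches is overkill --
  # count mismatches against the aligned window via the truth of uniform
  # starts being recoverable from an error-free control run with the same seed
  spec0 <- community_spec(data.frame(tag = p$tag, abundance = 100),
                          total_reads = 5000, sub_rate_start = 0, sub_rate_end = 0,
                          ins_rate = 0, del_rate = 0, strand = FALSE, seed = 47)
  clean <- simulate_reads(p, spec0)
  a <- strsplit(reads$sequence, "")
  b <- strsplit(clean$sequence, "")
  mism <- sum(mapply(function(x, y) sum(x != y), a, b))
  n_bases <- sum(nchar(reads$sequence))
  expected_rate <- mean(c(0.001, 0.01))   # linear ramp average
  expect_lt(abs(mism / n_bases - expected_rate),
            3 * sqrt(expected_rate / n_bases) + 1e-4)
})

test_that("paired-end mode emits mate pairs that the classifier can use independently", {
  p <- generate_panel(2, 3000, seed = 53)
  spec <- community_spec(data.frame(tag = p$tag, abundance = c(40, 60)),
                         total_reads = 200, paired = TRUE, insert_size = 300,
                         seed = 59)
  reads <- simulate_reads(p, spec)
  expect_equal(nrow(reads), 400)
  expect_setequal(unique(reads$mate), c(1L, 2L))
  expect_true(all(grepl("/[12]$", reads$read_id)))
  m <- build_model(p, n = 12)
  cls <- classify_read_sets(split(reads$sequence, reads$tag), m)
  expect_equal(cls$predicted, cls$set)
})

test_that("simulated reads and truth tables round-trip through disk", {
  p <- generate_panel(2, 2000, seed = 61)
  spec <- community_spec(data.frame(tag = p$tag, abundance = c(50, 50)),
                         total_reads = 50, seed = 67)
  reads <- simulate_reads(p, spec)
  fq <- withr::local_tempfile(fileext = ".fq")
  tr <- withr::local_tempfile(fileext = ".tsv")
  write_simulated_reads(reads, fq, tr)
  back <- read_reads(fq)
  expect_equal(unname(back), reads$sequence)
  truth <- utils::read.delim(tr, comment.char = "#")
  expect_equal(truth$read_id, reads$read_id)
  expect_equal(truth$tag, reads$tag)
})
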