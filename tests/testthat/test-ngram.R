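# n-gram extraction, dampening weights, profiles, model building

test_that("n-gram extraction follows the k-n+1 sliding window", {
  r <- extract_ngrams("ACGTACGTACGTA", 12)
  expect_setequal(r$distinct, c("ACGTACGTACGT", "CGTACGTACGTA"))
  expect_equal(r$total, 2)
  expect_equal(r$repeated, 0)

  r <- extract_ngrams("AAAAAAAAAAAAA", 12)   # homopolymer, k = 13
  expect_equal(r$distinct, "AAAAAAAAAAAA")
  expect_equal(r$total, 2)
  expect_equal(r$repeated, 1)

  # ambiguity letters are literal alphabet members
  expect_equal(extract_ngrams("ACGTN", 3)$distinct, c("ACG", "CGT", "GTN"))

  # shorter than n: empty result, not an error
  r <- extract_ngrams("ACG", 12)
  expect_equal(r$total, 0)
  expect_length(r$distinct, 0)
})

test_that("distinct + repeated = total = length - n + 1 over random sequences", {
  for (seed in 1:10) {
    s <- with(list(), { set.seed(seed); paste(sample(c("A","C","G","T"), 200, TRUE), collapse = "") })
    n <- sample(2:15, 1)
    r <- extract_ngrams(s, n)
    expect_equal(r$total, nchar(s) - n + 1)
    expect_equal(length(r$distinct) + r$repeated, r$total)
  }
})

test_that("dampening weight has the exact endpoints and closed-form values", {
  expect_identical(dampening_weight(1, 2031), 1)
  expect_identical(dampening_weight(2031, 2031), 0)
  expect_equal(dampening_weight(10, 100), 0.5)
  expect_equal(dampening_weight(2, 3), log(3 / 2) / log(3))  # ~0.3690702
  expect_error(dampening_weight(0, 10), "m must")
  expect_error(dampening_weight(11, 10), "m must")
})

test_that("weight is strictly decreasing in m and base-invariant", {
  for (C in c(2, 10, 2031)) {
    w <- dampening_weight(seq_len(C), C)
    expect_true(all(diff(w) < 0))
    expect_equal(w[1], 1)
    expect_equal(w[C], 0)
    expect_equal(dampening_weight(seq_len(C), C, base = 10), w, tolerance = 1e-14)
    expect_equal(dampening_weight(seq_len(C), C, base = 2), w, tolerance = 1e-14)
  }
})

test_that("profiles count repeats per genome and compute panel mu/sigma", {
  p <- genome_panel(name = c("a a", "b b"),
                    sequence = c("AAAAAAAAAAAAAA",        # len 14: total 3, distinct 1
                                 "ACGTACGTACGTACGTACGT"), # periodic: repeats
                    tag = c("AAA_AAA_1", "BBB_BBB_1"))
  pr <- build_profile(p, n = 12)
  g1 <- pr$genomes[tag == "AAA_AAA_1"]
  expect_equal(g1$total, 3)
  expect_equal(g1$distinct, 1)
  expect_equal(g1$repeated, 2)
  expect_equal(g1$repeat_ratio, 100 * 2 / 3, tolerance = 1e-12)
  # population sd of the two repeat ratios
  rr <- pr$genomes$repeat_ratio
  expect_equal(pr$mu, mean(rr))
  expect_equal(pr$sigma, sqrt(mean((rr - mean(rr))^2)))
  expect_gt(build_profile(p, n = 12, sigma_type = "sample")$sigma, pr$sigma)
})

test_that("duplicate tags error unless replicons are pooled", {
  p <- genome_panel(name = c("x x", "x x", "y y"),
                    sequence = c("ACGTACGTACGTACG", "GGGGGGGGGGGGGGG", "TTTTACGTACGTTTT"),
                    tag = c("XXX_XXX_1", "XXX_XXX_1", "YYY_YYY_1"))
  expect_error(build_profile(p, n = 12), "duplicate")
  pr <- build_profile(p, n = 12, pool_replicons = TRUE)
  expect_equal(nrow(pr$genomes), 2)
  # pooled totals: (15-12+1) + (15-12+1) = 8
  expect_equal(pr$genomes[tag == "XXX_XXX_1"]$total, 8)
})

test_that("full model indexes the union of distinct n-grams with correct m", {
  p <- toy_panel()   # disjoint sequences
  m <- build_model(p, n = 12)
  expect_true(all(m$index$m == 1))
  expect_true(all(m$index$weight == 1))

  # identical sequences under distinct tags: everything common with m = 2
  p2 <- genome_panel(name = c("a a", "b b"),
                     sequence = rep("ACGTTGCAACGTTGCA", 2),
                     tag = c("AAA_AAA_1", "BBB_BBB_1"))
  m2 <- build_model(p2, n = 12)
  expect_true(all(m2$index$m == 2))
  expect_true(all(m2$index$weight == 0))

  # 3-genome panel, shared n-gram in 2 of 3 gets the closed-form weight
  shared <- "ACGTGGCCAATT"
  p3 <- genome_panel(name = c("a a", "b b", "c c"),
                     sequence = c(paste0(shared, "CCCCC"),
                                  paste0("GGGGG", shared),
                                  "TATATATATATATATATA"),
                     tag = c("AAA_AAA_1", "BBB_BBB_1", "CCC_CCC_1"))
  m3 <- build_model(p3, n = 12)
  expect_equal(m3$index[ngram == shared]$weight, log(3 / 2) / log(3))
  expect_equal(m3$index[ngram == shared]$m, 2L)
})

test_that("partial models sample round(alpha * distinct) per genome, reproducibly", {
  p <- random_panel(3, 1000, seed = 9)
  full <- build_model(p, n = 12)
  half1 <- build_model(p, n = 12, alpha = 0.5, seed = 3)
  half2 <- build_model(p, n = 12, alpha = 0.5, seed = 3)
  expect_identical(half1$membership, half2$membership)   # determinism
  expect_identical(half1$index$weight, half2$index$weight)

  sets <- genome_sets <- split(full$membership$ngram, full$membership$tag)
  half_sets <- split(half1$membership$ngram, half1$membership$tag)
  for (t in names(sets)) {
    expect_equal(length(half_sets[[t]]), round(0.5 * length(sets[[t]])))
    expect_true(all(half_sets[[t]] %in% sets[[t]]))  # subset of full universe
  }
  expect_error(build_model(p, n = 12, alpha = 0), "alpha")
  expect_error(build_model(p, n = 12, alpha = 1.2), "alpha")
  expect_error(build_model(p, n = 12, alpha = 0.5), "seed")
})

test_that("repeat ratios come from full genomes even in partial models", {
  p <- random_panel(3, 1000, seed = 12)
  full <- build_model(p, n = 12)
  part <- build_model(p, n = 12, alpha = 0.25, seed = 4)
  expect_identical(part$genomes$repeat_ratio, full$genomes$repeat_ratio)
  expect_identical(part$mu, full$mu)
})
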