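# fixtures and independent oracles shared across test files

# tiny deterministic panel: two genomes engineered to share exactly one
# 12-gram region and otherwise be disjoint is fiddly with random sequence,
# so toy panels are built from explicit sequences where needed and random
# panels from generate_panel() otherwise.
toy_panel <- function() {
  genome_panel(
    name = c("Alpha one strainA", "Beta two strainB"),
    sequence = c("ACGTACGTACGTACGT", "TTTTTTTTTTTTTTTT"),
    tag = c("ALP_ONE_A", "BET_TWO_B")
  )
}

# random small panel of independent genomes (no strain structure)
random_panel <- function(k, len, seed) {
  generate_panel(k, len, mutation_rate = 0.001, repeat_fraction = 0,
                 species_per_genus = 2L, seed = seed)
}

# per-genome distinct n-gram sets via the public API
genome_sets_of <- function(panel, n = 12) {
  tags <- unique(panel$tag)
  stats::setNames(lapply(tags, function(t)
    extract_ngrams(panel$sequence[panel$tag == t], n)$distinct), tags)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# pool of k distinct 3-letter codes
code3_pool <- function(k) vapply(seq_len(k), function(i)
  paste0(LETTERS[(i - 1) %/% 26 + 1], LETTERS[(i - 1) %% 26 + 1], "A"), character(1))

# ---- independent brute-force classification oracle ----------------------
# Dense-matrix implementation straight from the definition: build the
# (query n-grams x genomes) weight matrix and take column sums. Written
# against per-genome n-gram SETS, independent of the package's index/join
# machinery (only substring extraction is shared, by necessity).
oracle_sets <- function(panel, n) {
  tags <- unique(panel$tag)
  sets <- lapply(tags, function(t) {
    s <- panel$sequence[panel$tag == t]
    unique(unlist(lapply(s, function(x) {
      k <- nchar(x)
      if (k < n) character(0) else substring(x, 1:(k - n + 1), n:k)
    })))
  })
  names(sets) <- tags
  sets
}

oracle_classify <- function(query, sets) {
  q <- unique(query)
  C <- length(sets)
  inset <- vapply(sets, function(s) q %in% s, logical(length(q)))
  if (length(q) == 1) inset <- matrix(inset, nrow = 1, dimnames = list(NULL, names(sets)))
  m <- rowSums(inset)
  weight <- ifelse(m > 0, log(C / pmax(m, 1)) / log(C), 0)
  Y <- inset * weight          # weight if present, else 0
  scores <- colSums(Y)
  scores <- scores[colSums(inset) > 0]    # genomes with at least one hit
  ord <- order(-scores, names(scores))
  scores[ord]
}

# ---- shared full-scale benchmark (computed once per test run) ------------
# Study conditions: 50 genomes x 100 kb, 10 strain pairs at 0.1% divergence,
# repeat fraction 0.25, 100k reads of 100 bp, staggered truth in [0.1, 10]%.
benchmark_cache <- new.env(parent = emptyenv())
get_benchmark <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(benchmark_cache[[key]])) {
    benchmark_cache[[key]] <- run_staggered_benchmark(seed)
  }
  benchmark_cache[[key]]
}
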