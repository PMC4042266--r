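# n-gram extraction, unique/common profiling, dampening weights, model build

#' Extract all n-grams of a nucleotide sequence
#'
#' Sliding window of length `n`, step 1, over the forward strand; a sequence
#' of length k yields k - n + 1 n-grams. Ambiguity codes (N, R, Y, ...) are
#' literal characters of the alphabet and appear in n-grams verbatim.
#'
#' @param sequence upper-case nucleotide string.
#' @param n gram length (default 12).
#' @return list with `distinct` (character vector, first-occurrence order),
#'   `total` (k - n + 1) and `repeated` (total - number distinct). A sequence
#'   shorter than `n` gives `total = 0` and an empty set, never an error, so
#'   short reads cannot abort a run.
#' @examples
#' extract_ngrams("ACGTN", 3)
#' @export
extract_ngrams <- function(sequence, n = 12L) {
  stopifnot(n >= 1)
  g <- all_ngrams(sequence, n)
  d <- unique(g)
  list(distinct = d, total = length(g), repeated = length(g) - length(d))
}

# all n-grams (with repeats, in order); character(0) if too short
all_ngrams <- function(sequence, n) {
  k <- nchar(sequence)
  if (k < n) return(character(0))
  substring(sequence, 1:(k - n + 1L), n:k)
}

# n-grams of many reads at once -> data.table(rid, ngram)
# grouped by read length so substr() vectorises across reads
read_ngrams <- function(reads, n) {
  len <- nchar(reads)
  keep <- len >= n
  out <- vector("list", 0L)
  for (L in unique(len[keep])) {
    idx <- which(len == L & keep)
    per <- L - n + 1L
    chunks <- lapply(seq_len(per), function(j) substr(reads[idx], j, j + n - 1L))
    out[[length(out) + 1L]] <- data.table::data.table(
      rid = rep(idx, times = per),
      ngram = unlist(chunks, use.names = FALSE)
    )
  }
  if (length(out) == 0)
    return(data.table::data.table(rid = integer(0), ngram = character(0)))
  data.table::rbindlist(out)
}

#' Dampening weight for a shared n-gram
#'
#' The inverse-document-frequency style weight `log(C/m)/log(C)` for an
#' n-gram present in `m` of the `C` panel genomes: 1 when the n-gram is
#' unique to one genome, 0 when it occurs in every genome, strictly
#' decreasing in `m`. The ratio of logarithms makes the value independent of
#' the logarithm base.
#'
#' @param m number of genomes containing the n-gram (1..C).
#' @param C panel size (>= 2).
#' @param base logarithm base (result is base-invariant; exposed for the
#'   base-invariance property tests).
#' @return weight in `[0, 1]`, vectorised over `m`.
#' @examples
#' dampening_weight(1, 2031)   # 1
#' dampening_weight(2031, 2031)  # 0
#' dampening_weight(10, 100)   # 0.5
#' @export
dampening_weight <- function(m, C, base = exp(1)) {
  stopifnot(C >= 2)
  if (any(m < 1 | m > C)) stop("m must satisfy 1 <= m <= C")
  log(C / m, base = base) / log(C, base = base)
}

#' Unique/common n-gram profile of a genome panel
#'
#' Computes, for every genome, its distinct n-gram set size, total n-gram
#' count (length - n + 1, summed over replicons when pooling), repeated
#' n-gram count and repeat ratio (percent), plus the panel-level mean and
#' standard deviation of the repeat ratios used later by the abundance
#' correction.
#'
#' @param panel a [genome_panel()] with at least 2 genomes.
#' @param n gram length.
#' @param sigma_type `"population"` (default) or `"sample"` standard
#'   deviation of the repeat ratios.
#' @param pool_replicons treat rows sharing a tag as replicons of one genome
#'   (pooled n-grams); otherwise duplicate tags are an error.
#' @return an `ngram_profile`: list with `genomes` (data.table: tag, name,
#'   length, total, distinct, repeated, repeat_ratio), `mu`, `sigma`, `n`.
#' @export
build_profile <- function(panel, n = 12L, sigma_type = c("population", "sample"),
                          pool_replicons = FALSE) {
  sigma_type <- match.arg(sigma_type)
  if (anyDuplicated(panel$tag) && !pool_replicons)
    stop(sprintf("duplicate genome tag '%s' (use pool_replicons=TRUE for multi-replicon genomes)",
                 panel$tag[anyDuplicated(panel$tag)]))
  tags <- unique(panel$tag)
  if (length(tags) < 2) stop("a panel needs at least 2 genomes")

  rows <- lapply(tags, function(t) {
    seqs <- panel$sequence[panel$tag == t]
    grams <- unlist(lapply(seqs, all_ngrams, n = n), use.names = FALSE)
    d <- unique(grams)
    data.table::data.table(
      tag = t, name = panel$name[panel$tag == t][1],
      length = sum(nchar(seqs)),
      total = length(grams), distinct = length(d),
      repeated = length(grams) - length(d),
      repeat_ratio = if (length(grams) > 0) 100 * (length(grams) - length(d)) / length(grams) else NA_real_
    )
  })
  genomes <- data.table::rbindlist(rows)
  rr <- genomes$repeat_ratio
  mu <- mean(rr)
  sigma <- if (sigma_type == "population") {
    sqrt(mean((rr - mu)^2))
  } else {
    stats::sd(rr)
  }
  structure(list(genomes = genomes, mu = mu, sigma = sigma, n = as.integer(n),
                 sigma_type = sigma_type),
            class = "ngram_profile")
}

#' @export
print.ngram_profile <- function(x, ...) {
  cat(sprintf("ngram_profile (n=%d): %d genomes; repeat ratio mu=%.2f%% sigma=%.2f%% (%s)\n",
              x$n, nrow(x$genomes), x$mu, x$sigma, x$sigma_type))
  print(x$genomes, ...)
  invisible(x)
}

new_ngram_model <- function(n, C, alpha, seed, genomes, mu, sigma, sigma_type,
                            index, membership) {
  data.table::setkey(index, ngram)
  data.table::setkey(membership, ngram)
  structure(list(n = n, C = C, alpha = alpha, seed = seed, genomes = genomes,
                 mu = mu, sigma = sigma, sigma_type = sigma_type,
                 index = index, membership = membership),
            class = "ngram_model")
}

#' Build the weighted n-gram index over a genome panel
#'
#' Each genome contributes its distinct (non-repeated) n-grams — all of them
#' at `alpha = 1`, or a seeded random sample of `round(alpha * distinct)` of
#' them for partial models emulating incompletely sequenced genomes. Every
#' n-gram in the resulting universe is weighted by [dampening_weight()] of
#' its member-genome count; n-grams unique to one genome get weight 1.
#' Repeat ratios (and their panel mean/sd) are always computed from the full
#' genomes, since they are genome properties, not model properties.
#'
#' @inheritParams build_profile
#' @param alpha fraction of each genome's distinct n-grams indexed, in (0, 1].
#' @param seed RNG seed; required when `alpha < 1`.
#' @param drop_ambiguous drop n-grams containing non-ACGT characters.
#' @return an `ngram_model`: list with `n`, `C`, `alpha`, `seed`, `genomes`
#'   (per-genome statistics incl. repeat ratio), `mu`, `sigma`, `index`
#'   (data.table ngram, m, weight keyed by ngram) and `membership`
#'   (data.table ngram, tag keyed by ngram).
#' @export
build_model <- function(panel, n = 12L, alpha = 1, seed = NULL,
                        sigma_type = c("population", "sample"),
                        pool_replicons = FALSE, drop_ambiguous = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (alpha < 1 && is.null(seed)) stop("a seed is required when alpha < 1")
  sigma_type <- match.arg(sigma_type)
  prof <- build_profile(panel, n = n, sigma_type = sigma_type,
                        pool_replicons = pool_replicons)
  tags <- prof$genomes$tag

  memb <- lapply(seq_along(tags), function(i) {
    t <- tags[i]
    seqs <- panel$sequence[panel$tag == t]
    d <- unique(unlist(lapply(seqs, all_ngrams, n = n), use.names = FALSE))
    if (drop_ambiguous) d <- d[!grepl("[^ACGT]", d)]
    if (alpha < 1) {
      take <- round(alpha * length(d))
      d <- with_seed(child_seed(seed, i), sample(d, take))
    }
    data.table::data.table(ngram = d, tag = t)
  })
  membership <- data.table::rbindlist(memb)
  index <- membership[, list(m = .N), by = "ngram"]
  index[, weight := dampening_weight(m, length(tags))]
  new_ngram_model(n = as.integer(n), C = length(tags), alpha = alpha,
                  seed = seed, genomes = prof$genomes, mu = prof$mu,
                  sigma = prof$sigma, sigma_type = sigma_type,
                  index = index, membership = membership)
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("ngram_model: n=%d, C=%d genomes, alpha=%g%s\n", x$n, x$C,
              x$alpha, if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)))
  cat(sprintf("  %s indexed n-grams: %s unique (weight 1), %s common\n",
              format(nrow(x$index), big.mark = ","),
              format(sum(x$index$m == 1L), big.mark = ","),
              format(sum(x$index$m > 1L), big.mark = ",")))
  cat(sprintf("  panel repeat ratio: mu=%.2f%%, sigma=%.2f%% (%s sd)\n",
              x$mu, x$sigma, x$sigma_type))
  invisible(x)
}
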