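# relative abundance: intersection counts -> observed -> corrected -> estimated

#' Count read/genome n-gram intersections
#'
#' For each read the distinct n-grams are matched against the reference
#' genome's indexed n-gram set. By default (`per_read = TRUE`) matches are
#' summed over reads, so the count grows linearly with sequencing depth and
#' hence with the genome's relative abundance. `per_read = FALSE` instead
#' counts the pooled set intersection (distinct read n-grams ∩ genome
#' n-grams); that quantity saturates at the genome's distinct n-gram count
#' once coverage approaches 1x and is kept only for comparison.
#'
#' @param reads character vector of reads from one genome.
#' @param model an `ngram_model`.
#' @param tag genome tag to count against.
#' @param per_read sum per-read distinct matches (default) or pooled-set
#'   intersection.
#' @param both_strands also match reverse complements of read n-grams.
#' @return integer count.
#' @export
count_intersections <- function(reads, model, tag, per_read = TRUE,
                                both_strands = TRUE) {
  stopifnot(inherits(model, "ngram_model"))
  if (!tag %in% model$genomes$tag) stop(sprintf("tag '%s' not in model", tag))
  gset <- model$membership[tag, on = "tag", ngram]
  rn <- read_ngrams(reads, model$n)
  if (nrow(rn) == 0) return(0L)
  rn <- unique(rn)                      # distinct n-grams within each read
  hit <- rn$ngram %chin% gset
  if (both_strands) {
    miss <- which(!hit)
    rc <- revcomp(rn$ngram[miss])
    hit[miss[!is.na(rc) & rc %chin% gset]] <- TRUE
  }
  if (per_read) sum(hit) else length(unique(rn$ngram[hit]))
}

#' Observed relative abundance from intersection counts
#'
#' `observed_i = (count_i / sum_j count_j) * k`, with `k` the number of
#' genomes in the community, so a perfectly even community has observed
#' abundance 1 for every genome. The alternative literal denominator (sum of
#' the genomes' own distinct n-gram set sizes) is available via
#' `denominator = "genome_sets"` together with `set_sizes`.
#'
#' @param intersections named numeric vector tag -> intersection count.
#' @param k number of genomes (defaults to `length(intersections)`).
#' @param denominator `"intersections"` (default) or `"genome_sets"`.
#' @param set_sizes named vector of genome distinct n-gram set sizes,
#'   required for `denominator = "genome_sets"`.
#' @return named numeric vector of observed abundances summing to `k` (under
#'   the default denominator).
#' @export
observed_abundance <- function(intersections, k = length(intersections),
                               denominator = c("intersections", "genome_sets"),
                               set_sizes = NULL) {
  denominator <- match.arg(denominator)
  if (k < 1) stop("k must be >= 1")
  if (any(intersections < 0)) stop("intersection counts must be >= 0")
  if (all(intersections == 0)) stop("no genome detected (all intersection counts are zero)")
  denom <- if (denominator == "intersections") {
    sum(intersections)
  } else {
    if (is.null(set_sizes)) stop("set_sizes required for denominator='genome_sets'")
    sum(set_sizes[names(intersections)])
  }
  intersections / denom * k
}

#' Repeat-ratio correction of observed abundances
#'
#' Genomes with extreme repeat ratios are systematically over-estimated
#' (ratio above 50%) or under-estimated (below 15%), so a repeat-dependent
#' offset `log10(RR) / denom` is subtracted from the observed abundance,
#' where `denom` is the panel mean `mu` of repeat ratios for
#' 15 < RR < 50, `mu - sigma` for RR > 50 and `mu + sigma` for RR < 15.
#' The boundary values RR = 15 and RR = 50 use `mu`. `mu` and `sigma` are
#' always those of the current panel — they change whenever genomes are
#' added or removed.
#'
#' @param observed numeric vector of observed abundances.
#' @param repeat_ratio percent repeat ratio per genome (> 0).
#' @param mu panel mean repeat ratio (> 0).
#' @param sigma panel standard deviation of repeat ratios (>= 0).
#' @return numeric vector of corrected abundances (may be negative for tiny
#'   observed values; [estimated_abundance()] clamps).
#' @examples
#' corrected_abundance(1, 30, 27.57, 12.52)  # mu branch
#' @export
corrected_abundance <- function(observed, repeat_ratio, mu, sigma) {
  stopifnot(length(observed) == length(repeat_ratio))
  if (any(repeat_ratio <= 0)) stop("repeat_ratio must be > 0")
  if (mu <= 0) stop("mu must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  denom <- rep(mu, length(repeat_ratio))
  denom[repeat_ratio > 50] <- mu - sigma
  denom[repeat_ratio < 15] <- mu + sigma
  if (any(repeat_ratio > 50) && mu - sigma <= 0)
    stop("degenerate panel: mu - sigma <= 0 with a repeat ratio above 50%")
  observed - log10(repeat_ratio) / denom
}

#' Normalize corrected abundances to percentages
#'
#' Negative corrected values are clamped to 0, then all values are scaled so
#' their sum equals `target` — 100 for percentages, or the number of species
#' for the per-species convention.
#'
#' @param corrected named numeric vector of corrected abundances.
#' @param target normalization target (default 100).
#' @return named numeric vector summing to `target`.
#' @export
estimated_abundance <- function(corrected, target = 100) {
  x <- pmax(corrected, 0)
  s <- sum(x)
  if (s <= 0) stop("all corrected abundances are <= 0; nothing to normalize")
  x / s * target
}

#' Full abundance pipeline for truth-grouped read sets
#'
#' Runs intersection counting, observed abundance, repeat-ratio correction
#' and normalization for a mock community whose reads are grouped by source
#' genome. Genomes whose repeat ratio is exactly 0 (possible only for tiny
#' toy sequences) take zero correction, since there are no repeats to
#' correct for and log10(0) is undefined.
#'
#' @param read_sets named list: genome tag -> character vector of reads.
#' @param model an `ngram_model`.
#' @param target normalization target (100, or the number of species).
#' @param per_read,both_strands see [count_intersections()].
#' @return an `abundance_table`: data.table with columns `tag`,
#'   `intersection_count`, `repeat_ratio`, `observed`, `corrected`,
#'   `estimated`, with attributes `mu`, `sigma`, `target`.
#' @export
abundance_table <- function(read_sets, model, target = 100, per_read = TRUE,
                            both_strands = TRUE) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  tags <- names(read_sets)
  counts <- vapply(tags, function(t) {
    as.numeric(count_intersections(read_sets[[t]], model, t,
                                   per_read = per_read,
                                   both_strands = both_strands))
  }, numeric(1))
  rr <- model$genomes$repeat_ratio[match(tags, model$genomes$tag)]
  obs <- observed_abundance(counts, k = length(tags))
  corr <- obs
  pos <- rr > 0
  corr[pos] <- corrected_abundance(obs[pos], rr[pos], model$mu, model$sigma)
  est <- estimated_abundance(corr, target = target)
  out <- data.table::data.table(tag = tags, intersection_count = counts,
                                repeat_ratio = rr, observed = obs,
                                corrected = corr, estimated = est)
  data.table::setattr(out, "mu", model$mu)
  data.table::setattr(out, "sigma", model$sigma)
  data.table::setattr(out, "target", target)
  data.table::setattr(out, "class", c("abundance_table", class(out)))
  out[]
}
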