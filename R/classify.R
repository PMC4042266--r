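# weighted column-sum classification of n-gram sets

#' Classify a set of n-grams against a weighted model
#'
#' Conceptually an (n-grams x genomes) matrix is formed whose entry is the
#' n-gram's weight if the genome contains it and 0 otherwise; each genome's
#' score is its column sum and the set is assigned to the genome with the
#' highest score. The implementation computes the identical quantity by a
#' keyed join on the sparse membership table. Query n-grams are collapsed to
#' a set before scoring, so read-derived duplicates are not double counted.
#' N-grams absent from the model contribute nothing.
#'
#' With `both_strands = TRUE` (default) each query n-gram is looked up as-is
#' and as its reverse complement, and per genome the higher-weighted
#' orientation counts; ambiguity-containing n-grams are looked up as-is only.
#' Set `both_strands = FALSE` for the literal forward-only scheme.
#'
#' @param query_ngrams character vector of n-grams (deduplicated internally).
#' @param model an `ngram_model` from [build_model()] or [read_model()].
#' @param both_strands also look up reverse complements.
#' @return an `identification`: list with `ranking` (data.table tag, score,
#'   sorted by score descending, ties broken lexicographically by tag),
#'   `predicted` (top tag, or `NA` when nothing matched), `margin` (top score
#'   minus runner-up), `tie` (top two scores equal — callers should treat a
#'   tie as a misprediction) and `unclassifiable`.
#' @export
classify_set <- function(query_ngrams, model, both_strands = TRUE) {
  stopifnot(inherits(model, "ngram_model"))
  if (length(query_ngrams) == 0) stop("query must be non-empty")
  q <- unique(query_ngrams)
  lk <- data.table::data.table(qid = seq_along(q), ngram = q)
  if (both_strands) {
    rc <- revcomp(q)
    ok <- !is.na(rc) & rc != q
    if (any(ok)) {
      lk <- data.table::rbindlist(list(
        lk, data.table::data.table(qid = which(ok), ngram = rc[ok])))
    }
  }
  hits <- model$membership[lk, on = "ngram", nomatch = 0L]
  if (nrow(hits) == 0) {
    return(structure(list(
      ranking = data.table::data.table(tag = character(0), score = numeric(0)),
      predicted = NA_character_, margin = NA_real_, tie = FALSE,
      unclassifiable = TRUE, n_query = length(q)), class = "identification"))
  }
  hits <- model$index[, list(ngram, weight)][hits, on = "ngram"]
  # per (query n-gram, genome): best orientation only
  per <- hits[, list(w = max(weight)), by = c("qid", "tag")]
  ranking <- per[, list(score = sum(w)), by = "tag"]
  data.table::setorder(ranking, -score, tag)
  tie <- nrow(ranking) > 1 && ranking$score[1] == ranking$score[2]
  margin <- if (nrow(ranking) > 1) ranking$score[1] - ranking$score[2] else ranking$score[1]
  structure(list(ranking = ranking, predicted = ranking$tag[1],
                 margin = margin, tie = tie, unclassifiable = FALSE,
                 n_query = length(q)),
            class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  if (x$unclassifiable) {
    cat("identification: unclassifiable (no query n-gram found in the model)\n")
    return(invisible(x))
  }
  cat(sprintf("identification: %s (margin %.4g%s) from %d query n-grams\n",
              x$predicted, x$margin, if (x$tie) ", TIE" else "", x$n_query))
  print(utils::head(x$ranking, 10), ...)
  invisible(x)
}

#' Sample a test fraction of a genome's n-grams
#'
#' Implements the 1/3/5/7% test-sampling protocol: `round(fraction * |set|)`
#' n-grams drawn without replacement, reproducibly under `seed`. Any
#' fraction in (0, 1] is accepted.
#'
#' @param ngrams character vector (a genome's distinct n-gram set).
#' @param fraction sampling fraction in (0, 1].
#' @param seed RNG seed.
#' @return character vector of sampled n-grams.
#' @export
sample_test_ngrams <- function(ngrams, fraction, seed = NULL) {
  if (length(ngrams) == 0) stop("cannot sample from an empty n-gram set")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(ngrams)
  with_seed(seed, sample(ngrams, round(fraction * length(ngrams))))
}

#' Classify several read sets, one per source genome
#'
#' The faithful operating mode of the method: reads arrive already grouped
#' into per-genome sets (as in a mock community with known truth) and each
#' whole set is mapped to one genome. Per-read classification of a mixed
#' sample is available via [classify_reads()] but is an extension beyond the
#' set-level scheme.
#'
#' @param read_sets named list: group label -> character vector of reads.
#' @param model an `ngram_model`.
#' @param both_strands see [classify_set()].
#' @return data.table with columns `set` (group label), `predicted`, `score`,
#'   `margin`, `tie`, `unclassifiable`.
#' @export
classify_read_sets <- function(read_sets, model, both_strands = TRUE) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  rows <- lapply(names(read_sets), function(lbl) {
    grams <- unique(read_ngrams(read_sets[[lbl]], model$n)$ngram)
    if (length(grams) == 0) {
      return(data.table::data.table(set = lbl, predicted = NA_character_,
                                    score = NA_real_, margin = NA_real_,
                                    tie = FALSE, unclassifiable = TRUE))
    }
    r <- classify_set(grams, model, both_strands = both_strands)
    data.table::data.table(set = lbl, predicted = r$predicted,
                           score = if (r$unclassifiable) NA_real_ else r$ranking$score[1],
                           margin = r$margin, tie = r$tie,
                           unclassifiable = r$unclassifiable)
  })
  data.table::rbindlist(rows)
}

#' Per-read classification (extension)
#'
#' Classifies every read independently by its own n-gram set. Single short
#' reads carry little discriminatory signal, which is why the set-level
#' [classify_read_sets()] is the primary mode; this helper exists for mixed
#' samples without prior grouping.
#'
#' @param reads named character vector of reads.
#' @param model an `ngram_model`.
#' @param both_strands see [classify_set()].
#' @return data.table `read`, `predicted`, `margin`, `tie`, `unclassifiable`.
#' @export
classify_reads <- function(reads, model, both_strands = TRUE) {
  ids <- names(reads) %||% as.character(seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    grams <- all_ngrams(reads[[i]], model$n)
    if (length(grams) == 0) {
      return(data.table::data.table(read = ids[i], predicted = NA_character_,
                                    margin = NA_real_, tie = FALSE,
                                    unclassifiable = TRUE))
    }
    r <- classify_set(grams, model, both_strands = both_strands)
    data.table::data.table(read = ids[i], predicted = r$predicted,
                           margin = r$margin, tie = r$tie,
                           unclassifiable = r$unclassifiable)
  })
  data.table::rbindlist(rows)
}
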