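# evaluation: per-level accuracy, balanced accuracy, cross-validation,
# partial-model (alpha) experiments, and the staggered-community benchmark

TAG_RE <- "^[A-Z]{3}_[A-Z]{3}_"

#' Classification accuracy at a taxonomic level
#'
#' Tags encode the hierarchy positionally, so matching is by prefix: first
#' 3 characters for genus, first 7 (`GGG_SSS`) for species, the full tag
#' for strain. `NA` predictions and classifier ties count as incorrect.
#'
#' @param truth,predicted equal-length character vectors of tags
#'   (`predicted` may contain `NA`).
#' @param level `"genus"`, `"species"` or `"strain"`.
#' @param tie optional logical vector; `TRUE` entries count as incorrect.
#' @return accuracy in percent.
#' @export
accuracy_at_level <- function(truth, predicted, level = c("strain", "species", "genus"),
                              tie = NULL) {
  level <- match.arg(level)
  stopifnot(length(truth) == length(predicted))
  bad <- which(!grepl(TAG_RE, truth))
  if (length(bad))
    stop(sprintf("malformed truth tag at entry %d: '%s'", bad[1], truth[bad[1]]))
  bad <- which(!is.na(predicted) & !grepl(TAG_RE, predicted))
  if (length(bad))
    stop(sprintf("malformed predicted tag at entry %d: '%s'", bad[1], predicted[bad[1]]))
  width <- switch(level, genus = 3L, species = 7L, strain = NA_integer_)
  ok <- if (is.na(width)) !is.na(predicted) & truth == predicted
        else !is.na(predicted) & substr(truth, 1, width) == substr(predicted, 1, width)
  if (!is.null(tie)) ok <- ok & !tie
  100 * mean(ok)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' `100 * (sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return percent.
#' @examples
#' balanced_accuracy(0.41, 0.87)  # 64
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  100 * (sensitivity + specificity) / 2
}

#' Per-level evaluation report with optional abundance deviations
#'
#' @param truth,predicted tag vectors (see [accuracy_at_level()]).
#' @param tie optional tie flags from the classifier.
#' @param truth_abundance,estimated_abundance optional numeric vectors
#'   (percent) aligned with `truth` for the deviation table.
#' @return an `evaluation_report`: list with `accuracy` (named percent
#'   vector: genus, species, strain), `confusion` (data.table truth,
#'   predicted for mismatched strains) and `deviation` (data.table truth
#'   tag, truth %, estimated %, relative deviation %) or `NULL`.
#' @export
evaluation_report <- function(truth, predicted, tie = NULL,
                              truth_abundance = NULL, estimated_abundance = NULL) {
  acc <- c(genus = accuracy_at_level(truth, predicted, "genus", tie),
           species = accuracy_at_level(truth, predicted, "species", tie),
           strain = accuracy_at_level(truth, predicted, "strain", tie))
  wrong <- which(is.na(predicted) | truth != predicted)
  confusion <- data.table::data.table(truth = truth[wrong], predicted = predicted[wrong])
  deviation <- NULL
  if (!is.null(truth_abundance)) {
    stopifnot(length(truth_abundance) == length(truth),
              length(estimated_abundance) == length(truth))
    deviation <- data.table::data.table(
      tag = truth, truth = truth_abundance, estimated = estimated_abundance,
      rel_dev = 100 * (estimated_abundance - truth_abundance) / truth_abundance)
  }
  structure(list(accuracy = acc, confusion = confusion, deviation = deviation),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("accuracy: genus %.2f%% | species %.2f%% | strain %.2f%%\n",
              x$accuracy["genus"], x$accuracy["species"], x$accuracy["strain"]))
  if (nrow(x$confusion)) {
    cat(sprintf("%d misprediction(s):\n", nrow(x$confusion)))
    print(x$confusion, ...)
  }
  if (!is.null(x$deviation)) {
    cat(sprintf("abundance deviation: median |rel dev| %.1f%%, max %.1f%%\n",
                stats::median(abs(x$deviation$rel_dev)), max(abs(x$deviation$rel_dev))))
  }
  invisible(x)
}

#' Cross-validation by repeated query sub-sampling
#'
#' For each fold an independent seeded sample of `test_fraction` of every
#' genome's distinct n-grams is drawn and classified against the model built
#' from the full panel; strain-level accuracy is reported per fold and
#' averaged. (Folding over genomes would leave test genomes without a class
#' in the model, so folds here are repeated random query draws, consistent
#' with the 1/3/5/7% test-sampling protocol.)
#'
#' @param panel a [genome_panel()].
#' @param n gram length.
#' @param folds number of folds (>= 2).
#' @param test_fraction query sampling fraction in (0, 1].
#' @param seed RNG seed.
#' @param alpha model build fraction (see [build_model()]).
#' @param both_strands see [classify_set()].
#' @return list with `folds` (data.table fold, accuracy) and `mean_accuracy`.
#' @export
cross_validate <- function(panel, n = 12L, folds = 10L, test_fraction = 0.01,
                           seed = NULL, alpha = 1, both_strands = FALSE) {
  if (folds < 2) stop("folds must be >= 2")
  if (test_fraction <= 0 || test_fraction > 1) stop("test_fraction must lie in (0, 1]")
  if (length(unique(panel$tag)) < folds) stop("panel must have at least `folds` genomes")
  model <- build_model(panel, n = n, alpha = alpha,
                       seed = if (alpha < 1) child_seed(seed, 0L) else NULL)
  sets <- genome_ngram_sets(panel, n)
  acc <- vapply(seq_len(folds), function(f) {
    pred <- vapply(seq_along(sets), function(i) {
      q <- sample_test_ngrams(sets[[i]], test_fraction,
                              seed = child_seed(seed, f * 1000L + i))
      r <- classify_set(q, model, both_strands = both_strands)
      if (r$tie || r$unclassifiable) NA_character_ else r$predicted
    }, character(1))
    accuracy_at_level(names(sets), pred, "strain")
  }, numeric(1))
  list(folds = data.table::data.table(fold = seq_len(folds), accuracy = acc),
       mean_accuracy = mean(acc))
}

# named list tag -> distinct n-gram set
genome_ngram_sets <- function(panel, n) {
  tags <- unique(panel$tag)
  stats::setNames(lapply(tags, function(t) {
    unique(unlist(lapply(panel$sequence[panel$tag == t], all_ngrams, n = n),
                  use.names = FALSE))
  }), tags)
}

#' Partial-model (alpha::beta) degradation experiment
#'
#' Builds one model per `alpha` (fraction of each genome's n-grams indexed)
#' and classifies, for every genome and replicate, a fresh sample of
#' `test_fraction` of the full genome's n-grams. Mirrors the
#' partial-genome analysis: accuracy should be non-increasing as alpha
#' shrinks.
#'
#' @param panel a [genome_panel()].
#' @param n gram length.
#' @param alphas model build fractions, tested in the given order.
#' @param test_fraction query sampling fraction (beta protocol).
#' @param reps query replicates per alpha.
#' @param seed RNG seed.
#' @param both_strands see [classify_set()].
#' @return list with `runs` (data.table alpha, rep, accuracy) and `summary`
#'   (data.table alpha, mean_accuracy, ordered as given).
#' @export
alpha_beta_experiment <- function(panel, n = 12L,
                                  alphas = c(1, 0.75, 0.5, 0.25),
                                  test_fraction = 0.01, reps = 10L,
                                  seed = NULL, both_strands = FALSE) {
  sets <- genome_ngram_sets(panel, n)
  runs <- list()
  for (ai in seq_along(alphas)) {
    a <- alphas[ai]
    model <- build_model(panel, n = n, alpha = a,
                         seed = if (a < 1) child_seed(seed, ai) else NULL)
    for (r in seq_len(reps)) {
      pred <- vapply(seq_along(sets), function(i) {
        q <- sample_test_ngrams(sets[[i]], test_fraction,
                                seed = child_seed(seed, ai * 100000L + r * 100L + i))
        cls <- classify_set(q, model, both_strands = both_strands)
        if (cls$tie || cls$unclassifiable) NA_character_ else cls$predicted
      }, character(1))
      runs[[length(runs) + 1L]] <- data.table::data.table(
        alpha = a, rep = r,
        accuracy = accuracy_at_level(names(sets), pred, "strain"))
    }
  }
  runs <- data.table::rbindlist(runs)
  summary <- runs[, list(mean_accuracy = mean(accuracy)), by = "alpha"]
  list(runs = runs, summary = summary)
}

#' End-to-end staggered mock-community benchmark
#'
#' The package's reference experiment: generate a synthetic panel with
#' strain pairs, build the full model, simulate a staggered community with
#' the default error model, classify every genome's read set as a whole,
#' and estimate abundances. Defaults follow the package's study conditions:
#' 50 genomes of 100 kb (10 strain pairs at 0.1% divergence + 30
#' singletons, repeat fraction 0.25), n = 12, 100,000 reads of 100 bp,
#' staggered truth abundances log-uniform in [0.1%, 10%].
#'
#' @param seed RNG seed driving panel, abundances and reads.
#' @param n_genomes,genome_length,n_strain_pairs,mutation_rate,repeat_fraction
#'   panel parameters (see [generate_panel()]).
#' @param total_reads,read_length simulation size.
#' @param n gram length.
#' @param abundance_range staggered truth range in percent.
#' @return list with `model`, `truth` (data.table tag, abundance),
#'   `classification` (data.table from [classify_read_sets()]),
#'   `strain_accuracy` (percent of read sets assigned to the right strain),
#'   `abundance` (abundance_table merged with truth and relative
#'   deviation), and `report` (an [evaluation_report()]).
#' @export
run_staggered_benchmark <- function(seed,
                                    n_genomes = 50L, genome_length = 100000L,
                                    n_strain_pairs = 10L, mutation_rate = 0.001,
                                    repeat_fraction = 0.25,
                                    total_reads = 100000L, read_length = 100L,
                                    n = 12L, abundance_range = c(0.1, 10)) {
  groups <- c(rep(2L, n_strain_pairs), rep(1L, n_genomes - 2L * n_strain_pairs))
  panel <- generate_panel(n_genomes, genome_length, strain_groups = groups,
                          mutation_rate = mutation_rate,
                          repeat_fraction = repeat_fraction,
                          seed = child_seed(seed, 1L))
  model <- build_model(panel, n = n)
  ab <- staggered_abundances(length(panel$tag), abundance_range[1],
                             abundance_range[2], seed = child_seed(seed, 2L))
  truth <- data.table::data.table(tag = panel$tag, abundance = ab)
  spec <- community_spec(data.frame(tag = truth$tag, abundance = truth$abundance),
                         total_reads = total_reads, read_length = read_length,
                         seed = child_seed(seed, 3L))
  reads <- simulate_reads(panel, spec)
  read_sets <- split(reads$sequence, reads$tag)
  read_sets <- read_sets[truth$tag]   # keep panel order

  cls <- classify_read_sets(read_sets, model)
  pred <- cls$predicted
  pred[cls$tie] <- NA_character_
  strain_accuracy <- accuracy_at_level(cls$set, pred, "strain")

  abt <- abundance_table(read_sets, model, target = 100)
  abt <- merge(abt, truth, by = "tag", sort = FALSE)
  abt[, rel_dev := 100 * (estimated - abundance) / abundance]

  report <- evaluation_report(cls$set, pred,
                              truth_abundance = abt$abundance[match(cls$set, abt$tag)],
                              estimated_abundance = abt$estimated[match(cls$set, abt$tag)])
  list(model = model, truth = truth, classification = cls,
       strain_accuracy = strain_accuracy, abundance = abt, report = report,
       seed = seed)
}
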