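# synthetic genome panels and mock-community read simulation

#' Generate a synthetic genome panel with strain structure and repeats
#'
#' Emulates the salient features of a bacterial reference panel at a
#' controllable scale: strain groups share a species backbone and differ
#' only by point mutations at `mutation_rate` (strain-level divergence);
#' a `repeat_fraction` of each backbone is built from tandem or dispersed
#' copies of internal segments, so genome repeat ratios can be steered over
#' the range seen in real panels; tags follow the `GGG_SSS_strain` scheme
#' with consecutive species grouped into genera.
#'
#' The first strain of a group is the backbone itself; each further strain
#' carries independent point mutations, so two sibling strains diverge at
#' about `mutation_rate` (vs the backbone) to `2 * mutation_rate` (between
#' two mutated siblings).
#'
#' @param num_genomes total genomes.
#' @param genome_length bases per genome.
#' @param strain_groups integer vector of group sizes summing to
#'   `num_genomes`; default all singletons.
#' @param mutation_rate per-base substitution rate within a strain group,
#'   in (0, 0.2].
#' @param repeat_fraction fraction of each genome built from internal
#'   segment copies; scalar or one value per strain group.
#' @param species_per_genus consecutive species sharing a genus code.
#' @param seed RNG seed (panel generation is fully deterministic under it).
#' @return a [genome_panel()].
#' @export
generate_panel <- function(num_genomes, genome_length,
                           strain_groups = NULL, mutation_rate = 0.001,
                           repeat_fraction = 0.25, species_per_genus = 2L,
                           seed = NULL) {
  stopifnot(num_genomes >= 1, genome_length >= 1)
  if (mutation_rate <= 0 || mutation_rate > 0.2)
    stop("mutation_rate must lie in (0, 0.2]")
  if (any(repeat_fraction < 0) || any(repeat_fraction >= 1))
    stop("repeat_fraction must lie in [0, 1)")
  strain_groups <- strain_groups %||% rep(1L, num_genomes)
  if (sum(strain_groups) != num_genomes)
    stop("strain_groups must sum to num_genomes")
  repeat_fraction <- rep_len(repeat_fraction, length(strain_groups))

  with_seed(seed, {
    name <- tag <- sequence <- character(0)
    for (sp in seq_along(strain_groups)) {
      backbone <- repeat_expanded_sequence(genome_length, repeat_fraction[sp])
      genus <- (sp - 1L) %/% species_per_genus + 1L
      for (st in seq_len(strain_groups[sp])) {
        s <- if (st == 1L) backbone else point_mutate(backbone, mutation_rate)
        tag <- c(tag, sprintf("%s_%s_S%d", code3(genus), code3(sp), st))
        name <- c(name, sprintf("Genus%d species%d strain S%d", genus, sp, st))
        sequence <- c(sequence, s)
      }
    }
    genome_panel(name = name, sequence = sequence, tag = tag)
  })
}

# random sequence of total length L in which ~frac of the bases come from
# copied internal segments (half tandem duplications, half dispersed copies)
repeat_expanded_sequence <- function(L, frac) {
  core_len <- max(1L, round(L * (1 - frac)))
  s <- random_dna(core_len)
  while (nchar(s) < L) {
    seg_len <- min(L - nchar(s), sample(500:2000, 1))
    if (seg_len >= nchar(s)) seg_len <- max(1L, nchar(s) - 1L)
    src <- sample.int(nchar(s) - seg_len + 1L, 1)
    seg <- substr(s, src, src + seg_len - 1L)
    if (stats::runif(1) < 0.5) {
      # tandem: duplicate in place
      s <- paste0(substr(s, 1, src + seg_len - 1L), seg,
                  substr(s, src + seg_len, nchar(s)))
    } else {
      # dispersed: insert a copy elsewhere
      at <- sample.int(nchar(s) + 1L, 1)
      s <- paste0(substr(s, 1, at - 1L), seg, substr(s, at, nchar(s)))
    }
  }
  substr(s, 1, L)
}

# independent point substitutions at the given per-base rate
point_mutate <- function(sequence, rate) {
  L <- nchar(sequence)
  pos <- which(stats::runif(L) < rate)
  if (length(pos) == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

#' Draw a staggered abundance profile
#'
#' Log-uniform draws on `[lo, hi]` percent (the standard staggered-mock
#' profile, spanning the abundance range on a log scale), rescaled to sum to
#' 100 with values clipped to stay inside `[lo, hi]`.
#'
#' @param k number of community members.
#' @param lo,hi abundance range in percent.
#' @param seed RNG seed.
#' @return numeric vector of length `k` summing to 100.
#' @export
staggered_abundances <- function(k, lo = 0.1, hi = 10, seed = NULL) {
  stopifnot(k >= 2, lo > 0, hi > lo, k * lo <= 100, k * hi >= 100)
  with_seed(seed, {
    a <- exp(stats::runif(k, log(lo), log(hi)))
    for (it in 1:100) {
      a <- a / sum(a) * 100
      if (all(a >= lo & a <= hi)) break
      fixed <- a < lo | a > hi
      a[a < lo] <- lo
      a[a > hi] <- hi
      rem <- 100 - sum(a[fixed])
      a[!fixed] <- a[!fixed] / sum(a[!fixed]) * rem
    }
    a
  })
}

#' Specify a mock community for read simulation
#'
#' @param members data.frame with columns `tag` and `abundance` (percent;
#'   must sum to 100 within 1e-9).
#' @param total_reads total number of reads (or read pairs when `paired`).
#' @param read_length read length in bases (default 100).
#' @param paired emit mate pairs.
#' @param insert_size fragment length for paired simulation.
#' @param sub_rate_start,sub_rate_end per-base substitution error rate at
#'   the first and last read position; the rate ramps linearly along the
#'   read (Illumina-like; defaults 0.1% to 1%).
#' @param ins_rate,del_rate flat per-base insertion/deletion rates
#'   (defaults 0.01%).
#' @param strand draw each read's strand uniformly; `FALSE` = forward only.
#' @param weight_by_length expected read count proportional to
#'   abundance x genome length (copy-number semantics); `FALSE` =
#'   abundance only.
#' @param seed RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(members, total_reads, read_length = 100L,
                           paired = FALSE, insert_size = 300L,
                           sub_rate_start = 0.001, sub_rate_end = 0.01,
                           ins_rate = 1e-4, del_rate = 1e-4,
                           strand = TRUE, weight_by_length = TRUE,
                           seed = NULL) {
  stopifnot(is.data.frame(members), all(c("tag", "abundance") %in% names(members)))
  if (any(members$abundance <= 0)) stop("abundances must be > 0")
  if (abs(sum(members$abundance) - 100) > 1e-9)
    stop(sprintf("abundances must sum to 100 (got %.9f)", sum(members$abundance)))
  if (total_reads < 1) stop("total_reads must be >= 1")
  structure(list(members = members, total_reads = as.integer(total_reads),
                 read_length = as.integer(read_length), paired = paired,
                 insert_size = as.integer(insert_size),
                 sub_rate_start = sub_rate_start, sub_rate_end = sub_rate_end,
                 ins_rate = ins_rate, del_rate = del_rate, strand = strand,
                 weight_by_length = weight_by_length, seed = seed),
            class = "community_spec")
}

#' Simulate mock-community reads with truth labels
#'
#' Read counts per genome are multinomial with probabilities proportional to
#' abundance (times genome length under the default copy-number semantics).
#' Start positions are uniform, strands uniform when strand simulation is
#' on, and each read then passes through the error model: position-ramped
#' substitutions plus flat-rate insertions and deletions. Reads whose source
#' window would overrun the genome end are shifted back, treating genomes as
#' linear sequences.
#'
#' @param panel a [genome_panel()] containing every member tag.
#' @param spec a [community_spec()].
#' @return data.table with columns `read_id`, `tag` (truth label), `mate`
#'   (1/2; all 1 for single-end) and `sequence`, carrying the spec as
#'   attribute `spec`.
#' @export
simulate_reads <- function(panel, spec) {
  stopifnot(inherits(spec, "community_spec"))
  members <- spec$members
  missing <- setdiff(members$tag, panel$tag)
  if (length(missing))
    stop(sprintf("community members absent from panel: %s",
                 paste(missing, collapse = ", ")))
  glen <- panel$length[match(members$tag, panel$tag)]
  if (spec$read_length < 1) stop("read_length must be >= 1")
  if (any(glen < spec$read_length))
    stop("every member genome must be at least one read length long")

  with_seed(spec$seed, {
    w <- members$abundance * if (spec$weight_by_length) glen else 1
    counts <- as.vector(stats::rmultinom(1, spec$total_reads, w))
    out <- vector("list", nrow(members))
    serial <- 0L
    for (i in seq_len(nrow(members))) {
      nr <- counts[i]
      if (nr == 0) next
      g <- panel$sequence[match(members$tag[i], panel$tag)]
      frag_len <- if (spec$paired) min(spec$insert_size, nchar(g)) else spec$read_length
      start <- sample.int(nchar(g) - frag_len + 1L, nr, replace = TRUE)
      frags <- substr_many(g, start, frag_len)
      if (spec$strand) {
        flip <- stats::runif(nr) < 0.5
        frags[flip] <- revcomp_iupac(frags[flip])
      }
      if (spec$paired) {
        r1 <- substr(frags, 1L, spec$read_length)
        r2 <- revcomp_iupac(substr(frags, frag_len - spec$read_length + 1L, frag_len))
        ids <- sprintf("r%07d_%s", serial + seq_len(nr), members$tag[i])
        dt <- data.table::data.table(
          read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
          tag = members$tag[i],
          mate = rep(c(1L, 2L), each = nr),
          sequence = c(apply_errors(r1, spec), apply_errors(r2, spec)))
      } else {
        dt <- data.table::data.table(
          read_id = sprintf("r%07d_%s", serial + seq_len(nr), members$tag[i]),
          tag = members$tag[i], mate = 1L,
          sequence = apply_errors(frags, spec))
      }
      serial <- serial + nr
      out[[i]] <- dt
    }
    reads <- data.table::rbindlist(out)
    data.table::setattr(reads, "spec", spec)
    reads[]
  })
}

# vectorised fixed-width substrings of one long string
substr_many <- function(s, start, width) {
  substring(s, start, start + width - 1L)
}

# error model: substitutions at a linearly ramped per-position rate, then
# insertions/deletions at flat per-base rates (handled per affected read;
# indel-bearing reads are rare at the default 0.01% rates)
apply_errors <- function(reads, spec) {
  if (length(reads) == 0) return(reads)
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1)
  nr <- length(reads)
  rate <- if (L == 1) spec$sub_rate_start else
    spec$sub_rate_start + (spec$sub_rate_end - spec$sub_rate_start) *
      (seq_len(L) - 1) / (L - 1)

  # one long read-major character vector
  chars <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  hit <- which(stats::runif(nr * L) < rate[rep(seq_len(L), times = nr)])
  if (length(hit)) {
    repl <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {   # substitution must change the base
      repl[same] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  cols <- split(chars, rep(seq_len(L), times = nr))  # position-major lists
  out <- do.call(paste0, cols[order(as.integer(names(cols)))])

  n_indel <- stats::rbinom(nr, L, spec$ins_rate + spec$del_rate)
  for (r in which(n_indel > 0)) {
    s <- out[r]
    for (k in seq_len(n_indel[r])) {
      at <- sample.int(nchar(s), 1)
      if (stats::runif(1) < spec$ins_rate / (spec$ins_rate + spec$del_rate)) {
        s <- paste0(substr(s, 1, at), sample(c("A", "C", "G", "T"), 1),
                    substr(s, at + 1, nchar(s)))
      } else if (nchar(s) > 1) {
        s <- paste0(substr(s, 1, at - 1L), substr(s, at + 1, nchar(s)))
      }
    }
    out[r] <- s
  }
  out
}

#' Write simulated reads and their truth table to disk
#'
#' One reads file (FASTA or FASTQ by extension) and a tab-separated truth
#' table (`read_id`, `tag`) with a provenance header recording the seed.
#'
#' @param reads output of [simulate_reads()].
#' @param reads_path reads file (`.fa`, `.fasta`, `.fq`, `.fastq`).
#' @param truth_path truth TSV.
#' @export
write_simulated_reads <- function(reads, reads_path, truth_path) {
  spec <- attr(reads, "spec")
  write_reads(stats::setNames(reads$sequence, reads$read_id), reads_path)
  con <- file(truth_path, "w")
  on.exit(close(con))
  writeLines(c("# ngramid simulated read truth",
               sprintf("# seed=%s total_reads=%d read_length=%d",
                       spec$seed %||% "NA", spec$total_reads, spec$read_length),
               "read_id\ttag"), con)
  writeLines(paste0(reads$read_id, "\t", reads$tag), con)
  invisible(reads_path)
}
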