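#' Genome panel container
#'
#' A genome panel is a plain `data.frame` with one row per sequence record and
#' columns `name` (free-text organism name), `tag` (hierarchical
#' `GGG_SSS_strain` identifier), `sequence` (upper-case nucleotides over the
#' IUPAC alphabet) and `length`. Rows sharing a `tag` are interpreted as
#' replicons (chromosome + plasmids) of one genome by functions that accept
#' `pool_replicons = TRUE`.
#'
#' @param name character vector of organism names.
#' @param tag character vector of genome tags; defaults to [make_tag()] of
#'   `name`.
#' @param sequence character vector of nucleotide sequences.
#' @return a `genome_panel` data.frame.
#' @examples
#' genome_panel("Escherichia coli K-12", sequence = "ACGTACGT")
#' @export
genome_panel <- function(name, sequence, tag = vapply(name, make_tag, character(1))) {
  stopifnot(length(name) == length(sequence), length(tag) == length(sequence))
  sequence <- toupper(sequence)
  bad <- regexpr(SIGMA_RE, sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("record '%s': invalid character '%s' at position %d",
                 name[i], substr(sequence[i], bad[i], bad[i]), bad[i]))
  }
  structure(
    data.frame(name = as.character(name), tag = as.character(tag),
               sequence = sequence, length = nchar(sequence),
               stringsAsFactors = FALSE),
    class = c("genome_panel", "data.frame")
  )
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("genome_panel: %d sequence record(s), %d distinct tag(s), %s bases total\n",
              nrow(x), length(unique(x$tag)), format(sum(x$length), big.mark = ",")))
  print(data.frame(tag = x$tag, name = x$name, length = x$length), ...)
  invisible(x)
}

#' Build a hierarchical genome tag from an organism name
#'
#' Tags have the form `GGG_SSS_strain`: the first three letters of the genus
#' and of the species, upper-cased, then the remaining tokens verbatim as the
#' strain field (internal whitespace normalised to underscores, so
#' `"Nostoc punctiforme PCC 73102"` gives `"NOS_PUN_PCC_73102"`). The strain
#' field may be empty.
#'
#' @param organism_name free-text name with at least genus and species tokens.
#' @return tag string.
#' @examples
#' make_tag("Chlamydia trachomatis D/UW-3/CX")  # "CHL_TRA_D/UW-3/CX"
#' make_tag("Escherichia coli")                 # "ESC_COL_"
#' @export
make_tag <- function(organism_name) {
  stopifnot(is.character(organism_name), length(organism_name) == 1)
  toks <- strsplit(trimws(organism_name), "\\s+")[[1]]
  if (length(toks) < 2)
    stop(sprintf("organism name '%s' needs at least genus and species tokens",
                 organism_name))
  abbr <- function(tok, what) {
    letters_only <- gsub("[^A-Za-z]", "", tok)
    if (nchar(letters_only) < 3)
      stop(sprintf("%s token '%s' has fewer than 3 letters", what, tok))
    toupper(substr(letters_only, 1, 3))
  }
  strain <- if (length(toks) > 2) paste(toks[-(1:2)], collapse = "_") else ""
  paste0(abbr(toks[1], "genus"), "_", abbr(toks[2], "species"), "_", strain)
}

#' Read a multi-record FASTA file into a genome panel
#'
#' Sequences are upper-cased, line wrapping is removed and record order is
#' preserved. Headers are used as organism names; tags are derived with
#' [make_tag()] when `tag_from_name = TRUE`, otherwise the first header token
#' is taken as the tag verbatim (useful for files whose headers already are
#' tags).
#'
#' @param path FASTA file.
#' @param tag_from_name derive tags from headers via [make_tag()]; if `FALSE`
#'   the first whitespace-separated header token is the tag.
#' @return a [genome_panel()].
#' @export
read_fasta <- function(path, tag_from_name = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) {
    return(genome_panel(character(0), character(0), character(0)))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">"))
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 meaningful[1]))
  set <- Biostrings::readBStringSet(path)
  name <- names(set)
  sequence <- toupper(as.character(set))
  bad <- regexpr(SIGMA_RE, sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("record '%s': invalid character '%s' at sequence position %d",
                 name[i], substr(sequence[i], bad[i], bad[i]), bad[i]))
  }
  tag <- if (tag_from_name) vapply(name, make_tag, character(1))
         else vapply(strsplit(name, "\\s+"), `[`, character(1), 1)
  genome_panel(name = name, sequence = sequence, tag = tag)
}

#' Write a genome panel (or any named sequences) to FASTA
#'
#' @param x a [genome_panel()] or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "genome_panel") || is.data.frame(x)) {
    seqs <- stats::setNames(x$sequence, x$name)
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is chosen from the file extension (`.fq`/`.fastq` vs anything
#' else), or forced with `format`. Quality strings are read but discarded:
#' classification and abundance estimation are sequence-only.
#'
#' @param path reads file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return named character vector of upper-case read sequences (names = read
#'   ids).
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  set <- if (format == "fastq") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readBStringSet(path)
  }
  stats::setNames(toupper(as.character(set)),
                  vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1))
}

#' Write reads to FASTQ (constant placeholder qualities) or FASTA
#'
#' @param reads named character vector of read sequences.
#' @param path output file; `.fq`/`.fastq` extension selects FASTQ.
#' @param header optional character vector of `"# "`-style provenance lines
#'   (FASTA only; FASTQ admits no comments).
#' @export
write_reads <- function(reads, path, header = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fq", "fastq")) {
    set <- Biostrings::DNAStringSet(reads)
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0(";", header), con)
    writeLines(paste0(">", names(reads), "\n", reads), con)
  }
  invisible(path)
}

# ---- model serialization -------------------------------------------------

#' Write a weighted n-gram model to a documented text format
#'
#' The file is a single TSV with a `#`-prefixed metadata block (format
#' version, n, panel size C, build fraction alpha, seed, repeat-ratio mu and
#' sigma, per-genome statistics, table row counts), followed by a `#unique`
#' section (`ngram`, `tag`) listing n-grams present in exactly one genome and
#' a `#common` section (`ngram`, `freq`, `weight`, `members`) for n-grams in
#' two or more genomes. Weights are serialized with 17 significant digits so
#' doubles round-trip bit-exactly. A `.gz` suffix gzip-compresses the file.
#'
#' @param model an [ngram_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ngram_model"))
  idx <- model$index
  uniq <- model$membership[idx[m == 1L], on = "ngram", nomatch = 0L]
  memb_common <- model$membership[idx[m > 1L], on = "ngram", nomatch = 0L]
  common <- memb_common[, .(members = paste(sort(tag), collapse = ",")), by = ngram]
  common <- idx[m > 1L][common, on = "ngram"]
  data.table::setorder(uniq, ngram)
  data.table::setorder(common, ngram)

  g <- model$genomes
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "#ngramid_model\t1",
    paste0("#n\t", model$n),
    paste0("#C\t", model$C),
    paste0("#alpha\t", fmt(model$alpha)),
    paste0("#seed\t", if (is.null(model$seed)) "NA" else model$seed),
    paste0("#mu\t", fmt(model$mu)),
    paste0("#sigma\t", fmt(model$sigma)),
    paste0("#sigma_type\t", model$sigma_type),
    paste0("#unique_rows\t", nrow(uniq)),
    paste0("#common_rows\t", nrow(common)),
    paste0("#genome\t", g$tag, "\t", g$name, "\t", g$length, "\t", g$total,
           "\t", g$distinct, "\t", g$repeated, "\t", fmt(g$repeat_ratio))
  ), con)
  writeLines("#unique", con)
  writeLines("ngram\ttag", con)
  if (nrow(uniq)) writeLines(paste0(uniq$ngram, "\t", uniq$tag), con)
  writeLines("#common", con)
  writeLines("ngram\tfreq\tweight\tmembers", con)
  if (nrow(common)) {
    writeLines(paste0(common$ngram, "\t", common$m, "\t", fmt(common$weight),
                      "\t", common$members), con)
  }
  invisible(path)
}

#' Read a weighted n-gram model written by [write_model()]
#'
#' @param path model file (optionally gzipped).
#' @param expect_n if given, error unless the stored n-gram length matches.
#' @return an [ngram_model].
#' @export
read_model <- function(path, expect_n = NULL) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0 || lines[1] != "#ngramid_model\t1")
    stop(sprintf("not an ngramid model file (bad or missing version line): %s", path))

  meta_lines <- grep("^#", lines)
  kv <- strsplit(lines[meta_lines], "\t", fixed = TRUE)
  key <- vapply(kv, `[`, character(1), 1)
  getv <- function(k) {
    hit <- which(key == paste0("#", k))
    if (length(hit) != 1) stop(sprintf("model metadata field '%s' missing or duplicated", k))
    kv[[hit]][2]
  }
  n <- as.integer(getv("n"))
  if (!is.null(expect_n) && n != expect_n)
    stop(sprintf("model was built with n=%d but n=%d was requested", n, expect_n))
  C <- as.integer(getv("C"))
  alpha <- as.numeric(getv("alpha"))
  seed <- getv("seed"); seed <- if (identical(seed, "NA")) NULL else as.integer(seed)
  mu <- as.numeric(getv("mu")); sigma <- as.numeric(getv("sigma"))
  sigma_type <- getv("sigma_type")
  n_uniq <- as.integer(getv("unique_rows")); n_common <- as.integer(getv("common_rows"))

  grows <- kv[key == "#genome"]
  genomes <- data.table::data.table(
    tag = vapply(grows, `[`, character(1), 2),
    name = vapply(grows, `[`, character(1), 3),
    length = as.numeric(vapply(grows, `[`, character(1), 4)),
    total = as.numeric(vapply(grows, `[`, character(1), 5)),
    distinct = as.numeric(vapply(grows, `[`, character(1), 6)),
    repeated = as.numeric(vapply(grows, `[`, character(1), 7)),
    repeat_ratio = as.numeric(vapply(grows, `[`, character(1), 8))
  )

  iu <- which(lines == "#unique"); ic <- which(lines == "#common")
  if (length(iu) != 1 || length(ic) != 1)
    stop(sprintf("model file is missing its table sections (truncated?): %s", path))
  uniq_body <- lines[seq.int(iu + 2L, length.out = max(0L, ic - iu - 2L))]
  common_body <- if (ic + 2L <= length(lines)) lines[(ic + 2L):length(lines)] else character(0)
  common_body <- common_body[nzchar(common_body)]
  if (length(uniq_body) != n_uniq || length(common_body) != n_common)
    stop(sprintf(
      "model file is truncated: expected %d unique / %d common rows, found %d / %d",
      n_uniq, n_common, length(uniq_body), length(common_body)))

  if (n_uniq > 0) {
    u <- data.table::fread(text = c("ngram\ttag", uniq_body), sep = "\t",
                           colClasses = list(character = 1:2))
  } else {
    u <- data.table::data.table(ngram = character(0), tag = character(0))
  }
  if (n_common > 0) {
    cm <- data.table::fread(text = c("ngram\tfreq\tweight\tmembers", common_body),
                            sep = "\t",
                            colClasses = c("character", "integer", "numeric", "character"))
  } else {
    cm <- data.table::data.table(ngram = character(0), freq = integer(0),
                                 weight = numeric(0), members = character(0))
  }

  index <- data.table::rbindlist(list(
    data.table::data.table(ngram = u$ngram, m = 1L, weight = 1),
    data.table::data.table(ngram = cm$ngram, m = cm$freq, weight = cm$weight)
  ))
  mem_common <- if (nrow(cm)) {
    sp <- strsplit(cm$members, ",", fixed = TRUE)
    data.table::data.table(ngram = rep(cm$ngram, lengths(sp)), tag = unlist(sp))
  } else {
    data.table::data.table(ngram = character(0), tag = character(0))
  }
  membership <- data.table::rbindlist(list(u[, .(ngram, tag)], mem_common))
  new_ngram_model(n = n, C = C, alpha = alpha, seed = seed,
                  genomes = genomes, mu = mu, sigma = sigma,
                  sigma_type = sigma_type, index = index, membership = membership)
}

#' Write an abundance table as TSV with a provenance header
#'
#' @param x an `abundance_table` (see [abundance_table()]).
#' @param path output TSV.
#' @param header extra provenance lines (prefixed `# `).
#' @export
write_abundance <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ngramid abundance table"),
    sprintf("# mu=%.6f sigma=%.6f target=%g", attr(x, "mu"), attr(x, "sigma"),
            attr(x, "target")),
    if (!is.null(header)) paste0("# ", header)
  ), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
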