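# shared helpers (internal)

# IUPAC nucleotide alphabet accepted throughout the package
SIGMA <- c("A", "C", "T", "G", "N", "R", "Y", "W", "M", "S", "K", "B", "D", "H", "V")
SIGMA_RE <- paste0("[^", paste(SIGMA, collapse = ""), "]")

#' Reverse complement of nucleotide strings
#'
#' Strict A/C/G/T complementation. Strings containing any other character
#' (ambiguity codes) are returned as `NA`: the index stores forward-strand
#' genome n-grams only and ambiguity codes are looked up literally, so they
#' have no second orientation.
#'
#' @param x character vector of nucleotide strings (upper case).
#' @return character vector; `NA` where `x` contains non-ACGT characters.
#' @keywords internal
revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- which(!grepl("[^ACGT]", x))
  if (length(ok)) out[ok] <- rev_strings(chartr("ACGT", "TGCA", x[ok]))
  out
}

# reverse complement honouring IUPAC ambiguity complements (A-T, C-G, R-Y,
# K-M, B-V, D-H; W, S, N self-complementary); used by the read simulator
revcomp_iupac <- function(x) {
  rev_strings(chartr("ACGTRYWSKMBVDHN", "TGCAYRWSMKVBHDN", x))
}

# reverse each string; vectorised column-wise within equal-length groups
rev_strings <- function(x) {
  out <- character(length(x))
  lens <- nchar(x)
  for (L in unique(lens)) {
    i <- which(lens == L)
    if (L == 0L) { out[i] <- ""; next }
    cols <- lapply(L:1, function(j) substr(x[i], j, j))
    out[i] <- do.call(paste0, cols)
  }
  out
}

# evaluate expr with a temporarily-seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed (kept well below .Machine$integer.max)
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483587)
}

# random A/C/G/T sequence of given length (uses current RNG state)
random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# three-letter code for a positive integer: 1 -> "AAA", 2 -> "AAB", ...
code3 <- function(i) {
  stopifnot(all(i >= 1))
  i <- as.integer(i) - 1L
  paste0(LETTERS[(i %/% 676L) %% 26L + 1L],
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
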