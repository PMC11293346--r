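## Small DNA string helpers shared across the package.  Sequences are plain
## uppercase character scalars; Biostrings does the heavy lifting where a
## real parser or biological operation is needed.

#' Normalise and validate a DNA sequence
#'
#' Uppercases the input and rejects characters outside the \code{ACGTN}
#' alphabet (\code{N} is tolerated as an ambiguity code; anything else is an
#' input error).
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @param allow_empty if \code{FALSE}, an empty sequence is an error.
#' @return the uppercased sequence.
#' @export
norm_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  x <- toupper(x)
  if (!allow_empty && nchar(x) == 0L)
    stop(what, " must be nonempty")
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside the ACGTN alphabet")
  x
}

#' Reverse complement of a DNA string
#'
#' @param x DNA character scalar.
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' Draws from the current RNG stream; callers that need reproducibility set
#' the seed (all simulation entry points in this package do).
#'
#' @param n length in bases.
#' @param gc GC content (probability of G or C per base).
#' @return character scalar of length \code{n}.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## 0-based half-open substring: bases [from, to) of x
substr0 <- function(x, from, to) {
  if (to <= from) return("")
  substr(x, from + 1L, to)
}

## deterministic child seed for a named pipeline stage, kept within the
## 32-bit integer range R's RNG accepts
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Translate a coding DNA sequence
#'
#' Standard-code translation of complete codons (trailing partial codons are
#' dropped); thin wrapper over \code{Biostrings::translate}.
#'
#' @param x DNA character scalar.
#' @return amino-acid character scalar (may be empty).
#' @export
translate_dna <- function(x) {
  x <- norm_dna(x, allow_empty = TRUE)
  n <- nchar(x) - nchar(x) %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     no.init.codon = TRUE))
}
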