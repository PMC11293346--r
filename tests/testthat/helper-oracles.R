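# Shared fixtures and independent oracles.
#
# The oracles here are deliberately naive re-derivations (plain-R dynamic
# programming, exhaustive scans, direct string construction) kept separate
# from the package's own code paths.

# cached toy experiment so every test file does not rebuild it
toy_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- hiti_experiment("toy")
    cache
  }
})

# brute-force affine-gap semi-global alignment score (ends free in both
# sequences); O(nm) plain-R triple-matrix DP
oracle_semiglobal_score <- function(a, b, match = 2, mismatch = -4,
                                    gap_open = 4, gap_ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  V <- matrix(NEG, n + 1, m + 1); E <- V; F <- V
  V[1, ] <- 0; V[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, V[i, j - 1] - gap_open - gap_ext)
      F[i, j] <- max(F[i - 1, j] - gap_ext, V[i - 1, j] - gap_open - gap_ext)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      V[i, j] <- max(V[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(V[n + 1, ], V[, m + 1])
}

# exhaustive infix edit distance: minimum utils::adist over all substrings
# of the text whose length is within +/- slack of the pattern's (any
# distance <= slack is achieved by such a substring, and the restriction
# only ever over-estimates, so decisions at <= slack mismatches agree)
oracle_infix_edit <- function(pattern, text, slack = 6L) {
  plen <- nchar(pattern); tlen <- nchar(text)
  best <- plen
  for (len in max(0L, plen - slack):min(tlen, plen + slack)) {
    if (len == 0L) { best <- min(best, plen); next }
    starts <- seq_len(tlen - len + 1L)
    subs <- substring(text, starts, starts + len - 1L)
    best <- min(best, min(utils::adist(pattern, subs)))
  }
  best
}

# oracle barcode assignment: exhaustive scan over both terminal windows of
# both strands, mirroring the demultiplexing contract
oracle_assign <- function(read, table) {
  span <- table$search_span; n <- nchar(read)
  rc <- revcomp(read)
  windows <- unique(c(substr(read, 1, min(span, n)),
                      substr(read, max(1, n - span + 1), n),
                      substr(rc, 1, min(span, n)),
                      substr(rc, max(1, n - span + 1), n)))
  d <- vapply(table$sequences, function(bc)
    min(vapply(windows, function(w) oracle_infix_edit(bc, w), 0)), 0)
  if (min(d) > table$max_mismatches) return("UNASSIGNED")
  hits <- which(d == min(d))
  if (length(hits) > 1) "UNASSIGNED" else table$ids[hits]
}

# standard-code codon translation oracle (independent of Biostrings)
oracle_translate <- function(cds) {
  codon_table <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- nchar(cds) %/% 3
  if (n == 0) return("")
  starts <- 3 * (seq_len(n) - 1) + 1
  paste(codon_table[substring(cds, starts, starts + 2)], collapse = "")
}

# string-level reverse complement oracle (chartr + rev, no Biostrings)
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
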