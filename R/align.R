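## R surface over the C++ affine-gap alignment kernels.

#' Alignment scoring parameters
#'
#' Affine-gap scores used by all aligners in the package: match +2,
#' mismatch -4, gap opening -4 charged once per gap, gap extension -2 per
#' gapped base (so a length-L gap scores -(4 + 2L)).  This is the same
#' parameterisation as \code{Biostrings::pairwiseAlignment}, which the test
#' suite uses as an independent cross-check of the kernel.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext gap penalties (given as positive costs).
#' @return list of scores.
#' @export
alignment_scores <- function(match = 2L, mismatch = -4L, gap_open = 4L,
                             gap_ext = 2L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext))
}

new_alignment_result <- function(raw, ref_label, strand) {
  ## m_columns: aligned base pairs (M columns); gc_identity is the
  ## gap-compressed identity (matches over aligned pairs), robust to long
  ## planted insertions, while identity includes gap columns
  ops <- cigar_ops(raw$cigar)
  m_cols <- sum(ops$len[ops$op %in% c("M", "X", "=")])
  res <- list(
    ref_label = ref_label,
    score = raw$score,
    cigar = raw$cigar,
    read_range = c(start = raw$read_start, end = raw$read_end),
    ref_range = c(start = raw$ref_start, end = raw$ref_end),
    matches = raw$matches,
    columns = raw$columns,
    m_columns = m_cols,
    identity = if (raw$columns > 0) raw$matches / raw$columns else 0,
    gc_identity = if (m_cols > 0) raw$matches / m_cols else 0,
    strand = strand)
  class(res) <- "AlignmentResult"
  res
}

#' Optimal semi-global (overlap) alignment
#'
#' Score-optimal affine-gap alignment with free end gaps in both
#' sequences; the CIGAR covers the aligned core only and the 0-based
#' half-open \code{read_range}/\code{ref_range} place it.  Identity is
#' matches over alignment columns (M+I+D).
#'
#' @param read,reference DNA character scalars (both nonempty).
#' @param scores see \code{\link{alignment_scores}}.
#' @param ref_label label stored in the result.
#' @param strand strand tag stored in the result (the caller aligns the
#'   reverse complement itself when scanning both orientations).
#' @return an \code{AlignmentResult}.
#' @export
align_semiglobal <- function(read, reference, scores = alignment_scores(),
                             ref_label = "ref", strand = "+") {
  read <- norm_dna(read, "read"); reference <- norm_dna(reference, "reference")
  raw <- .cpp_align(read, reference, scores$match, scores$mismatch,
                    scores$gap_open, scores$gap_ext, FALSE, FALSE)
  new_alignment_result(raw, ref_label, strand)
}

#' Optimal local alignment
#'
#' Smith-Waterman under the same affine-gap scores.
#'
#' @inheritParams align_semiglobal
#' @return an \code{AlignmentResult}.
#' @export
align_local <- function(read, reference, scores = alignment_scores(),
                        ref_label = "ref", strand = "+") {
  read <- norm_dna(read, "read"); reference <- norm_dna(reference, "reference")
  raw <- .cpp_align(read, reference, scores$match, scores$mismatch,
                    scores$gap_open, scores$gap_ext, TRUE, FALSE)
  new_alignment_result(raw, ref_label, strand)
}

#' Alignment score only (fast path for reference pre-selection)
#'
#' @inheritParams align_semiglobal
#' @param local if \code{TRUE}, local alignment.
#' @return integer score.
#' @export
align_score <- function(read, reference, scores = alignment_scores(),
                        local = FALSE) {
  .cpp_align(read, reference, scores$match, scores$mismatch,
             scores$gap_open, scores$gap_ext, local, TRUE)$score
}

#' Parse a CIGAR string into an operations table
#'
#' @param cigar CIGAR with M/I/D operations.
#' @return data frame (op, len).
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "")
    return(data.frame(op = character(), len = integer()))
  m <- gregexpr("\\d+[MIDX=]", cigar)[[1L]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDX=]", cigar))[[1L]]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Per-event table of an alignment's indels
#'
#' Walks the CIGAR from the alignment's reference/read start and reports
#' every insertion and deletion with its reference anchor (for an
#' insertion, the reference position the inserted bases precede; for a
#' deletion, the first deleted reference base), its read interval, and
#' length.
#'
#' @param alignment an \code{AlignmentResult}.
#' @return data frame (type, ref_pos, read_pos, len).
#' @export
alignment_indels <- function(alignment) {
  ops <- cigar_ops(alignment$cigar)
  ref <- alignment$ref_range[["start"]]
  read <- alignment$read_range[["start"]]
  out <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "X", "=")) {
      ref <- ref + len; read <- read + len
    } else if (op == "I") {
      out[[length(out) + 1L]] <-
        data.frame(type = "I", ref_pos = ref, read_pos = read, len = len)
      read <- read + len
    } else if (op == "D") {
      out[[length(out) + 1L]] <-
        data.frame(type = "D", ref_pos = ref, read_pos = read, len = len)
      ref <- ref + len
    }
  }
  if (length(out) == 0L)
    return(data.frame(type = character(), ref_pos = integer(),
                      read_pos = integer(), len = integer()))
  do.call(rbind, out)
}

#' Infix edit distance
#'
#' Minimum unit-cost edit distance (substitutions and indels) between the
#' whole pattern and any substring of the text.
#'
#' @param pattern,text DNA character scalars.
#' @return integer distance.
#' @export
infix_edit_distance <- function(pattern, text) {
  .cpp_infix_edit(pattern, text)
}
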