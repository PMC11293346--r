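## Short-read / amplicon analyses: windowed indel quantification at the cut
## site, vector-origin assignment of long insertions, and the two-stage
## short-read ITR-content frequency.

#' Labelled vector references with annotated ITR intervals
#'
#' @param donor a \code{DonorConstruct} (the donor AAV genome) or a list
#'   with \code{sequence} and \code{itr_intervals}.
#' @param nuclease a list with \code{sequence} and \code{itr_intervals}
#'   (see \code{\link{make_nuclease_vector}}).
#' @return a \code{VectorRefSet}: named list of
#'   \code{list(sequence, itr_intervals)} entries.
#' @export
vector_ref_set <- function(donor, nuclease) {
  as_entry <- function(x, what) {
    if (inherits(x, "DonorConstruct"))
      x <- list(sequence = x$full_sequence,
                itr_intervals = donor_itr_intervals(x))
    stopifnot(is.character(x$sequence), is.data.frame(x$itr_intervals))
    if (any(x$itr_intervals$start < 0L |
            x$itr_intervals$end > nchar(x$sequence)))
      stop(what, ": ITR intervals outside reference bounds")
    x
  }
  structure(list(donor = as_entry(donor, "donor"),
                 nuclease = as_entry(nuclease, "nuclease")),
            class = "VectorRefSet")
}

## best-strand alignment of a read against one reference
best_strand_alignment <- function(read, reference, scores, local = FALSE,
                                  ref_label = "ref") {
  f <- if (local) align_local else align_semiglobal
  fw <- f(read, reference, scores, ref_label, "+")
  rv <- f(revcomp(read), reference, scores, ref_label, "-")
  if (rv$score > fw$score) rv else fw
}

#' Windowed amplicon indel quantification
#'
#' Aligns each read to the amplicon reference (both strands, semi-global)
#' and calls it modified if any insertion or deletion overlaps the
#' \code{[cut - window, cut + window)} interval: a deletion overlaps if
#' any deleted reference base falls in the window, an insertion if its
#' reference anchor does.  Substitutions alone never set modified.  Reads
#' below the identity floor are excluded from the denominator and counted
#' separately.
#'
#' @param reads data frame (read_id, sequence).
#' @param reference amplicon reference sequence.
#' @param cut 0-based cut coordinate on the reference (must lie inside).
#' @param window half-width of the evaluation window (default 17).
#' @param min_identity exclusion floor on gap-compressed identity (matches
#'   over aligned base pairs; a long planted insertion does not depress
#'   it).
#' @param min_aligned minimum aligned base pairs for inclusion.
#' @param count_substitutions if \code{TRUE}, window substitutions also
#'   set modified (for parity with amplicon tools that count them); off by
#'   default since the quantity of interest is indels.
#' @param scores alignment scores.
#' @return list with \code{calls} (read_id, modified, n_events, events as
#'   JSON), \code{modified_fraction}, \code{n_aligned}, \code{n_excluded}.
#' @export
call_amplicon_indels <- function(reads, reference, cut, window = 17L,
                                 min_identity = 0.7, min_aligned = 50L,
                                 count_substitutions = FALSE,
                                 scores = alignment_scores()) {
  reference <- norm_dna(reference, "reference")
  if (cut < 0L || cut > nchar(reference))
    stop("cut coordinate lies outside the reference")
  w0 <- cut - window; w1 <- cut + window
  rows <- vector("list", nrow(reads))
  excluded <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    aln <- best_strand_alignment(reads$sequence[i], reference, scores)
    if (aln$gc_identity < min_identity || aln$m_columns < min_aligned) {
      excluded[i] <- TRUE; next
    }
    ev <- alignment_indels(aln)
    hit <- ev[(ev$type == "I" & ev$ref_pos >= w0 & ev$ref_pos < w1) |
                (ev$type == "D" & ev$ref_pos < w1 & ev$ref_pos + ev$len > w0),
              , drop = FALSE]
    modified <- nrow(hit) > 0L
    if (!modified && count_substitutions) {
      seg_ref <- substr0(reference, max(0L, w0),
                         min(nchar(reference), w1))
      seg_read <- read_segment_for_ref(aln, if (aln$strand == "+")
        reads$sequence[i] else revcomp(reads$sequence[i]),
        max(0L, w0), min(nchar(reference), w1))
      modified <- nchar(seg_read) == nchar(seg_ref) && seg_read != seg_ref
    }
    rows[[i]] <- data.frame(
      read_id = reads$read_id[i], modified = modified,
      n_events = nrow(hit),
      events = if (nrow(hit) == 0L) "[]" else
        as.character(jsonlite::toJSON(hit)),
      strand = aln$strand, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[!excluded])
  n_aligned <- sum(!excluded)
  list(calls = calls,
       modified_fraction = if (n_aligned > 0)
         mean(calls$modified) else NA_real_,
       n_aligned = n_aligned, n_excluded = sum(excluded))
}

#' Extract windowed insertion sequences from amplicon reads
#'
#' Convenience for the origin analysis: aligns reads to the amplicon and
#' returns the inserted sequences longer than \code{min_len} whose anchor
#' falls within the window around the cut.
#'
#' @inheritParams call_amplicon_indels
#' @param min_len strict length filter: only insertions with
#'   \code{len > min_len} are returned ("longer than 10 nucleotides").
#' @param min_aligned minimum aligned base pairs for inclusion.
#' @return data frame (read_id, ref_pos, len, sequence).
#' @export
extract_window_insertions <- function(reads, reference, cut, window = 17L,
                                      min_len = 10L, min_identity = 0.7,
                                      min_aligned = 50L,
                                      scores = alignment_scores()) {
  reference <- norm_dna(reference, "reference")
  out <- list()
  for (i in seq_len(nrow(reads))) {
    aln <- best_strand_alignment(reads$sequence[i], reference, scores)
    if (aln$gc_identity < min_identity || aln$m_columns < min_aligned) next
    oread <- if (aln$strand == "+") toupper(reads$sequence[i]) else
      revcomp(reads$sequence[i])
    ev <- alignment_indels(aln)
    ev <- ev[ev$type == "I" & ev$len > min_len &
               ev$ref_pos >= cut - window & ev$ref_pos < cut + window,
             , drop = FALSE]
    for (k in seq_len(nrow(ev)))
      out[[length(out) + 1L]] <- data.frame(
        read_id = reads$read_id[i], ref_pos = ev$ref_pos[k],
        len = ev$len[k],
        sequence = substr0(oread, ev$read_pos[k], ev$read_pos[k] + ev$len[k]),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), ref_pos = integer(),
                      len = integer(), sequence = character()))
  do.call(rbind, out)
}

#' Assign a vector origin to captured insertions
#'
#' Each inserted sequence is locally aligned against both vector genomes
#' on both strands; the winning reference gives the origin, sub-labelled
#' \code{_itr} when the aligned reference interval overlaps an annotated
#' ITR.  Ties between the two vectors, or fewer than \code{min_bases}
#' aligned reference bases, yield \code{unknown}.
#'
#' @param insertions character vector of inserted sequences, or the data
#'   frame from \code{\link{extract_window_insertions}}.
#' @param vectors a \code{VectorRefSet}.
#' @param min_bases minimum aligned reference bases for a call.
#' @param scores alignment scores.
#' @return character vector of labels in \code{donor_itr},
#'   \code{donor_internal}, \code{nuclease_itr}, \code{nuclease_internal},
#'   \code{unknown}.
#' @export
classify_insertion_origins <- function(insertions, vectors, min_bases = 10L,
                                       scores = alignment_scores()) {
  stopifnot(inherits(vectors, "VectorRefSet"))
  seqs <- if (is.data.frame(insertions)) insertions$sequence else insertions
  vapply(seqs, function(s) {
    s <- norm_dna(s)
    alns <- lapply(names(vectors), function(v)
      best_strand_alignment(s, vectors[[v]]$sequence, scores, local = TRUE,
                            ref_label = v))
    sc <- vapply(alns, `[[`, 0L, "score")
    if (max(sc) == 0L || sum(sc == max(sc)) > 1L) return("unknown")
    best <- alns[[which.max(sc)]]
    covered <- best$ref_range[["end"]] - best$ref_range[["start"]]
    if (covered < min_bases) return("unknown")
    vec <- names(vectors)[which.max(sc)]
    iv <- vectors[[vec]]$itr_intervals
    in_itr <- any(best$ref_range[["start"]] < iv$end &
                    best$ref_range[["end"]] > iv$start)
    paste0(vec, if (in_itr) "_itr" else "_internal")
  }, "", USE.NAMES = FALSE)
}

## read segments not explained by the amplicon: unaligned prefix/suffix
## plus inserted segments from the CIGAR
unexplained_segments <- function(aln, oread, min_len = 1L) {
  segs <- c(substr0(oread, 0L, aln$read_range[["start"]]),
            substr0(oread, aln$read_range[["end"]], nchar(oread)))
  ev <- alignment_indels(aln)
  ev <- ev[ev$type == "I", , drop = FALSE]
  if (nrow(ev) > 0L)
    segs <- c(segs, vapply(seq_len(nrow(ev)), function(k)
      substr0(oread, ev$read_pos[k], ev$read_pos[k] + ev$len[k]), ""))
  segs[nchar(segs) >= min_len]
}

#' Two-stage short-read ITR frequency
#'
#' Stage 1 maps each read to the amplicon reference by local alignment
#' (both strands) and keeps reads with identity \code{>= min_identity}
#' over \code{>= min_aligned} alignment columns.  Stage 2 tests, for each
#' kept read, the read sequence not explained by the amplicon (unaligned
#' ends and inserted segments) for ITR content with
#' \code{\link{detect_itr_content}}.  The result is the relative
#' frequency: ITR-containing reads over mapped reads.
#'
#' @param reads data frame (read_id, sequence).
#' @param reference amplicon reference (the expected clean junction
#'   product).
#' @param itr an \code{ItrElement}.
#' @param min_bases,itr_min_identity ITR-content thresholds (">9 bp" ->
#'   10 at 90\%).
#' @param min_identity,min_aligned stage-1 mapping thresholds.
#' @param scores alignment scores.
#' @return list with \code{frequency} (\code{NA} if no read maps),
#'   \code{n_mapped}, \code{n_itr}, \code{n_unmapped}, and \code{itr_flags}
#'   (logical per mapped read, truth-comparison hook).
#' @export
quantify_itr_short_reads <- function(reads, reference, itr, min_bases = 10L,
                                     itr_min_identity = 0.9,
                                     min_identity = 0.7, min_aligned = 50L,
                                     scores = alignment_scores()) {
  reference <- norm_dna(reference, "reference")
  mapped_ids <- character(0); flags <- logical(0)
  n_unmapped <- 0L
  for (i in seq_len(nrow(reads))) {
    aln <- best_strand_alignment(reads$sequence[i], reference, scores,
                                 local = TRUE)
    if (aln$identity < min_identity || aln$columns < min_aligned) {
      n_unmapped <- n_unmapped + 1L; next
    }
    oread <- if (aln$strand == "+") toupper(reads$sequence[i]) else
      revcomp(reads$sequence[i])
    segs <- unexplained_segments(aln, oread, min_len = min_bases)
    hit <- any(vapply(segs, function(s)
      detect_itr_content(s, itr, min_bases, itr_min_identity)$flag, FALSE))
    mapped_ids <- c(mapped_ids, reads$read_id[i])
    flags <- c(flags, hit)
  }
  n_mapped <- length(mapped_ids)
  list(frequency = if (n_mapped > 0) mean(flags) else NA_real_,
       n_mapped = n_mapped, n_itr = sum(flags), n_unmapped = n_unmapped,
       itr_flags = setNames(flags, mapped_ids))
}
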