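## Long-read junction classification: align each read to the expected
## junction references, count windowed insertions from the CIGAR, test
## insertion / junction sequence for ITR content, and call the outcome
## class with a fixed precedence:
##   1. itr_containing  -- windowed insertion with ITR content, or a
##      best-scoring ITR-retained reference whose junction-proximal ITR
##      segment is confirmed in the read;
##   2. reverse_orientation -- a reverse-class reference wins w/o ITR;
##   3. nhej_indel      -- qualifying indels overlap the junction window;
##   4. hiti_clean      -- the forward reference wins with no events;
##   5. unedited        -- the unedited reference wins with no events;
##   6. unassigned      -- identity below floor or window not covered.

#' Classification thresholds
#'
#' @param min_identity identity floor for assignment; below it a read is
#'   \code{unassigned} rather than force-called.
#' @param window half-width (bases) of the insertion-counting window
#'   around the junction.
#' @param min_insertion minimum insertion length counted in the window
#'   (">9 bp" rule: 10).
#' @param min_indel minimum indel length that qualifies a read as
#'   \code{nhej_indel}.  The default 10 makes calls robust to the
#'   one-base indel noise of long reads; set 1 (see
#'   \code{\link{strict_thresholds}}) for error-free data where every
#'   indel is real.
#' @param itr_min_bases minimum aligned ITR bases for ITR content
#'   (">9 bp" -> 10).
#' @param itr_min_identity identity required of the ITR local alignment.
#' @return list of thresholds.
#' @export
classify_thresholds <- function(min_identity = 0.7, window = 200L,
                                min_insertion = 10L, min_indel = 10L,
                                itr_min_bases = 10L,
                                itr_min_identity = 0.9) {
  list(min_identity = min_identity, window = as.integer(window),
       min_insertion = as.integer(min_insertion),
       min_indel = as.integer(min_indel),
       itr_min_bases = as.integer(itr_min_bases),
       itr_min_identity = itr_min_identity)
}

#' @rdname classify_thresholds
#' @param ... overrides passed to \code{\link{classify_thresholds}}.
#' @export
strict_thresholds <- function(...) {
  classify_thresholds(min_indel = 1L, ...)
}

#' Count insertions within a window around the junction
#'
#' Insertion operations of length \code{>= min_len} whose reference anchor
#' lies within \code{[junction_coord - window, junction_coord + window)}.
#'
#' @param alignment an \code{AlignmentResult} against a junction reference.
#' @param junction_coord 0-based junction coordinate on the reference.
#' @param ref_length reference length (for bounds checking).
#' @param window window half-width.
#' @param min_len minimum insertion length.
#' @return data frame (type, ref_pos, read_pos, len) of qualifying
#'   insertions.
#' @export
count_window_insertions <- function(alignment, junction_coord, ref_length,
                                    window = 200L, min_len = 10L) {
  if (junction_coord < 0L || junction_coord > ref_length)
    stop("junction_coord lies outside the reference")
  ev <- alignment_indels(alignment)
  ev <- ev[ev$type == "I" & ev$len >= min_len &
             ev$ref_pos >= junction_coord - window &
             ev$ref_pos < junction_coord + window, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect ITR content in a sequence segment
#'
#' Best local alignment of the segment against the ITR and its reverse
#' complement, under a scoring scheme derived from \code{min_identity}:
#' every error column (mismatch or gap base) costs
#' \code{2 * min_identity / (1 - min_identity)} (less one integer step so
#' the boundary is inclusive), so any alignment with a positive score has
#' identity of at least \code{min_identity}.  \code{matched_bases} is the
#' number of ITR bases that alignment covers, and the flag is true when
#' \code{matched_bases >= min_bases} (the ">9 bp" rule with the default
#' 10).  \code{min_identity = 1} degenerates to exact substring matching.
#'
#' @param segment DNA character scalar (may be empty: no content).
#' @param itr an \code{ItrElement}.
#' @param min_bases,min_identity thresholds.
#' @return list with \code{matched_bases}, \code{flag}, \code{identity},
#'   \code{strand}.
#' @export
detect_itr_content <- function(segment, itr, min_bases = 10L,
                               min_identity = 0.9) {
  stopifnot(inherits(itr, "ItrElement"))
  if (is.na(segment) || nchar(segment) == 0L)
    return(list(matched_bases = 0L, flag = FALSE, identity = 0, strand = "+"))
  err_cost <- if (min_identity >= 1) 1000000L else
    max(1L, as.integer(ceiling(2 * min_identity / (1 - min_identity))) - 1L)
  scores <- alignment_scores(match = 2L, mismatch = -err_cost,
                             gap_open = 0L, gap_ext = err_cost)
  fw <- align_local(segment, itr$sequence, scores, itr$label, "+")
  rv <- align_local(segment, revcomp(itr$sequence), scores, itr$label, "-")
  best <- if (rv$score > fw$score) rv else fw
  covered <- best$ref_range[["end"]] - best$ref_range[["start"]]
  list(matched_bases = as.integer(covered),
       flag = covered >= min_bases,
       identity = best$identity, strand = best$strand)
}

## read segment aligned to reference interval [from, to), via CIGAR walk
read_segment_for_ref <- function(alignment, read, from, to) {
  ops <- cigar_ops(alignment$cigar)
  ref <- alignment$ref_range[["start"]]
  rd <- alignment$read_range[["start"]]
  r0 <- NA_integer_; r1 <- NA_integer_
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    consumes_ref <- op %in% c("M", "X", "=", "D")
    consumes_read <- op %in% c("M", "X", "=", "I")
    ref2 <- ref + if (consumes_ref) len else 0L
    rd2 <- rd + if (consumes_read) len else 0L
    if (consumes_ref && ref < to && ref2 > from) {
      ov0 <- max(ref, from); ov1 <- min(ref2, to)
      if (consumes_read) {
        seg0 <- rd + (ov0 - ref); seg1 <- rd + (ov1 - ref)
      } else { seg0 <- rd; seg1 <- rd }
      if (is.na(r0)) r0 <- seg0
      r1 <- seg1
    }
    ref <- ref2; rd <- rd2
  }
  if (is.na(r0)) return("")
  substr0(read, r0, r1)
}

## ITR-derived reference interval adjacent to the junction of an
## ITR-retained reference (donor side starts/ends with an ITR)
retained_itr_interval <- function(ref_row, itr_len) {
  jc <- ref_row$junction_coord
  if (ref_row$side == "5p") c(jc, jc + itr_len) else c(jc - itr_len, jc)
}

#' Classify one read against a junction reference set
#'
#' Aligns the read (both strands) to every reference of the library's
#' side, picks the best score, and applies the precedence described at the
#' top of this file.  Ties are broken toward the forward strand, then
#' reference order.
#'
#' @param read DNA character scalar.
#' @param refs a \code{JunctionRefSet}.
#' @param itr an \code{ItrElement}.
#' @param side \code{"5p"} or \code{"3p"}; defaults to the refs' side if
#'   unique.
#' @param thresholds see \code{\link{classify_thresholds}}.
#' @param scores alignment scores.
#' @param read_id identifier carried into the result.
#' @return one-row data frame (read_id, side, class, itr_bases,
#'   n_insertions, insertions as a JSON cell, best_ref, identity, strand,
#'   score).
#' @export
classify_read <- function(read, refs, itr, side = NULL,
                          thresholds = classify_thresholds(),
                          scores = alignment_scores(), read_id = "read") {
  if (nrow(refs) == 0L) stop("empty junction reference set")
  if (is.null(side)) {
    side <- unique(refs$side)
    if (length(side) != 1L)
      stop("refs contain both sides; specify `side`")
  }
  refs <- refs[refs$side == side, , drop = FALSE]
  read <- norm_dna(read)
  rc <- revcomp(read)
  sc_fw <- vapply(refs$sequence, function(r)
    align_score(read, r, scores), 0L, USE.NAMES = FALSE)
  sc_rv <- vapply(refs$sequence, function(r)
    align_score(rc, r, scores), 0L, USE.NAMES = FALSE)
  strand <- if (max(sc_rv) > max(sc_fw)) "-" else "+"
  sc <- if (strand == "+") sc_fw else sc_rv
  oread <- if (strand == "+") read else rc
  best_i <- which.max(sc)
  ref_row <- refs[best_i, ]
  aln <- align_semiglobal(oread, ref_row$sequence, scores,
                          ref_label = ref_row$label, strand = strand)
  result <- function(class, itr_bases = 0L, ins = NULL) {
    data.frame(read_id = read_id, side = side, class = class,
               itr_bases = as.integer(itr_bases),
               n_insertions = if (is.null(ins)) 0L else nrow(ins),
               insertions = if (is.null(ins) || nrow(ins) == 0L) "[]" else
                 as.character(jsonlite::toJSON(ins)),
               best_ref = ref_row$label, identity = aln$identity,
               strand = strand, score = aln$score,
               stringsAsFactors = FALSE)
  }
  if (aln$identity < thresholds$min_identity) return(result("unassigned"))
  jc <- ref_row$junction_coord
  ref_len <- nchar(ref_row$sequence)
  w0 <- max(0L, jc - thresholds$window)
  w1 <- min(ref_len, jc + thresholds$window)
  if (aln$ref_range[["start"]] > w0 || aln$ref_range[["end"]] < w1)
    return(result("unassigned"))
  ## (1) ITR content: windowed insertions ...
  ins <- count_window_insertions(aln, jc, ref_len,
                                 thresholds$window, thresholds$min_insertion)
  if (nrow(ins) > 0L) {
    ## pad the inserted segment by min_bases on each side: equally scoring
    ## alignments can shift an insertion by a few bases, moving planted
    ## ITR bases just outside the I operation
    pad <- thresholds$itr_min_bases
    hits <- lapply(seq_len(nrow(ins)), function(i) {
      seg <- substr0(oread, max(0L, ins$read_pos[i] - pad),
                     min(nchar(oread), ins$read_pos[i] + ins$len[i] + pad))
      detect_itr_content(seg, itr, thresholds$itr_min_bases,
                         thresholds$itr_min_identity)
    })
    matched <- vapply(hits, `[[`, 0L, "matched_bases")
    if (any(vapply(hits, `[[`, FALSE, "flag")))
      return(result("itr_containing", max(matched), ins))
  }
  ## ... or a confirmed ITR-retained reference match
  if (ref_row$class %in% c("itr_retained_forward", "itr_retained_reverse")) {
    iv <- retained_itr_interval(ref_row, nchar(itr$sequence))
    seg <- read_segment_for_ref(aln, oread, max(0L, iv[1L]),
                                min(ref_len, iv[2L]))
    hit <- detect_itr_content(seg, itr, thresholds$itr_min_bases,
                              thresholds$itr_min_identity)
    if (hit$flag) return(result("itr_containing", hit$matched_bases, ins))
  }
  ## (2) reverse orientation
  if (ref_row$class %in% c("hiti_reverse", "itr_retained_reverse"))
    return(result("reverse_orientation", 0L, ins))
  ## (3) junction-window indels without ITR content
  ev <- alignment_indels(aln)
  qual <- ev[ev$len >= thresholds$min_indel &
               ((ev$type == "I" & ev$ref_pos >= w0 & ev$ref_pos < w1) |
                (ev$type == "D" & ev$ref_pos < w1 & ev$ref_pos + ev$len > w0)),
             , drop = FALSE]
  if (nrow(qual) > 0L) return(result("nhej_indel", 0L, ins))
  ## (4) / (5) clean calls by winning reference
  if (ref_row$class == "hiti_forward") return(result("hiti_clean", 0L, ins))
  if (ref_row$class == "unedited") return(result("unedited", 0L, ins))
  if (ref_row$class == "itr_retained_forward")
    return(result("hiti_clean", 0L, ins)) # retained ref won but no ITR seen
  result("unassigned")
}

#' Classify a set of reads
#'
#' @param reads data frame (read_id, sequence) as from
#'   \code{\link{read_fastq}} or \code{\link{simulate_reads}}.
#' @inheritParams classify_read
#' @return data frame with one row per read (see
#'   \code{\link{classify_read}}).
#' @export
classify_reads <- function(reads, refs, itr, side = NULL,
                           thresholds = classify_thresholds(),
                           scores = alignment_scores()) {
  rows <- lapply(seq_len(nrow(reads)), function(i)
    classify_read(reads$sequence[i], refs, itr, side, thresholds, scores,
                  read_id = reads$read_id[i]))
  do.call(rbind, rows)
}

#' Write per-read classifications as TSV
#'
#' @param classifications data frame from \code{\link{classify_reads}}.
#' @param path TSV file.
#' @export
write_classifications <- function(classifications, path) {
  write.table(classifications, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Per-side class fractions
#'
#' Fractions of each called class per junction side.  The primary
#' denominator excludes \code{unassigned} reads; because it is not obvious
#' which denominator a published percentage uses, the fraction over all
#' reads is reported alongside.
#'
#' @param classifications data frame from \code{\link{classify_reads}}.
#' @return data frame (side, class, n, fraction,
#'   fraction_incl_unassigned); fractions over classified reads sum to 1
#'   per side.
#' @export
summarize_junctions <- function(classifications) {
  if (nrow(classifications) == 0L) stop("no classifications to summarize")
  out <- lapply(split(classifications, classifications$side), function(cl) {
    n_all <- nrow(cl)
    tab <- table(cl$class)
    classes <- names(tab)
    n <- as.integer(tab)
    n_classified <- sum(n[classes != "unassigned"])
    frac <- if (n_classified > 0) n / n_classified else rep(NA_real_, length(n))
    frac[classes == "unassigned"] <- NA_real_
    data.frame(side = cl$side[1L], class = classes, n = n,
               fraction = as.numeric(frac),
               fraction_incl_unassigned = n / n_all,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
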