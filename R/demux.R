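## Barcode demultiplexing of long reads: 24-nt terminal barcodes, best
## edit-distance occurrence within a bounded span at either read end, on
## either strand, with up to max_mismatches differences.  Ambiguous
## (tied) hits are never guessed.

#' A barcode table
#'
#' @param ids sample identifiers (unique).
#' @param sequences barcode sequences (unique; 24 nt is the convention for
#'   the long-read protocol but any length is accepted).
#' @param max_mismatches maximum edit distance for an assignment
#'   (default 4).
#' @param search_span bases scanned from each read end (default 200).
#' @return a \code{BarcodeTable}.  A warning is raised if any two barcodes
#'   are closer than \code{2 * max_mismatches + 1} edits, since such pairs
#'   can produce ambiguous assignments.
#' @export
barcode_table <- function(ids, sequences, max_mismatches = 4L,
                          search_span = 200L) {
  sequences <- vapply(sequences, norm_dna, "", what = "barcode",
                      USE.NAMES = FALSE)
  if (length(ids) != length(sequences) || length(ids) == 0L)
    stop("ids and sequences must be nonempty and of equal length")
  if (anyDuplicated(ids)) stop("barcode ids must be unique")
  if (anyDuplicated(sequences)) stop("barcode sequences must be unique")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  if (length(sequences) > 1L) {
    d <- utils::adist(sequences)
    mind <- min(d[upper.tri(d)])
    if (mind <= 2L * max_mismatches)
      warning("minimum pairwise barcode edit distance (", mind,
              ") is <= 2 * max_mismatches; assignments may be ambiguous")
  }
  structure(list(ids = as.character(ids), sequences = sequences,
                 max_mismatches = as.integer(max_mismatches),
                 search_span = as.integer(search_span)),
            class = "BarcodeTable")
}

#' Read a barcode table from TSV
#'
#' Two columns: id, sequence (with header).
#'
#' @param path TSV file.
#' @param ... passed to \code{\link{barcode_table}}.
#' @export
read_barcode_table <- function(path, ...) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  barcode_table(tab[[1L]], tab[[2L]], ...)
}

#' @rdname read_barcode_table
#' @param table a \code{BarcodeTable}.
#' @export
write_barcode_table <- function(table, path) {
  write.table(data.frame(id = table$ids, sequence = table$sequences),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## best (minimum) edit distance of each barcode against the read's
## terminal windows on both strands
barcode_distances <- function(read, table) {
  span <- table$search_span
  n <- nchar(read)
  rc <- revcomp(read)
  windows <- unique(c(substr(read, 1L, min(span, n)),
                      substr(read, max(1L, n - span + 1L), n),
                      substr(rc, 1L, min(span, n)),
                      substr(rc, max(1L, n - span + 1L), n)))
  vapply(table$sequences, function(bc)
    min(vapply(windows, function(w) .cpp_infix_edit(bc, w), 0L)),
    0L, USE.NAMES = FALSE)
}

#' Assign a read to a barcode
#'
#' Scans both ends of the read and of its reverse complement within
#' \code{search_span} bases for the best edit-distance occurrence of each
#' barcode.  The unique barcode with distance \code{<= max_mismatches}
#' wins; a tie between distinct barcodes, or no barcode within the budget,
#' returns \code{"UNASSIGNED"}.
#'
#' @param read DNA character scalar (nonempty).
#' @param table a \code{BarcodeTable}.
#' @return barcode id or \code{"UNASSIGNED"}.
#' @export
assign_barcode <- function(read, table) {
  stopifnot(inherits(table, "BarcodeTable"))
  read <- norm_dna(read, "read")
  d <- barcode_distances(read, table)
  best <- min(d)
  if (best > table$max_mismatches) return("UNASSIGNED")
  hits <- which(d == best)
  if (length(hits) > 1L) return("UNASSIGNED")
  table$ids[hits]
}

#' Demultiplex a FASTQ into per-sample read sets
#'
#' Every input read lands in exactly one output bin (a sample or
#' \code{UNASSIGNED}); the summary counts sum to the input count.
#'
#' @param fastq path to a FASTQ file, or a reads data frame as returned by
#'   \code{\link{read_fastq}}.
#' @param table a \code{BarcodeTable}.
#' @param outdir if non-\code{NULL}, per-sample FASTQ files (and an
#'   \code{unassigned.fastq}) are written there.
#' @return list with \code{assignments} (data frame read_id, barcode_id),
#'   \code{reads} (named list of per-sample read data frames) and
#'   \code{summary} (named counts, including \code{UNASSIGNED}).
#' @export
demux_fastq <- function(fastq, table, outdir = NULL) {
  stopifnot(inherits(table, "BarcodeTable"))
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  ids <- vapply(reads$sequence, assign_barcode, "", table = table,
                USE.NAMES = FALSE)
  bins <- c(table$ids, "UNASSIGNED")
  split_reads <- lapply(bins, function(b) reads[ids == b, , drop = FALSE])
  names(split_reads) <- bins
  counts <- setNames(vapply(split_reads, nrow, 0L), bins)
  stopifnot(sum(counts) == nrow(reads))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (b in bins)
      if (nrow(split_reads[[b]]) > 0L)
        write_fastq(split_reads[[b]],
                    file.path(outdir, paste0(tolower(b), ".fastq")))
    jsonlite::write_json(as.list(counts),
                         file.path(outdir, "demux_summary.json"),
                         auto_unbox = TRUE)
  }
  list(assignments = data.frame(read_id = reads$read_id, barcode_id = ids,
                                stringsAsFactors = FALSE),
       reads = split_reads, summary = counts)
}

#' Deterministic random barcode set
#'
#' Generates well-separated random barcodes by rejection sampling: a
#' candidate is kept only if its edit distance to every kept barcode
#' exceeds \code{2 * max_mismatches}.
#'
#' @param n number of barcodes.
#' @param length barcode length (default 24).
#' @param seed RNG seed.
#' @param max_mismatches separation target (default 4).
#' @return a \code{BarcodeTable}.
#' @export
random_barcodes <- function(n, length = 24L, seed = 1L, max_mismatches = 4L) {
  set.seed(derive_seed(seed, "barcodes"))
  kept <- character(0)
  while (length(kept) < n) {
    cand <- random_dna(length)
    if (all(utils::adist(cand, kept) > 2L * max_mismatches) ||
        length(kept) == 0L)
      kept <- c(kept, cand)
  }
  barcode_table(sprintf("sample%d", seq_len(n)), kept,
                max_mismatches = max_mismatches)
}
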