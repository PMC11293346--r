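## Synthetic-data stage: alleles drawn from a stated mixture of integration
## outcome classes, then reads with platform error models, a barcode, and a
## truth sidecar.  Everything is deterministic given the top-level seed;
## child seeds for sub-stages are derived with derive_seed().

#' The integration outcome classes the simulator knows
#' @return character vector of class names.
#' @export
outcome_classes <- function() {
  c("unedited", "nhej_indel", "hiti_forward", "hiti_reverse",
    "itr_retained_forward", "itr_retained_reverse",
    "itr_fragment_capture", "cas9_fragment_capture",
    "large_deletion", "large_inversion")
}

#' A mixture over integration outcome classes
#'
#' @param ... named fractions, e.g. \code{hiti_forward = 0.95,
#'   itr_retained_forward = 0.05}; classes not named get 0.
#' @return named numeric vector over all classes, validated to be
#'   nonnegative and to sum to 1 within 1e-9.
#' @export
outcome_mixture <- function(...) {
  frac <- c(...)
  if (is.null(names(frac)) || any(names(frac) == ""))
    stop("mixture fractions must be named by outcome class")
  unknown <- setdiff(names(frac), outcome_classes())
  if (length(unknown))
    stop("unknown outcome class(es): ", paste(unknown, collapse = ", "))
  out <- setNames(numeric(length(outcome_classes())), outcome_classes())
  out[names(frac)] <- as.numeric(frac)
  if (any(out < 0)) stop("mixture fractions must be nonnegative")
  if (abs(sum(out) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(out), ")")
  structure(out, class = c("OutcomeMixture", class(out)))
}

#' Default mixtures for the three sequencing experiments
#'
#' Long-read junction libraries carry a small fraction of reads with
#' retained ITRs (defaults 1.4\% at the 5' junction, 3\% at the 3'
#' junction); the short-read 5' junction library carries 9.8\%; the
#' indel-quantification amplicon library is dominated by unedited and
#' small-indel reads (~30\% indels) with ~1\% vector-fragment capture,
#' mostly ITR.
#'
#' @param itr_fraction fraction of ITR-retained outcomes.
#' @return an \code{OutcomeMixture}.
#' @export
mixture_long_read <- function(itr_fraction = 0.014) {
  outcome_mixture(hiti_forward = 1 - itr_fraction,
                  itr_retained_forward = itr_fraction)
}

#' @rdname mixture_long_read
#' @export
mixture_short_read <- function(itr_fraction = 0.098) {
  outcome_mixture(hiti_forward = 1 - itr_fraction,
                  itr_retained_forward = itr_fraction)
}

#' @rdname mixture_long_read
#' @param indel_fraction fraction of small-indel reads.
#' @param capture_fraction fraction of vector-fragment capture reads
#'   (split 70/30 between donor-ITR and nuclease-vector fragments).
#' @export
mixture_amplicon <- function(indel_fraction = 0.30,
                             capture_fraction = 0.01) {
  outcome_mixture(unedited = 1 - indel_fraction - capture_fraction,
                  nhej_indel = indel_fraction,
                  itr_fragment_capture = 0.7 * capture_fraction,
                  cas9_fragment_capture = 0.3 * capture_fraction)
}

#' A sequencing error profile
#'
#' Per-base substitution / insertion / deletion rates plus the read-length
#' model: long mode reads span the full junction amplicon, short mode
#' reads are fixed-length fragments.  The defaults are simple documented
#' placeholders, not estimates of any particular instrument run.
#'
#' @param platform \code{"long"} or \code{"short"}.
#' @param sub,ins,del per-base error rates, each in [0, 0.5).
#' @param read_length fragment length for short mode.
#' @param quality constant Phred quality assigned to every base.
#' @return an \code{ErrorProfile}.
#' @export
error_profile <- function(platform = c("long", "short"), sub = NULL,
                          ins = NULL, del = NULL, read_length = 200L,
                          quality = NULL) {
  platform <- match.arg(platform)
  defaults <- if (platform == "long")
    list(sub = 0.02, ins = 0.005, del = 0.01, quality = 12L)
  else
    list(sub = 0.001, ins = 0, del = 0, quality = 30L)
  p <- list(platform = platform,
            sub = if (is.null(sub)) defaults$sub else sub,
            ins = if (is.null(ins)) defaults$ins else ins,
            del = if (is.null(del)) defaults$del else del,
            read_length = as.integer(read_length),
            quality = if (is.null(quality)) defaults$quality else quality)
  rates <- c(p$sub, p$ins, p$del)
  if (any(rates < 0 | rates >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  structure(p, class = "ErrorProfile")
}

#' @rdname error_profile
#' @export
error_free_profile <- function(platform = c("long", "short"),
                               read_length = 200L) {
  error_profile(match.arg(platform), sub = 0, ins = 0, del = 0,
                read_length = read_length)
}

## truncated geometric on 1..max with success probability p
rindel_len <- function(p, max) {
  probs <- p * (1 - p)^(0:(max - 1L))
  sample.int(max, 1L, prob = probs)
}

#' Per-class allele simulation parameters
#'
#' @param indel_p,indel_max truncated-geometric law for small indel
#'   lengths (support 1..\code{indel_max}).
#' @param frag_min,frag_max uniform length range for captured vector
#'   fragments.
#' @param itr_context how far (bases) an ITR-captured fragment may extend
#'   beyond the repeat into flanking vector sequence; keeps the class
#'   ITR-dominated.
#' @param large_min,large_max length range for large deletions and
#'   inversions (201 bases up to 35 kb, clipped to the locus allowance).
#' @param nuclease_vector nuclease vector model (see
#'   \code{\link{make_nuclease_vector}}), required for
#'   \code{cas9_fragment_capture}.
#' @return parameter list for \code{\link{simulate_allele}}.
#' @export
allele_params <- function(indel_p = 0.3, indel_max = 20L,
                          frag_min = 10L, frag_max = 145L,
                          itr_context = 20L,
                          large_min = 201L, large_max = 35000L,
                          nuclease_vector = NULL) {
  list(indel_p = indel_p, indel_max = as.integer(indel_max),
       frag_min = as.integer(frag_min), frag_max = as.integer(frag_max),
       itr_context = as.integer(itr_context),
       large_min = as.integer(large_min), large_max = as.integer(large_max),
       nuclease_vector = nuclease_vector)
}

#' Simulate one edited allele of a given outcome class
#'
#' Constructs the allele sequence for one outcome class at the cut site:
#' indels of truncated-geometric length (insertions are templated
#' duplications of the flank upstream of the cut), donor-core insertion in
#' either
#' orientation, full-donor (ITR-retained) insertion, vector sub-fragment
#' capture (biased to the ITRs for the ITR class), and large deletions or
#' inversions (uniform length, 201 bases up to 35 kb or what the locus
#' allows).
#'
#' @param class one of \code{\link{outcome_classes}}.
#' @param locus a \code{TargetLocus}.
#' @param donor a \code{DonorConstruct}.
#' @param params list from \code{allele_params()}; supply
#'   \code{nuclease_vector} (see \code{\link{make_nuclease_vector}}) to
#'   simulate \code{cas9_fragment_capture}.
#' @param rng_seed optional seed; if \code{NULL} the current RNG stream is
#'   used (as when called from \code{\link{simulate_alleles}}).
#' @return list with \code{sequence}, \code{class}, \code{junction_5p},
#'   \code{junction_3p} (0-based allele coordinates of the edit
#'   boundaries), and \code{itr_bases} (planted ITR bases in the insert).
#' @export
simulate_allele <- function(class, locus, donor, params = allele_params(),
                            rng_seed = NULL) {
  if (!class %in% outcome_classes()) stop("unknown outcome class: ", class)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cut <- cut_position(locus)
  seq <- locus$sequence
  L <- nchar(seq)
  left <- substr0(seq, 0L, cut)
  right <- substr0(seq, cut, L)
  ins <- NULL; itr_bases <- 0L
  if (class == "unedited") {
    ins <- ""
  } else if (class == "nhej_indel") {
    len <- rindel_len(params$indel_p, params$indel_max)
    if (runif(1) < 0.5) {
      ## NHEJ insertions are modelled as templated duplications of the
      ## sequence immediately 5' of the cut, the predominant repair
      ## signature at blunt double-strand breaks
      ins <- substr0(seq, cut - len, cut)
    } else {
      if (cut + len > L) stop("locus too short for requested deletion")
      right <- substr0(seq, cut + len, L)
      ins <- ""
    }
  } else if (class == "hiti_forward") {
    ins <- donor_core(donor)
  } else if (class == "hiti_reverse") {
    ins <- revcomp(donor_core(donor))
  } else if (class == "itr_retained_forward") {
    ins <- donor$full_sequence
    itr_bases <- nchar(donor$itr$sequence)
  } else if (class == "itr_retained_reverse") {
    ins <- revcomp(donor$full_sequence)
    itr_bases <- nchar(donor$itr$sequence)
  } else if (class %in% c("itr_fragment_capture", "cas9_fragment_capture")) {
    if (class == "itr_fragment_capture") {
      ## fragment overlapping an ITR by at least 10 bases; it may extend
      ## up to itr_context bases into the flanking vector sequence, as
      ## captured vector ends do, but stays ITR-dominated
      src <- donor$full_sequence
      iv <- donor_itr_intervals(donor)
      iv <- iv[sample.int(nrow(iv), 1L), ]
      ctx <- params$itr_context
      w_lo <- max(0L, iv$start - ctx)
      w_hi <- min(nchar(src), iv$end + ctx)
      len <- sample(params$frag_min:min(params$frag_max, w_hi - w_lo), 1L)
      anchor <- min(10L, len)
      lo <- max(w_lo, iv$start - (len - anchor))
      hi <- min(w_hi - len, iv$end - anchor)
      fstart <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      itr_bases <- min(fstart + len, iv$end) - max(fstart, iv$start)
    } else {
      nv <- params$nuclease_vector
      if (is.null(nv))
        stop("cas9_fragment_capture needs params$nuclease_vector")
      src <- nv$sequence
      iv <- data.frame(start = nv$itr_intervals$end[1L],
                       end = nv$itr_intervals$start[2L])
      span <- iv$end - iv$start
      len <- sample(params$frag_min:min(params$frag_max, span), 1L)
      fstart <- iv$start + sample.int(span - len + 1L, 1L) - 1L
    }
    frag <- substr0(src, fstart, fstart + len)
    if (runif(1) < 0.5) frag <- revcomp(frag)
    ins <- frag
  } else { # large_deletion / large_inversion
    allowance <- L - cut - 1L
    if (allowance < params$large_min)
      stop("locus too short for a large deletion/inversion (allowance ",
           allowance, " < ", params$large_min, ")")
    len <- sample(params$large_min:min(params$large_max, allowance), 1L)
    if (class == "large_deletion") {
      right <- substr0(seq, cut + len, L)
      ins <- ""
    } else {
      ins <- revcomp(substr0(seq, cut, cut + len))
      right <- substr0(seq, cut + len, L)
    }
  }
  list(sequence = paste0(left, ins, right), class = class,
       junction_5p = cut, junction_3p = cut + nchar(ins),
       itr_bases = as.integer(itr_bases))
}

#' Simulate a population of alleles from an outcome mixture
#'
#' Classes are drawn i.i.d. from the mixture (a multinomial at the
#' population level), then each allele is constructed by
#' \code{\link{simulate_allele}}.
#'
#' @param n number of alleles.
#' @param mixture an \code{OutcomeMixture}.
#' @param locus,donor,params as in \code{\link{simulate_allele}}.
#' @param seed top-level seed.
#' @return list with \code{sequences} (character vector) and \code{truth}
#'   (data frame: allele_id, class, junction_5p, junction_3p, itr_bases).
#' @export
simulate_alleles <- function(n, mixture, locus, donor,
                             params = allele_params(), seed = 1L) {
  stopifnot(inherits(mixture, "OutcomeMixture"), n >= 1L)
  set.seed(derive_seed(seed, "alleles"))
  classes <- sample(names(mixture), n, replace = TRUE, prob = as.numeric(mixture))
  sims <- lapply(classes, simulate_allele, locus = locus, donor = donor,
                 params = params)
  truth <- data.frame(
    allele_id = sprintf("allele_%06d", seq_len(n)),
    class = classes,
    junction_5p = vapply(sims, `[[`, 0, "junction_5p"),
    junction_3p = vapply(sims, `[[`, 0, "junction_3p"),
    itr_bases = vapply(sims, `[[`, 0L, "itr_bases"),
    stringsAsFactors = FALSE)
  list(sequences = vapply(sims, `[[`, "", "sequence"), truth = truth)
}

#' PCR length-bias sampling weights
#'
#' Weight proportional to \code{exp(-lambda * length)}: shorter templates
#' amplify better.  \code{lambda = 0} (the default everywhere) disables the
#' bias and returns uniform weights.
#'
#' @param alleles character vector of allele sequences, or numeric lengths.
#' @param lambda per-base decay, \code{>= 0}.
#' @return numeric weights summing to 1.
#' @export
apply_pcr_bias <- function(alleles, lambda = 0) {
  if (lambda < 0) stop("lambda must be >= 0")
  len <- if (is.numeric(alleles)) alleles else nchar(alleles)
  w <- exp(-lambda * (len - min(len))) # shift for numerical stability
  w / sum(w)
}

## apply per-base substitution / insertion / deletion errors to one read
apply_errors <- function(seq, sub, ins, del) {
  n <- nchar(seq)
  if (n == 0L || (sub == 0 && ins == 0 && del == 0)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  u <- runif(n)
  is_sub <- u < sub
  is_del <- u >= sub & u < sub + del
  is_ins <- u >= sub + del & u < sub + del + ins
  if (any(is_sub)) {
    alt <- c("A", "C", "G", "T")
    chars[is_sub] <- vapply(chars[is_sub], function(b)
      sample(setdiff(alt, b), 1L), "")
  }
  if (any(is_ins))
    chars[is_ins] <- paste0(chars[is_ins],
                            sample(c("A", "C", "G", "T"),
                                   sum(is_ins), replace = TRUE))
  if (any(is_del)) chars[is_del] <- ""
  paste(chars, collapse = "")
}

#' Simulate sequencing reads from alleles
#'
#' Long mode: one read per sampled allele spanning the full junction
#' amplicon (\code{flank_up} bases upstream of the 5' junction through the
#' whole insert to \code{flank_down} bases downstream of the 3' junction,
#' clipped to the allele), with the 24-nt barcode prepended before strand
#' flipping and errors.  Short mode: fixed-length fragments
#' placed uniformly such that the 5' junction is covered with at least
#' \code{min_overlap} bases on each side; no barcode.  Random read strand
#' in both modes; constant quality per platform.
#'
#' @param sim result of \code{\link{simulate_alleles}}.
#' @param profile an \code{ErrorProfile}.
#' @param n_reads number of reads (> 0).
#' @param seed top-level seed.
#' @param side \code{"5p"} or \code{"3p"}: which junction the library spans.
#' @param barcode 24-nt sample barcode (long mode; \code{NULL} for none).
#' @param barcode_id label written to the truth table.
#' @param flank_up,flank_down amplicon extent around the junction in long
#'   mode.
#' @param min_overlap minimum bases on each side of the junction in short
#'   mode; the default 50 emulates junction amplicon fragments that carry
#'   enough anchor sequence to be mappable (the downstream two-stage ITR
#'   quantification requires 50 aligned bases) and to span the
#'   indel-evaluation window.
#' @param pcr_lambda PCR length-bias decay passed to
#'   \code{\link{apply_pcr_bias}}.
#' @return list with \code{reads} (data frame: read_id, sequence, quality)
#'   and \code{truth} (one row per read: read_id, allele_id, class,
#'   barcode_id, strand, read_start in allele coordinates, junction
#'   coordinates, itr_bases).
#' @export
simulate_reads <- function(sim, profile, n_reads, seed = 1L,
                           side = c("5p", "3p"), barcode = NULL,
                           barcode_id = "sample1",
                           flank_up = 1000L, flank_down = 1000L,
                           min_overlap = 50L, pcr_lambda = 0) {
  side <- match.arg(side)
  stopifnot(inherits(profile, "ErrorProfile"))
  if (n_reads <= 0L) stop("n_reads must be > 0")
  if (profile$platform == "long" && !is.null(barcode)) {
    barcode <- norm_dna(barcode, "barcode")
    if (nchar(barcode) != 24L) stop("barcode must be 24 nt in long mode")
  }
  set.seed(derive_seed(seed, paste0("reads_", side)))
  n_alleles <- length(sim$sequences)
  w <- apply_pcr_bias(sim$sequences, pcr_lambda)
  idx <- sample.int(n_alleles, n_reads, replace = TRUE, prob = w)
  jc <- if (side == "5p") sim$truth$junction_5p else sim$truth$junction_3p
  reads <- character(n_reads); strands <- character(n_reads)
  starts <- integer(n_reads)
  for (k in seq_len(n_reads)) {
    i <- idx[k]
    a <- sim$sequences[i]
    j <- jc[i]
    if (profile$platform == "long") {
      ## the junction PCR product spans the whole insert plus locus
      ## flanks, so the amplicon runs from upstream of the 5' junction to
      ## downstream of the 3' one
      s <- max(0L, sim$truth$junction_5p[i] - flank_up)
      e <- min(nchar(a), sim$truth$junction_3p[i] + flank_down)
      frag <- substr0(a, s, e)
      if (!is.null(barcode)) frag <- paste0(barcode, frag)
    } else {
      len <- profile$read_length
      lo <- max(0L, j - len + min_overlap)
      hi <- min(nchar(a) - len, j - min_overlap)
      if (hi < lo) hi <- lo
      s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      frag <- substr0(a, s, s + len)
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") frag <- revcomp(frag)
    reads[k] <- apply_errors(frag, profile$sub, profile$ins, profile$del)
    strands[k] <- strand
    starts[k] <- s
  }
  qual_char <- rawToChar(as.raw(33L + profile$quality))
  reads_df <- data.frame(
    read_id = sprintf("read_%06d", seq_len(n_reads)),
    sequence = reads,
    quality = vapply(nchar(reads), function(n)
      paste(rep(qual_char, n), collapse = ""), ""),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = reads_df$read_id,
    allele_id = sim$truth$allele_id[idx],
    class = sim$truth$class[idx],
    barcode_id = if (is.null(barcode)) NA_character_ else barcode_id,
    strand = strands,
    read_start = starts,
    junction_5p = sim$truth$junction_5p[idx],
    junction_3p = sim$truth$junction_3p[idx],
    itr_bases = sim$truth$itr_bases[idx],
    side = side,
    stringsAsFactors = FALSE)
  list(reads = reads_df, truth = truth)
}

#' Write / read FASTQ (Sanger Phred+33)
#'
#' @param reads data frame with read_id, sequence, quality.
#' @param path FASTQ file.
#' @return invisibly the path; \code{read_fastq} returns the data frame.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record at index ",
         length(lines) %/% 4L + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  for (k in seq_len(n)) {
    b <- (k - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@") || !startsWith(lines[b + 3L], "+") ||
        nchar(lines[b + 2L]) != nchar(lines[b + 4L]))
      stop("malformed FASTQ record at index ", k)
  }
  ## Biostrings warns about dropped metadata columns on plain FASTQ input
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             sequence = as.character(set),
             quality = as.character(Biostrings::quality(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read the truth sidecar (TSV with header)
#'
#' @param truth truth data frame.
#' @param path TSV file.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
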