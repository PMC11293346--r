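## Ready-made study-shaped constructs.  The locus is a random surrogate for
## the targeted intron (real genomic coordinates are out of scope); the
## guide is the published albumin intron-13 protospacer, embedded at a
## chosen position.  Two construct scales are provided: "full" mirrors the
## ~2 kb donor of a typical HITI vector, "toy" keeps every element short so
## alignment-heavy tests stay fast.

#' The albumin intron-13 protospacer used throughout examples
#' @return 20-nt character scalar.
#' @export
alb_protospacer <- function() "GTATTTAATAGGCAGCAGTG"

#' Build a surrogate target locus with the guide embedded
#'
#' Generates a random intron-like locus and splices protospacer+PAM in at
#' the requested position, so that the blunt cut falls at \code{cut_at}.
#'
#' @param length locus length in bases.
#' @param cut_at desired cut coordinate (0-based).
#' @param seed RNG seed (the locus is deterministic given the seed).
#' @param protospacer,pam guide sequence; PAM defaults to AGG (the paper
#'   prints only the protospacer).
#' @return a \code{TargetLocus}.
#' @export
surrogate_locus <- function(length = 5000L, cut_at = 2500L, seed = 101L,
                            protospacer = alb_protospacer(), pam = "AGG") {
  set.seed(seed)
  start <- cut_at - 17L
  if (start < 0L || start + 23L > length)
    stop("cut_at leaves no room for the guide site")
  bg <- random_dna(length)
  seq <- paste0(substr0(bg, 0L, start), protospacer, pam,
                substr0(bg, start + 23L, length))
  g <- guide_site(protospacer, pam, "+", start)
  target_locus(seq, g, label = "mAlb_intron13_surrogate")
}

## exact T2A peptide EGRGSLLTCGDVEENPGP, ends at the G^P skipping boundary
t2a_cds <- function() {
  "GAAGGCAGAGGCAGCCTGCTGACCTGCGGCGACGTGGAGGAGAACCCCGGCCCC"
}

#' Example HITI donor payloads
#'
#' \code{"full"} approximates the element sizes of a dsRed HITI donor
#' (splice acceptor, trapped exon 14, T2A, ~0.7 kb CDS, pA, U6-gRNA
#' cassette; ~1.6 kb payload, ~2 kb donor with ITRs); \code{"toy"} keeps
#' every element tens of bases for fast tests.  The T2A element is the real
#' 54-nt peptide sequence in both scales so that product prediction works.
#'
#' @param scale \code{"full"} or \code{"toy"}.
#' @param seed RNG seed for the filler sequences.
#' @return named list of element sequences, in donor order.
#' @export
example_payload <- function(scale = c("full", "toy"), seed = 102L) {
  scale <- match.arg(scale)
  set.seed(seed)
  sizes <- if (scale == "full")
    c(sas = 150L, exon14 = 201L, cds = 678L, pa = 225L, u6_grna = 351L)
  else
    c(sas = 12L, exon14 = 18L, cds = 30L, pa = 12L, u6_grna = 21L)
  filler <- lapply(sizes, random_dna)
  ## CDS begins with ATG and stays in frame
  filler$cds <- paste0("ATG", substr(filler$cds, 4L, sizes[["cds"]]))
  list(sas = filler$sas, exon14 = filler$exon14, t2a = t2a_cds(),
       cds = filler$cds, pa = filler$pa, u6_grna = filler$u6_grna)
}

#' A complete example HITI experiment
#'
#' Bundles a surrogate locus, a donor built from \code{\link{example_payload}},
#' and the junction reference set, all deterministic given the seed.
#'
#' @param scale construct scale, see \code{\link{example_payload}}.
#' @param seed RNG seed for the surrogate sequences.
#' @param flank_locus,flank_donor flanks passed to
#'   \code{\link{build_expected_junctions}}.
#' @param itr the ITR element; defaults to the bundled AAV2 ITR.
#' @return list with \code{locus}, \code{donor}, \code{refs}, \code{itr}.
#' @export
hiti_experiment <- function(scale = c("full", "toy"), seed = 101L,
                            flank_locus = 250L, flank_donor = 250L,
                            itr = aav2_itr()) {
  scale <- match.arg(scale)
  locus <- surrogate_locus(seed = seed)
  donor <- build_donor(example_payload(scale, seed = seed + 1L),
                       locus$guide, itr)
  refs <- build_expected_junctions(locus, donor, flank_locus, flank_donor)
  list(locus = locus, donor = donor, refs = refs, itr = itr)
}

#' A surrogate nuclease (SpCas9) vector genome
#'
#' ITR + promoter/nuclease/polyA filler + reverse-complement ITR; used as
#' the second reference when assigning vector origins to captured
#' insertions.
#'
#' @param itr an \code{ItrElement}.
#' @param core_length length of the internal (non-ITR) segment.
#' @param seed RNG seed.
#' @return list with \code{sequence} and \code{itr_intervals} (data frame,
#'   0-based half-open).
#' @export
make_nuclease_vector <- function(itr = aav2_itr(), core_length = 600L,
                                 seed = 103L) {
  set.seed(seed)
  core <- random_dna(core_length)
  len_itr <- nchar(itr$sequence)
  seq <- paste0(itr$sequence, core, revcomp(itr$sequence))
  list(sequence = seq,
       itr_intervals = data.frame(
         label = c("left_itr", "right_itr"),
         start = c(0L, len_itr + core_length),
         end = c(len_itr, len_itr + core_length + len_itr)))
}
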