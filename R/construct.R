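## Construct model: target locus, guide, HITI donor, and the expected
## junction reference sequences for every integration outcome class.
##
## Coordinate conventions (used everywhere in this package):
##  * all coordinates are 0-based, half-open intervals [start, end);
##  * a cut position is the coordinate of the first base 3' of the blunt
##    cut on the + strand;
##  * a junction coordinate is the position where the second segment of a
##    junction reference begins (locus|donor boundary).

#' Describe a SpCas9 guide site on a locus
#'
#' @param protospacer 20-nt protospacer sequence (as read 5'->3' on the
#'   guide strand).
#' @param pam 3-nt PAM, must match the SpCas9 NGG pattern.
#' @param strand \code{"+"} or \code{"-"}: strand of the locus the guide
#'   matches.
#' @param start 0-based coordinate of the leftmost protospacer base on the
#'   + strand of the locus, whichever strand the guide reads from.
#' @param cut_offset bases from the protospacer 5' end to the blunt cut;
#'   17 is the canonical SpCas9 cut 3 nt from the PAM.
#' @return an object of class \code{GuideSite}.
#' @export
guide_site <- function(protospacer, pam = "TGG", strand = "+", start = 0L,
                       cut_offset = 17L) {
  protospacer <- norm_dna(protospacer, "protospacer")
  pam <- norm_dna(pam, "pam")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  if (!grepl("^[ACGT]GG$", pam))
    stop("pam must match the NGG pattern, got ", pam)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (cut_offset < 0L || cut_offset > 20L)
    stop("cut_offset must lie in [0, 20]")
  structure(list(protospacer = protospacer, pam = pam, strand = strand,
                 start = as.integer(start),
                 cut_offset = as.integer(cut_offset)),
            class = "GuideSite")
}

#' A target locus with its guide
#'
#' Validates that protospacer + PAM occur at the stated coordinate and
#' strand.  On the + strand the protospacer occupies
#' \code{[start, start+20)} and the PAM \code{[start+20, start+23)}; on the
#' - strand the protospacer occupies the same + strand interval (read in
#' reverse complement) and the PAM sits at \code{[start-3, start)}.
#'
#' @param sequence locus DNA (an intron surrogate is fine for testing).
#' @param guide a \code{GuideSite}.
#' @param label free-text name.
#' @return an object of class \code{TargetLocus}.
#' @export
target_locus <- function(sequence, guide, label = "locus") {
  sequence <- norm_dna(sequence, "locus sequence")
  stopifnot(inherits(guide, "GuideSite"))
  s <- guide$start
  L <- nchar(sequence)
  site <- paste0(guide$protospacer, guide$pam)
  if (guide$strand == "+") {
    if (s < 0L || s + 23L > L)
      stop("guide does not fit on the locus at start=", s)
    found <- substr0(sequence, s, s + 23L)
  } else {
    if (s - 3L < 0L || s + 20L > L)
      stop("guide does not fit on the locus at start=", s)
    found <- revcomp(substr0(sequence, s - 3L, s + 20L))
  }
  if (found != site)
    stop("protospacer+PAM not found at (start=", s, ", strand=",
         guide$strand, "): expected ", site, ", found ", found)
  structure(list(sequence = sequence, guide = guide, label = label),
            class = "TargetLocus")
}

#' Blunt-cut coordinate of a guide on its locus
#'
#' Returns the 0-based + strand coordinate of the first base 3' of the
#' blunt SpCas9 cut.  For a + strand guide this is \code{start +
#' cut_offset}; for a - strand guide the cut mirrors to \code{start + 20 -
#' cut_offset}.
#'
#' @param locus a \code{TargetLocus}.
#' @return integer coordinate.
#' @export
cut_position <- function(locus) {
  stopifnot(inherits(locus, "TargetLocus"))
  g <- locus$guide
  if (g$strand == "+") g$start + g$cut_offset else g$start + 20L - g$cut_offset
}

#' An inverted terminal repeat element
#'
#' @param sequence ITR DNA; the canonical AAV2 ITR ships with the package
#'   (see \code{\link{aav2_itr}}), but any nonempty sequence is accepted so
#'   tests can use short toy ITRs.
#' @param label free-text name.
#' @return an object of class \code{ItrElement}.
#' @export
itr_element <- function(sequence, label = "ITR") {
  structure(list(sequence = norm_dna(sequence, "ITR sequence"),
                 label = label),
            class = "ItrElement")
}

#' The canonical AAV2 inverted terminal repeat
#'
#' 145-nt AAV serotype 2 ITR (flip orientation) bundled as a FASTA data
#' file.
#'
#' @return an \code{ItrElement}.
#' @export
aav2_itr <- function() {
  path <- system.file("extdata", "aav2_itr.fa", package = "hitiseq",
                      mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(path)
  itr_element(as.character(seqs[[1L]]), names(seqs)[1L])
}

#' Assemble a HITI donor construct
#'
#' Lays out the AAV-HITI donor genome: left ITR, left inverted target site,
#' the payload elements (splice acceptor, trapped exon, T2A, transgene CDS,
#' polyadenylation signal, U6-gRNA cassette), right inverted target site,
#' right ITR.  Both inverted target sites are the reverse complement of
#' protospacer+PAM, so the nuclease releases the cassette and forward
#' integration destroys the site.  The right ITR is stored as the reverse
#' complement of the supplied ITR, mirroring the opposed orientation of the
#' two ends of an AAV genome.
#'
#' @param payload named ordered list/character vector of element sequences;
#'   conventionally \code{sas}, \code{exon14}, \code{t2a}, \code{cds},
#'   \code{pa}, \code{u6_grna}, but any nonempty set of labels is accepted.
#' @param guide the \code{GuideSite} whose inverted site flanks the cassette.
#' @param itr an \code{ItrElement}.
#' @return an object of class \code{DonorConstruct}: a list with an
#'   \code{elements} data frame (label, sequence, start, end; 0-based
#'   half-open, tiling the construct) and \code{full_sequence}.
#' @export
build_donor <- function(payload, guide, itr) {
  stopifnot(inherits(guide, "GuideSite"), inherits(itr, "ItrElement"))
  payload <- as.list(payload)
  if (length(payload) == 0L) stop("payload must contain at least one element")
  if (is.null(names(payload)) || any(names(payload) == ""))
    stop("payload elements must be named")
  nm <- names(payload)
  payload <- lapply(seq_along(payload), function(i)
    norm_dna(payload[[i]], paste0("payload element '", nm[i], "'"),
             allow_empty = TRUE))
  names(payload) <- nm
  inv_site <- revcomp(paste0(guide$protospacer, guide$pam))
  labels <- c("left_itr", "left_inverted_site", names(payload),
              "right_inverted_site", "right_itr")
  seqs <- c(itr$sequence, inv_site, unlist(payload), inv_site,
            revcomp(itr$sequence))
  lens <- nchar(seqs)
  end <- cumsum(lens)
  start <- end - lens
  elements <- data.frame(label = labels, sequence = unname(seqs),
                         start = as.integer(start), end = as.integer(end),
                         stringsAsFactors = FALSE)
  structure(list(elements = elements,
                 full_sequence = paste(seqs, collapse = ""),
                 guide = guide, itr = itr),
            class = "DonorConstruct")
}

## payload element names fixed by build_donor
donor_element <- function(donor, label) {
  i <- match(label, donor$elements$label)
  if (is.na(i)) stop("donor has no element labelled '", label, "'")
  donor$elements[i, , drop = FALSE]
}

#' Cut points of the inverted target sites on the donor
#'
#' Each inverted site is revcomp(protospacer+PAM), i.e. the guide matches
#' the donor - strand with its protospacer occupying donor coordinates
#' \code{[s+3, s+23)}.  Mirroring the blunt-cut convention, the cut lands
#' at \code{s + 23 - cut_offset} (6 nt into the site for the canonical
#' offset 17).
#'
#' @param donor a \code{DonorConstruct}.
#' @return integer vector \code{c(left, right)} of donor cut coordinates.
#' @export
donor_cut_points <- function(donor) {
  stopifnot(inherits(donor, "DonorConstruct"))
  off <- 23L - donor$guide$cut_offset
  left <- donor_element(donor, "left_inverted_site")$start + off
  right <- donor_element(donor, "right_inverted_site")$start + off
  c(left = left, right = right)
}

#' The donor core released by nuclease cleavage
#'
#' The segment between the two inverted-site cut points: what remains of
#' the cassette after Cas9 cleaves both inverted target sites, and hence
#' the unit integrated in a forward or reverse HITI event.
#'
#' @param donor a \code{DonorConstruct}.
#' @return character scalar.
#' @export
donor_core <- function(donor) {
  cp <- donor_cut_points(donor)
  substr0(donor$full_sequence, cp[["left"]], cp[["right"]])
}

#' Annotated ITR intervals of a donor or vector sequence
#'
#' @param donor a \code{DonorConstruct}.
#' @return data frame (label, start, end), 0-based half-open.
#' @export
donor_itr_intervals <- function(donor) {
  el <- donor$elements
  el[el$label %in% c("left_itr", "right_itr"), c("label", "start", "end")]
}

#' Write donor element annotation as BED
#'
#' Four-column BED (0-based half-open, as BED requires) of the element
#' intervals on donor coordinates.
#'
#' @param donor a \code{DonorConstruct}.
#' @param path output file.
#' @param chrom name used in the chrom column.
#' @return invisibly, the path.
#' @export
write_donor_bed <- function(donor, path, chrom = "donor") {
  bed <- data.frame(chrom = chrom, start = donor$elements$start,
                    end = donor$elements$end, name = donor$elements$label)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Expected junction reference sequences for every outcome class
#'
#' Builds, for each side of the integration site, the reference amplicon a
#' read from that outcome class should match:
#' \itemize{
#'   \item \code{hiti_forward}: locus up to the cut joined to the donor
#'     core (cassette released by cleavage) in the forward orientation;
#'   \item \code{hiti_reverse}: donor core in reverse-complement
#'     orientation;
#'   \item \code{itr_retained_forward}/\code{_reverse}: the full donor
#'     including ITRs, i.e. integration of the uncleaved vector genome;
#'   \item \code{unedited}: the locus spanning the cut.
#' }
#' References are truncated to \code{flank_locus} bases of locus sequence
#' and \code{flank_donor} bases of donor-derived sequence around the
#' junction, so alignment cost scales with the window of interest rather
#' than with construct size.
#'
#' @param locus a \code{TargetLocus}.
#' @param donor a \code{DonorConstruct} built with the same guide.
#' @param flank_locus locus bases kept on the locus side of each junction.
#' @param flank_donor donor bases kept on the donor side.
#' @return a \code{JunctionRefSet}: data frame (label, side, class,
#'   sequence, junction_coord) with uniqueness of labels enforced;
#'   junction_coord is the 0-based position where the second segment
#'   begins.  Attributes carry the ITR interval of the retained-ITR
#'   references for window anchoring.
#' @export
build_expected_junctions <- function(locus, donor, flank_locus = 250L,
                                     flank_donor = 250L) {
  stopifnot(inherits(locus, "TargetLocus"), inherits(donor, "DonorConstruct"))
  cut <- cut_position(locus)
  L <- nchar(locus$sequence)
  if (cut < 0L || cut > L) stop("cut position lies outside the locus")
  up <- substr0(locus$sequence, max(0L, cut - flank_locus), cut)
  down <- substr0(locus$sequence, cut, min(L, cut + flank_locus))
  core <- donor_core(donor)
  full <- donor$full_sequence
  take_head <- function(x) substr0(x, 0L, min(nchar(x), flank_donor))
  take_tail <- function(x) substr0(x, max(0L, nchar(x) - flank_donor), nchar(x))

  classes <- c("hiti_forward", "hiti_reverse",
               "itr_retained_forward", "itr_retained_reverse")
  donor_5p <- c(take_head(core), take_head(revcomp(core)),
                take_head(full), take_head(revcomp(full)))
  donor_3p <- c(take_tail(core), take_tail(revcomp(core)),
                take_tail(full), take_tail(revcomp(full)))

  refs <- rbind(
    data.frame(label = paste0(classes, "_5p"), side = "5p", class = classes,
               sequence = paste0(up, donor_5p),
               junction_coord = nchar(up), stringsAsFactors = FALSE),
    data.frame(label = paste0(classes, "_3p"), side = "3p", class = classes,
               sequence = paste0(donor_3p, down),
               junction_coord = nchar(donor_3p), stringsAsFactors = FALSE),
    data.frame(label = c("unedited_5p", "unedited_3p"),
               side = c("5p", "3p"), class = "unedited",
               sequence = paste0(up, down),
               junction_coord = nchar(up), stringsAsFactors = FALSE))
  bad <- refs$junction_coord <= 0L | refs$junction_coord >= nchar(refs$sequence)
  if (any(bad))
    stop("degenerate junction reference(s): ",
         paste(refs$label[bad], collapse = ", "),
         " (flanks too small or cut at locus edge)")
  stopifnot(!anyDuplicated(refs$label))
  structure(refs, class = c("JunctionRefSet", "data.frame"),
            cut = cut, flank_locus = flank_locus, flank_donor = flank_donor,
            itr = donor$itr$sequence)
}

#' Write / read a junction reference set as FASTA
#'
#' One record per reference; the header is
#' \code{label|side|class|junction_coord} so the set round-trips.
#'
#' @param refs a \code{JunctionRefSet}.
#' @param path FASTA file.
#' @return invisibly the path, or the re-read \code{JunctionRefSet}.
#' @export
write_junction_fasta <- function(refs, path) {
  set <- Biostrings::DNAStringSet(refs$sequence)
  names(set) <- paste(refs$label, refs$side, refs$class, refs$junction_coord,
                      sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_junction_fasta
#' @export
read_junction_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  refs <- data.frame(label = vapply(parts, `[`, "", 1L),
                     side = vapply(parts, `[`, "", 2L),
                     class = vapply(parts, `[`, "", 3L),
                     sequence = as.character(set),
                     junction_coord = as.integer(vapply(parts, `[`, "", 4L)),
                     stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  structure(refs, class = c("JunctionRefSet", "data.frame"))
}

#' Protein products of the integrated fusion transcript
#'
#' A productive integration yields a single fusion transcript; ribosomal
#' skipping at the T2A glycine-proline boundary releases an upstream
#' product ending at the glycine (the tagged endogenous protein) and a
#' downstream product that starts with the proline left on the transgene's
#' N terminus.
#'
#' @param donor a \code{DonorConstruct} containing \code{t2a} and
#'   \code{cds} payload elements.
#' @return list with \code{upstream} and \code{downstream} amino-acid
#'   strings.
#' @export
predict_processed_products <- function(donor) {
  stopifnot(inherits(donor, "DonorConstruct"))
  if (!"t2a" %in% donor$elements$label)
    stop("donor has no T2A element; cannot predict skipping products")
  t2a_aa <- translate_dna(donor_element(donor, "t2a")$sequence)
  if (!grepl("GP$", t2a_aa))
    stop("T2A element does not translate to a ...G^P boundary: ", t2a_aa)
  cds <- if ("cds" %in% donor$elements$label)
    donor_element(donor, "cds")$sequence else ""
  list(upstream = sub("P$", "", t2a_aa),
       downstream = paste0("P", translate_dna(cds)))
}
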