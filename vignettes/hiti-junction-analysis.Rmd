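---
title: "Classifying AAV-HITI integration outcomes from junction reads"
author: "hitiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying AAV-HITI integration outcomes from junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitiseq)
```

## The problem

Homology-independent targeted integration (HITI) knocks a promoter-less
donor cassette into a CRISPR-Cas9 cut site using non-homologous end
joining (NHEJ).  The donor travels as an AAV vector genome, flanked by the
vector's ~145-nt inverted terminal repeats (ITRs), and carries the guide's
own target site at each extremity in *inverted* orientation, so that the
nuclease releases the cassette from the vector and forward integration
destroys the site.  Sequencing PCR products that span the locus/donor
junctions reveals a spectrum of outcomes:

* the intended forward integration of the *released* cassette
  (`hiti_forward` → read call `hiti_clean`);
* integration in the reverse orientation (`hiti_reverse` →
  `reverse_orientation`);
* integration of the whole vector genome with ITRs still attached
  (`itr_retained_*` → `itr_containing`);
* capture of vector sub-fragments, mostly ITR ends
  (`itr_fragment_capture`, `cas9_fragment_capture`);
* small indels without integration (`nhej_indel`), the unedited locus,
  and large (>200 bp, up to 35 kb) deletions or inversions.

The package models the constructs, simulates junction reads from a stated
outcome mixture with a truth sidecar, demultiplexes barcoded long reads,
classifies reads at both junctions, quantifies amplicon indels, assigns
vector origins to captured insertions, and aggregates the results,
including the arithmetic that reconciles integration-event fractions with
transgene-positive cell counts (e.g. 19.7% + 14.5% = 34.2% ITR-free
events; 48% of those productive gives 16.4%).

## Coordinates and constructs

All coordinates are 0-based half-open; a cut position is the first base 3'
of the blunt cut on the + strand; a junction coordinate is the first base
of the second segment of a junction reference.  SpCas9 is modelled as a
blunt cutter 3 nt from the PAM (`cut_offset = 17`), the canonical
behaviour.

The donor stores both inverted target sites as
`revcomp(protospacer + PAM)`.  Mirroring the blunt-cut rule, the donor-side
cut falls 6 nt into each site (`site_start + 23 - cut_offset`), so the
released core keeps a 17-nt residual of the left site and a 6-nt residual
of the right one.  The base-level layout of the residuals is not published
for this construct family; this convention is the package's own, recorded
here, and every downstream quantity is computed from it consistently.

Junction references are built per side and outcome class: locus flank up
to the cut joined to the corresponding donor segment (released core,
reverse-complemented core, or full donor including ITRs), plus the
unedited amplicon.  References are truncated to configurable flanks
(`flank_locus`, `flank_donor`) so alignment cost scales with the window of
interest, not construct size.

Because the real locus coordinates are out of scope, the locus is a
random surrogate with the published 20-nt albumin intron-13 protospacer
spliced in; the PAM is set to AGG (only the protospacer is printed in the
source material).  The bundled ITR is the canonical 145-nt AAV2 repeat.

## Alignment

One affine-gap kernel (Rcpp) drives everything: semi-global ("overlap",
end gaps free in both sequences) for read-to-reference alignment, local
(Smith-Waterman) for ITR detection and origin assignment, and an infix
edit-distance for barcodes.  Scores are match +2, mismatch -4, gap open
-4, gap extend -2, with a length-L gap costing `open + L * ext` — the
same parameterisation as `Biostrings::pairwiseAlignment`, which the test
suite uses as an independent cross-check, alongside a plain-R
dynamic-programming oracle.  Two identity flavours are reported:
`identity` (matches over all alignment columns, used as the long-read
assignment floor of 0.7) and `gc_identity` (gap-compressed: matches over
aligned pairs, used with a ≥50 aligned-pairs requirement to exclude
unalignable amplicon reads — a genuine 145-nt insertion in a 200-nt read
should not be "low identity").

## The classifier

For each read, both strands are scored against every reference of the
library's side; the best score wins (ties: forward strand, then reference
order).  Calls follow a fixed precedence:

1. `itr_containing` — a CIGAR insertion of ≥10 nt anchored within ±200 bp
   of the junction whose sequence carries ITR content, or a best-scoring
   ITR-retained reference whose junction-proximal ITR segment is
   confirmed in the read;
2. `reverse_orientation` — a reverse-class reference wins without ITR
   evidence;
3. `nhej_indel` — a qualifying indel overlaps the junction window;
4. `hiti_clean` / `unedited` — the forward / unedited reference wins with
   no qualifying events;
5. `unassigned` — identity below 0.7 or the window not covered.

Two threshold details matter:

* **ITR detection** (`detect_itr_content`): the ">9 bp" rule is read as
  ≥10 ITR bases at ≥90% identity.  The detector aligns the segment
  locally against the ITR and its reverse complement under an error cost
  derived from `min_identity` (every error column costs
  `2·id/(1-id)`, less one integer step so the boundary is inclusive), so
  any positive-scoring alignment automatically satisfies the identity
  floor; `matched_bases` is the ITR bases covered, and
  `min_identity = 1` degenerates to exact substring matching.  The
  detector is only ever applied to insertion segments (padded by 10 read
  bases per side, because equally-scoring alignments can shift an
  insertion by a few bases) and to the junction-proximal segment of
  ITR-retained candidates — never to whole reads, where a ≥10 bp @ 90%
  match against a 145-nt repeat arises by chance in a substantial
  fraction of random 200-nt sequences.
* **Qualifying indels** (`min_indel`): long-read indel noise puts small
  indels in every 400-bp window, so by default only indels of ≥10 nt can
  override the best-reference call.  `strict_thresholds()` lowers this to
  1 for error-free data, where every indel is planted; the exact-recovery
  invariants in the test suite use it.

The per-side summary reports class fractions over classified reads and,
because published percentages do not always state their denominator, the
fraction over all reads including `unassigned` as well.

## The simulator

`simulate_alleles` draws classes i.i.d. from an `outcome_mixture` and
builds each allele at the cut:

* `nhej_indel`: indel length from a truncated geometric (p = 0.3, support
  1–20; configurable) — both values are documented nulls, not estimates.
  Insertions are *templated duplications* of the flank 5' of the cut, the
  dominant NHEJ signature; this also means the only ITR false-positive
  channel is a fixed property of the surrogate sequences (their best
  chance ITR match is 8–9 bases, below the 10-base floor) rather than a
  per-read lottery.
* `itr_fragment_capture`: a 10–145-nt fragment overlapping an ITR by ≥10
  bases, extending at most 20 bases (`itr_context`) into flanking vector
  sequence.  Fragments dominated by vector interior are a different
  outcome (they present as plain insertions or reverse junctions) and are
  covered by `cas9_fragment_capture`, which samples the nuclease-vector
  interior.
* `large_deletion` / `large_inversion`: length uniform on
  [201, min(35 000, locus allowance)].

Long reads span the full junction amplicon — from `flank_up` bases
upstream of the 5' junction through the entire insert to `flank_down`
bases downstream of the 3' junction — matching junction PCR products that
contain the whole integrated donor; the 24-nt barcode is prepended before
random strand flipping and per-base substitution/insertion/deletion
errors (long defaults 2%/0.5%/1%, constant Q12; short defaults 0.1%
substitutions, Q30 — placeholders, not instrument estimates).  Short reads
are fixed-length (200 nt) fragments placed uniformly with ≥50 bases on
each side of the junction (`min_overlap`); 50 matches the two-stage
mapping requirement below, so every simulated read is informative — with
smaller overlaps the measured ITR frequency is censored below the planted
fraction because ITR-dominated reads fail mapping.  One top-level seed
drives everything through per-stage derived seeds; identical inputs and
seed give byte-identical FASTQ, truth sidecars and reports.

What the generator does **not** emulate: homopolymer-structured nanopore
errors, chimeric reads, coverage non-uniformity beyond the exponential
PCR length-bias knob (`apply_pcr_bias`, weight ∝ exp(-λ·length), off by
default), multi-copy or concatemeric integrations, and real genomic
context.  Passing recovery tests therefore demonstrate the procedures'
correctness under the stated error model, not performance on real nanopore
data.

## Demultiplexing

Barcodes are located by minimum edit distance (substitutions *and*
indels — nanopore indel errors make substitution-only matching brittle;
the source protocol says only "mismatches", so this is a deliberate
choice) of the whole barcode against any substring of the first and last
200 bases of the read and of its reverse complement.  A read is assigned
to the unique barcode within 4 edits; ties are never guessed
(`UNASSIGNED`).  The table constructor warns when two barcodes are within
`2 × max_mismatches` edits of each other.

## Amplicon analyses

* `call_amplicon_indels`: a read is *modified* iff an insertion anchor or
  any deleted reference base falls within ±17 bases of the cut;
  substitutions never count (an option restores substitution counting for
  parity with common amplicon tools).
* `classify_insertion_origins`: insertions longer than 10 nt are locally
  aligned against both vector genomes on both strands; the winner is
  sub-labelled `_itr` when its reference interval overlaps an annotated
  ITR.  The two vectors share identical ITRs, so a fragment from inside
  the repeat alone ties and is reported `unknown` rather than guessed;
  attribution requires vector-specific context.  Note also that NHEJ
  duplications of the protospacer region genuinely align to the donor's
  inverted target site and may label `donor_internal` — the ambiguity is
  real, not an artefact.
* `quantify_itr_short_reads`: stage 1 keeps reads mapping to the expected
  junction amplicon locally at ≥0.7 identity over ≥50 columns; stage 2
  tests the read sequence *not explained* by that mapping (unaligned ends
  plus inserted segments) for ITR content.  Testing whole reads instead
  would, by the chance-match argument above, flag a large fraction of all
  reads.  The result is ITR-containing over mapped reads; zero mapped
  reads yield an explicit `NA`.

## Reporting

`aggregate_report` merges the available blocks, validates that every
fraction block sums to 1 (tolerance 1e-9), computes
`itr_free_total` (plain sum of ITR-free integration-event percentages) and
`productive_fraction` (share × total, rendered to one decimal as such
percentages are conventionally printed), and — when simulation truth is
supplied — a confusion matrix of expected calls
(`map_truth_to_call`) against observed calls.  Large deletions and
inversions have no amplifiable junction template and are excluded from the
expected-call map.  JSON serialisation is round-trip stable
(write → read → write is byte-identical).

"Productive" for simulated reads means forward orientation with no
deletion extending from the junction into the splice-acceptor element;
junction indels confined to the intron-derived segment are tolerated
because integration is intronic.  The 48% productive share used in the
worked arithmetic is an input, not something the simulation re-estimates.

## Problem sizes

Tests and the acceptance script use the `"toy"` construct scale (a ~0.5-kb
donor with the real 54-nt T2A element, 200/220-base junction reference
flanks, reads spanning ±210 bases of the junctions) with 2 000–5 000 reads
per experiment; the `"full"` scale (~2-kb donor, full-length amplicons) is
the default for interactive use.  The toy scale keeps a full
simulate–demultiplex–classify–report cycle at a few minutes on one CPU
while leaving every junction window (±200 bp) fully inside the
references.

## Known limitations

* The classifier assumes one integration event per read; multi-copy and
  concatemeric integrations are out of scope.
* The identity floor and window-coverage rule make no attempt to rescue
  reads whose alignment does not span the junction window; they are
  reported `unassigned`, and both denominators are exposed.
* ITR detection thresholds are calibrated to the stated error model; real
  nanopore homopolymer errors inside the GC-rich ITR hairpin may behave
  differently.
* The `unedited` locus and `nhej_indel` classes cannot be distinguished
  from `hiti_clean` by the junction PCR itself in a real experiment
  (unedited templates do not amplify with one primer in the donor); the
  simulator still supports them so the classifier can be exercised on
  mixtures that contain them.
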