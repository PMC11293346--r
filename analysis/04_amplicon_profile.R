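# Stage 4: short-read analyses -- windowed indel quantification at the cut
# (+/- 17 bases), origin assignment of >10-nt insertions, and the
# two-stage short-read ITR frequency.  Writes results/amplicon_profile.json.

source(file.path("analysis", "00_common.R"))

cut <- cut_position(EXPERIMENT$locus)
amp_ref <- substr(EXPERIMENT$locus$sequence, cut - 140 + 1, cut + 145)

reads_amp <- read_fastq(file.path(SIM_DIR, "amplicon.fastq"))
ic <- call_amplicon_indels(reads_amp, amp_ref, 140L)
cat(sprintf("amplicon indels: %.2f%% modified (%d aligned, %d excluded)\n",
            100 * ic$modified_fraction, ic$n_aligned, ic$n_excluded))

ins <- extract_window_insertions(reads_amp, amp_ref, 140L, min_len = 10L)
origins <- if (nrow(ins) > 0) {
  classify_insertion_origins(ins, vector_ref_set(EXPERIMENT$donor, NUCLEASE))
} else character(0)
cat(sprintf(">10-nt insertions: %d (%.2f%% of aligned reads)\n",
            nrow(ins), 100 * nrow(ins) / ic$n_aligned))
if (length(origins)) print(table(origins))

reads_sr <- read_fastq(file.path(SIM_DIR, "short_itr.fastq"))
hiti_ref <- EXPERIMENT$refs$sequence[EXPERIMENT$refs$label == "hiti_forward_5p"]
q <- quantify_itr_short_reads(reads_sr, hiti_ref, EXPERIMENT$itr)
cat(sprintf("short-read ITR frequency: %.2f%% (%d/%d mapped)\n",
            100 * q$frequency, q$n_itr, q$n_mapped))

jsonlite::write_json(
  list(modified_fraction = ic$modified_fraction,
       n_aligned = ic$n_aligned, n_excluded = ic$n_excluded,
       long_insertions = nrow(ins),
       origin_counts = as.list(table(origins)),
       itr_read_fraction = q$frequency,
       n_mapped = q$n_mapped, n_itr = q$n_itr),
  file.path(RESULTS, "amplicon_profile.json"), auto_unbox = TRUE,
  digits = NA)
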