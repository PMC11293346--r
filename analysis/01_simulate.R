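# Stage 1: build the construct models and simulate every sequencing
# library used downstream, with truth sidecars.
#
# Libraries (planted ITR-retained fractions follow the junction-specific
# defaults: 1.4% at the 5' junction, 3% at the 3' junction, 9.8% in the
# short-read library; the indel amplicon plants 29% indels + 1% captures):
#   results/sim/long_5p.fastq / long_3p.fastq  -- barcoded long reads
#   results/sim/short_itr.fastq                -- 5' junction short reads
#   results/sim/amplicon.fastq                 -- indel amplicon reads
# plus *_truth.tsv for each, and the junction reference FASTA / donor BED.

source(file.path("analysis", "00_common.R"))

ex <- EXPERIMENT
cat("locus:", ex$locus$label, nchar(ex$locus$sequence), "bases; cut at",
    cut_position(ex$locus), "\n")
cat("donor:", nchar(ex$donor$full_sequence), "bases;",
    nrow(ex$donor$elements), "elements; core",
    nchar(donor_core(ex$donor)), "bases\n")

write_junction_fasta(ex$refs, file.path(SIM_DIR, "junction_refs.fa"))
write_donor_bed(ex$donor, file.path(SIM_DIR, "donor_elements.bed"))
write_barcode_table(BARCODES, file.path(SIM_DIR, "barcodes.tsv"))

long_lib <- function(side, itr_fraction, stage_seed) {
  sim <- simulate_alleles(N_LONG, mixture_long_read(itr_fraction),
                          ex$locus, ex$donor, seed = stage_seed)
  rd <- simulate_reads(sim, error_profile("long"), n_reads = N_LONG,
                       seed = stage_seed, side = side,
                       barcode = BARCODES$sequences[1],
                       barcode_id = BARCODES$ids[1],
                       flank_up = 210L, flank_down = 210L)
  write_fastq(rd$reads, file.path(SIM_DIR, sprintf("long_%s.fastq", side)))
  write_truth(rd$truth, file.path(SIM_DIR, sprintf("long_%s_truth.tsv", side)))
  cat(sprintf("long %s library: %d reads, %.2f%% ITR-retained planted\n",
              side, N_LONG,
              100 * mean(rd$truth$class == "itr_retained_forward")))
}
long_lib("5p", 0.014, SEED + 101L)
long_lib("3p", 0.030, SEED + 202L)

sim_sr <- simulate_alleles(N_SHORT, mixture_short_read(0.098), ex$locus,
                           ex$donor, seed = SEED + 303L)
rd_sr <- simulate_reads(sim_sr, error_profile("short"), n_reads = N_SHORT,
                        seed = SEED + 303L, side = "5p")
write_fastq(rd_sr$reads, file.path(SIM_DIR, "short_itr.fastq"))
write_truth(rd_sr$truth, file.path(SIM_DIR, "short_itr_truth.tsv"))
cat(sprintf("short-read ITR library: %d reads, %.2f%% ITR-retained planted\n",
            N_SHORT, 100 * mean(rd_sr$truth$class == "itr_retained_forward")))

sim_amp <- simulate_alleles(N_SHORT,
                            mixture_amplicon(indel_fraction = 0.29,
                                             capture_fraction = 0.01),
                            ex$locus, ex$donor,
                            params = allele_params(nuclease_vector = NUCLEASE),
                            seed = SEED + 404L)
rd_amp <- simulate_reads(sim_amp, error_profile("short"), n_reads = N_SHORT,
                         seed = SEED + 404L, side = "5p")
write_fastq(rd_amp$reads, file.path(SIM_DIR, "amplicon.fastq"))
write_truth(rd_amp$truth, file.path(SIM_DIR, "amplicon_truth.tsv"))
cat(sprintf("indel amplicon library: %d reads, %.2f%% modified planted\n",
            N_SHORT, 100 * mean(rd_amp$truth$class != "unedited")))
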