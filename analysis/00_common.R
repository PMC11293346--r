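# Shared setup for the numbered analysis scripts: constructs, barcodes and
# paths are derived deterministically so every stage can be re-run alone.
# The seed can be overridden as the first command-line argument.

suppressPackageStartupMessages(library(hitiseq))

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 1) as.integer(args[[1]]) else 42L

RESULTS <- file.path("results")
SIM_DIR <- file.path(RESULTS, "sim")
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)

# scaled-down study surrogate: ~0.5 kb donor, 200/220-base junction flanks
# (problem sizes discussed in the methods vignette)
EXPERIMENT <- hiti_experiment("toy", flank_locus = 200L, flank_donor = 220L)
NUCLEASE <- make_nuclease_vector()
BARCODES <- random_barcodes(2, seed = SEED)

N_LONG <- 2000L    # long reads per junction library
N_SHORT <- 2000L   # short reads per amplicon library
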