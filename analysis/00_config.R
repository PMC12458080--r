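## Shared configuration for the analysis scripts. Run the scripts from the
## repository root in order (01 ... 05); each writes its tables under
## results/ and prints what it found.

suppressMessages({
  library(deaseq)
  library(data.table)
})

SEED <- 1L
SIM_DIR <- "results/sim"
TAB_DIR <- "results/tables"

## Study conditions: ~1e6-cytosine GC-rich genome, 500 genes. 5gmC density
## is set above the genomic ppm scale so that the landscape and association
## analyses have enough called sites to summarise; abundance realism at the
## native ~10 ppm is exercised by the package tests.
study_config <- function() {
  sim_config(genome_length = 1500000L, n_chrom = 4L, n_genes = 500L,
             gmc_ppm = 600)
}

need_file <- function(path, producer) {
  if (!file.exists(path))
    stop(path, " not found - run analysis/", producer, " first", call. = FALSE)
  path
}

dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(TAB_DIR, showWarnings = FALSE, recursive = TRUE)
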