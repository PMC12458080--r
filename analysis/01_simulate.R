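#!/usr/bin/env Rscript
## Build the synthetic study: reference genome with gene/TE/histone
## annotation, planted 5mC and 5gmC ground truth, spike-ins, and
## per-cytosine conversion counts for wild-type DEA-seq / TET-BS-seq / WGBS
## plus a Dnmt1-KO DEA-seq control, with expression linked to gene-body
## modification.

source("analysis/00_config.R")

cfg <- study_config()
ref <- simulate_reference(cfg, seed = SEED)
truth <- plant_modifications(ref, cfg, seed = SEED)

cat(sprintf("genome: %d chromosomes, %s bp, %s cytosines\n",
            length(ref$genome$seqs), format(sum(ref$genome$lengths), big.mark = ","),
            format(nrow(truth), big.mark = ",")))
cat(sprintf("planted: %d x 5mC sites, %d x 5gmC sites (%d shared with 5mC)\n",
            sum(truth$f_mc > 0), sum(truth$f_gmc > 0),
            sum(truth$f_mc > 0 & truth$f_gmc > 0)))

write_genome_fasta(ref$genome, file.path(SIM_DIR, "genome.fa"))
write_gff3(ref$genes, file.path(SIM_DIR, "genes.gff3"))
write_bed(ref$tes, file.path(SIM_DIR, "te.bed"))
for (mk in names(ref$marks))
  write_bed(ref$marks[[mk]], file.path(SIM_DIR, paste0(mk, ".bed")))
write_tsv_table(truth, file.path(SIM_DIR, "truth.tsv"))

## conversion counts per chemistry (independent library draws per sample)
samples <- list(
  wt_dea    = list(profile = chemistry_profile("DEA"),    seed = SEED),
  wt_tetbs  = list(profile = chemistry_profile("TET-BS"), seed = SEED + 1L),
  wt_wgbs   = list(profile = chemistry_profile("WGBS"),   seed = SEED + 2L)
)
for (nm in names(samples)) {
  rec <- simulate_counts(truth, samples[[nm]]$profile, cfg,
                         seed = samples[[nm]]$seed)
  write_cytosine_report(rec, file.path(SIM_DIR, paste0(nm, ".cx.tsv")))
  cat(sprintf("%s: %s records, mean depth %.1f\n", nm,
              format(nrow(rec), big.mark = ","),
              mean(rec$n_unconverted + rec$n_converted)))
}

## Dnmt1-KO control: no 5mC, hence no 5gmC; a few injected noise sites
## exercise the background subtraction downstream
ko_cfg <- study_config(); ko_cfg$ko_noise_sites <- 30L
ko <- simulate_ko_sample(truth, chemistry_profile("DEA"), ko_cfg,
                         seed = SEED + 3L)
write_cytosine_report(ko, file.path(SIM_DIR, "ko_dea.cx.tsv"))
cat(sprintf("ko_dea: %d noise sites injected\n", ko_cfg$ko_noise_sites))

## spike-in libraries per chemistry
sp <- make_spikeins()
for (nm in c("DEA", "TET-BS", "WGBS")) {
  rec <- simulate_spikein_counts(sp, chemistry_profile(nm), seed = SEED,
                                 total_observations = 1e5)
  write_cytosine_report(rec, file.path(SIM_DIR, paste0("spikein_",
                                                       make.names(nm), ".cx.tsv")))
}

## expression linked to gene-body modification (positive 5gmC first-third
## coefficient, negative gene-level 5mC coefficient)
expr <- simulate_expression(truth, ref$genes, cfg, seed = SEED + 4L)
write_tsv_table(expr, file.path(SIM_DIR, "expression.tsv"))
cat(sprintf("expression: %d genes, median FPKM %.2f\n",
            nrow(expr), median(expr$fpkm)))
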