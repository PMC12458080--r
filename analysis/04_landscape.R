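#!/usr/bin/env Rscript
## Genomic landscape of the called sites: cytosine-context composition,
## functional-region categories, TSS-distance profile, TE zones,
## histone-mark overlap and k-mer context enrichment, for 5gmC (DEA) and
## deconvolved 5mC side by side.

source("analysis/00_config.R")

genome <- read_genome_fasta(need_file(file.path(SIM_DIR, "genome.fa"),
                                      "01_simulate.R"))
genes <- read_gff_genes(file.path(SIM_DIR, "genes.gff3"))
tes <- read_bed(file.path(SIM_DIR, "te.bed"), "TE")
marks <- lapply(c("H3K9me1", "H3K4me3", "H3K9me3"), function(mk)
  read_bed(file.path(SIM_DIR, paste0(mk, ".bed")), mk))
names(marks) <- c("H3K9me1", "H3K4me3", "H3K9me3")
gmc <- read_tsv_table(need_file(file.path(TAB_DIR, "gmc_sites.tsv"),
                                "03_call_sites.R"))
gmc <- gmc[gmc$removed_by_ko == FALSE]
mc <- read_tsv_table(file.path(TAB_DIR, "mc_sites.tsv"))
acfg <- annotation_config()

summaries <- list()
for (nm in c("5gmC", "5mC")) {
  sites <- if (nm == "5gmC") gmc else mc

  ctx <- as.data.table(sites)[, .N, by = context][order(-N)]
  ctx[, fraction := N / sum(N)]
  cat(sprintf("%s context composition: %s\n", nm,
              paste(sprintf("%s %.1f%%", ctx$context, 100 * ctx$fraction),
                    collapse = ", ")))

  feat <- annotate_feature(sites, genes, acfg)
  ft <- as.data.table(table(feature = feat))
  ft[, fraction := N / sum(N)]
  cat(sprintf("%s top region: %s (%.1f%%); intron share %.1f%%\n", nm,
              ft$feature[which.max(ft$N)], 100 * max(ft$fraction),
              100 * ft[feature == "intron"]$fraction))

  tp <- tss_distance_profile(sites, genes, acfg)
  cat(sprintf("%s within 3 kb of a TSS: %.1f%%\n", nm,
              100 * tp$within_window_fraction))

  teo <- te_overlap(sites, tes, acfg)
  fl <- teo$summary[teo$summary$zone == "flank"]
  cat(sprintf("%s in TE flanks (<= 1 kb): %.1f%%\n", nm, 100 * fl$fraction))

  mo <- mark_overlap(sites, marks)
  cat(sprintf("%s inside histone marks: %s\n", nm,
              paste(sprintf("%s %.1f%%", mo$mark, 100 * mo$fraction_inside),
                    collapse = ", ")))

  summaries[[nm]] <- list(context = ctx, features = ft, tss = tp$table,
                          te = teo$summary, marks = mo)
  write_tsv_table(ctx, file.path(TAB_DIR, sprintf("context_%s.tsv", nm)))
  write_tsv_table(ft, file.path(TAB_DIR, sprintf("features_%s.tsv", nm)))
  write_tsv_table(teo$summary, file.path(TAB_DIR, sprintf("te_zones_%s.tsv", nm)))
  write_tsv_table(mo, file.path(TAB_DIR, sprintf("mark_overlap_%s.tsv", nm)))
}

## motif check for 5gmC: enrichment relative to the genomic background of
## C-centred windows
km <- kmer_context_freq(gmc, genome, k = 5)
write_tsv_table(km, file.path(TAB_DIR, "kmer_enrichment_5gmC.tsv"))
cat(sprintf("5gmC k-mer enrichment: %d of %d k-mers significant at FDR 0.05\n",
            sum(km$enriched), nrow(km)))
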