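#!/usr/bin/env Rscript
## Confident-site calling: gradient threshold testing between DEA-seq and
## TET-BS-seq, the (count > 10, ratio > 17%) call with Dnmt1-KO background
## subtraction, abundance in ppm, and deconvolution of 5mC from WGBS
## (BS-minus-DEA), with recovery measured against the planted truth.

source("analysis/00_config.R")

dea <- read_cytosine_report(need_file(file.path(SIM_DIR, "wt_dea.cx.tsv"),
                                      "01_simulate.R"))
tet <- read_cytosine_report(file.path(SIM_DIR, "wt_tetbs.cx.tsv"))
wgbs <- read_cytosine_report(file.path(SIM_DIR, "wt_wgbs.cx.tsv"))
ko <- read_cytosine_report(file.path(SIM_DIR, "ko_dea.cx.tsv"))
truth <- read_tsv_table(file.path(SIM_DIR, "truth.tsv"))

## gradient testing: pick thresholds that keep abundance plausible while
## maximizing DEA/TET-BS overlap
planted_mass_ppm <- 1e6 * sum(truth$f_gmc) / nrow(truth)
gg <- gradient_select(dea, tet,
                      count_grid = c(5L, 10L, 15L, 20L),
                      ratio_grid = c(0.10, 0.17, 0.25),
                      expected_ppm = planted_mass_ppm,
                      ko_records_a = ko)
write_tsv_table(gg$grid, file.path(TAB_DIR, "gradient_grid.tsv"))
cat(sprintf("gradient selection: count > %d, ratio > %.2f (Jaccard %.3f, %.1f ppm)\n",
            gg$selected$min_count, gg$selected$min_ratio, gg$selected$jaccard,
            gg$selected$ppm))

th <- call_thresholds(gg$selected$min_count, gg$selected$min_ratio)

## final 5gmC call with KO subtraction
cand <- call_gmc_sites(dea, th, sample_id = "wt_dea")
audit <- subtract_ko(cand, ko, th)
gmc <- retained_sites(audit)
cat(sprintf("5gmC: %d candidates, %d removed by KO, %d confident sites\n",
            nrow(audit), sum(audit$removed_by_ko), nrow(gmc)))
write_tsv_table(audit, file.path(TAB_DIR, "gmc_sites.tsv"))
write_bedgraph(gmc[order(chrom, pos)], "ratio",
               file.path(TAB_DIR, "gmc_ratio.bedgraph"))

ppm <- abundance_ppm(gmc, dea)
cat(sprintf("abundance: %.1f ppm called vs %.1f ppm planted mass\n",
            ppm, planted_mass_ppm))

## recovery against truth
key_t <- with(truth[truth$state == "5gmC"], paste(chrom, pos, strand))
key_c <- with(gmc, paste(chrom, pos, strand))
cat(sprintf("recovery: precision %.3f, recall %.3f\n",
            mean(key_c %in% key_t), mean(key_t %in% key_c)))

## 5mC via WGBS-minus-5gmC deconvolution
dec <- deconvolve_mc(wgbs, gmc, min_depth = 10L)
mc <- call_mc_sites(dec, th)
cat(sprintf("deconvolution: %d positions, negative mass %.2f, %d confident 5mC sites\n",
            nrow(dec), attr(dec, "negative_mass"), nrow(mc)))
write_tsv_table(mc, file.path(TAB_DIR, "mc_sites.tsv"))
write_bedgraph(mc[order(chrom, pos)], "ratio",
               file.path(TAB_DIR, "mc_ratio.bedgraph"))

dm <- merge(dec, as.data.table(truth)[, .(chrom, pos, strand, f_mc)],
            by = c("chrom", "pos", "strand"))
deep <- dm[!dm$wgbs_missing & dm$depth >= 30]
cat(sprintf("5mC ratio RMSE vs planted fraction (depth >= 30): %.4f\n",
            sqrt(mean((deep$mc_ratio - deep$f_mc)^2))))
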