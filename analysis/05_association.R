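#!/usr/bin/env Rscript
## Association analyses: 5gmC/5mC co-occurrence and exclusivity, expression
## quartiles and metagene profiles, per-region correlation between
## modification level and expression, and knockout-response proportions for
## genes with vs without 5gmC.

source("analysis/00_config.R")

genes <- read_gff_genes(need_file(file.path(SIM_DIR, "genes.gff3"),
                                  "01_simulate.R"))
dea <- read_cytosine_report(file.path(SIM_DIR, "wt_dea.cx.tsv"))
wgbs <- read_cytosine_report(file.path(SIM_DIR, "wt_wgbs.cx.tsv"))
expr <- read_tsv_table(file.path(SIM_DIR, "expression.tsv"))
gmc <- read_tsv_table(need_file(file.path(TAB_DIR, "gmc_sites.tsv"),
                                "03_call_sites.R"))
gmc <- gmc[gmc$removed_by_ko == FALSE]
mc <- read_tsv_table(file.path(TAB_DIR, "mc_sites.tsv"))
acfg <- annotation_config()

## overlap and exclusivity of the two modifications
ov <- site_overlap(gmc, mc)
cat(sprintf("overlap: %d 5gmC, %d 5mC, %d shared; 5gmC exclusive fraction %.2f\n",
            ov$n_gmc, ov$n_mc, ov$n_shared, ov$gmc_exclusive_fraction))
cat(sprintf("5gmC level at shared sites %.3f vs exclusive sites %.3f\n",
            ov$gmc_ratio_shared$mean, ov$gmc_ratio_exclusive$mean))
write_tsv_table(data.table(
  metric = c("n_gmc", "n_mc", "n_shared", "gmc_exclusive_fraction", "jaccard",
             "gmc_ratio_shared_mean", "gmc_ratio_exclusive_mean"),
  value = c(ov$n_gmc, ov$n_mc, ov$n_shared, ov$gmc_exclusive_fraction,
            ov$jaccard, ov$gmc_ratio_shared$mean, ov$gmc_ratio_exclusive$mean)),
  file.path(TAB_DIR, "overlap_report.tsv"))

## metagene profiles by expression quartile
qs <- expression_quartiles(expr, 0.25)
mg_gmc <- metagene_profile(dea, genes, list(high = qs$high, low = qs$low))
mg_mc <- metagene_profile(wgbs, genes, list(high = qs$high, low = qs$low))
prof <- rbindlist(lapply(names(mg_gmc$profiles), function(grp)
  data.table(modification = "5gmC", group = grp,
             bin = seq_len(mg_gmc$n_bins), mean_ratio = mg_gmc$profiles[[grp]])))
prof <- rbind(prof, rbindlist(lapply(names(mg_mc$profiles), function(grp)
  data.table(modification = "5mC", group = grp,
             bin = seq_len(mg_mc$n_bins), mean_ratio = mg_mc$profiles[[grp]]))))
write_tsv_table(prof, file.path(TAB_DIR, "metagene_profiles.tsv"))
body <- (mg_mc$flank_bins + 1):(mg_mc$flank_bins + mg_mc$body_bins)
cat(sprintf("gene-body 5mC, high vs low expression quartile: %.4f vs %.4f\n",
            mean(mg_mc$profiles$high[body], na.rm = TRUE),
            mean(mg_mc$profiles$low[body], na.rm = TRUE)))

## per-region rank correlation with expression
sc_gmc <- segment_correlation(dea, genes, expr, acfg)
sc_mc <- segment_correlation(wgbs, genes, expr, acfg)
sc <- rbind(cbind(modification = "5gmC", sc_gmc),
            cbind(modification = "5mC", sc_mc))
write_tsv_table(sc, file.path(TAB_DIR, "segment_correlation.tsv"))
ft <- sc_gmc[region == "body_first_third" & stat == "mean"]
cat(sprintf("5gmC first third of gene body vs FPKM: rho %.3f (p = %.2g)\n",
            ft$estimate, ft$p_value))
bm <- sc_mc[region == "body_middle_third" & stat == "mean"]
cat(sprintf("5mC middle third of gene body vs FPKM: rho %.3f (p = %.2g)\n",
            bm$estimate, bm$p_value))

## knockout-response proportions: genes with vs without 5gmC in the
## promoter/exon/intron/downstream universe
feat <- annotate_feature(gmc, genes, acfg)
genic <- gmc[as.character(feat) != "distal_intergenic"]
regions <- gene_regions(genes, acfg)
gr_s <- GenomicRanges::GRanges(genic$chrom, IRanges::IRanges(genic$pos, genic$pos))
gr_r <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
hits <- GenomicRanges::findOverlaps(gr_s, gr_r)
genes_with <- sort(unique(regions$gene_id[S4Vectors::subjectHits(hits)]))
genes_without <- setdiff(genes$genes$gene_id, genes_with)
cat(sprintf("genes containing 5gmC: %d of %d (%.1f%%)\n", length(genes_with),
            nrow(genes$genes), 100 * length(genes_with) / nrow(genes$genes)))

de <- simulate_de_table(genes$genes$gene_id,
                        genes$genes$gene_id %in% genes_with, seed = SEED + 9L)
dp <- de_proportions(genes_with, genes_without, de)
write_tsv_table(dp$table, file.path(TAB_DIR, "de_proportions.tsv"))
cat(sprintf("downregulated on knockout: %.1f%% of 5gmC genes vs %.1f%% of others (p = %.2g)\n",
            100 * dp$table$frac_down[1], 100 * dp$table$frac_down[2],
            dp$test_down))
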