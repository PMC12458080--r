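# deaseq

Analysis pipeline for base-resolution profiling of
**5-glyceryl-methylcytosine (5gmC)**, the vitamin-C-derived hypermodified
cytosine produced from 5-methylcytosine (5mC) by the dioxygenase CMD1 in
the green alga *Chlamydomonas reinhardtii*.

## The problem and the method

5gmC occurs at ~ppm abundance among genomic cytosines, and neither 5mC nor
5gmC changes base pairing, so both must be read through conversion
chemistry:

* **DEA-seq** — a DNA deaminase converts C and 5mC to U/T while the
  glyceryl group of 5gmC blocks deamination, so unconverted cytosines mark
  5gmC. Residual non-conversion is ~0.2%, uniform across CG/CHG/CHH.
* **TET-BS-seq** — TET oxidation then bisulfite; 5gmC resists both, but
  ~3% of 5mC escapes conversion in a context-dependent way, inflating
  false 5gmC calls at methylated CpG sites.
* **WGBS** — both 5mC and 5gmC read as C, so the 5mC signal is the WGBS
  ratio minus the confident 5gmC ratio (BS−DEA deconvolution):
  `mc_ratio = clamp(wgbs_ratio − gmc_ratio, 0, 1)`.

Starting from per-cytosine conversion-count tables (the Bismark CX-report
dialect), the package implements:

1. **Spike-in conversion estimation** — pooled and per-context conversion
   rates with Clopper–Pearson intervals, from an unmodified lambda-like
   control and a fully-5mC 480-bp amplicon; chemistry comparison by exact
   test (`estimate_conversion`, `compare_profiles`).
2. **Confident 5gmC calling** — strict double threshold (unconverted count
   > 10 AND ratio > 17%), Dnmt1-knockout background subtraction as
   positional exclusion, gradient threshold selection maximizing DEA/TET-BS
   overlap at plausible abundance, and mass-based ppm
   (`call_gmc_sites`, `subtract_ko`, `gradient_select`, `abundance_ppm`).
3. **5mC deconvolution** from WGBS (`deconvolve_mc`, `call_mc_sites`).
4. **Genomic landscape** — CG/CHG/CHH context classification, functional
   regions (promoter 2 kb / exon / intron / downstream 300 bp / distal),
   TSS-distance profiles (±3 kb), TE zones with a closed 1-kb flank,
   histone-mark overlap, k-mer enrichment with BH control
   (`classify_context`, `annotate_feature`, `tss_distance_profile`,
   `te_overlap`, `mark_overlap`, `kmer_context_freq`).
5. **Association** — 5gmC/5mC exclusivity, expression quartiles, metagene
   profiles over scaled gene bodies, per-region Spearman correlation with
   FPKM, knockout-response proportions (`site_overlap`,
   `expression_quartiles`, `metagene_profile`, `segment_correlation`,
   `de_proportions`).
6. **A synthetic-chemistry simulator** (`simulate_reference`,
   `plant_modifications`, `simulate_counts`, `make_spikeins`,
   `simulate_expression`) that generates genomes, ground-truth modification
   states and count data under each chemistry, so every stage is tested
   against planted truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
1.5-Mb genome (run them in order from the repository root):

```sh
Rscript analysis/01_simulate.R     # genome, truth, samples, spike-ins
Rscript analysis/02_conversion.R   # spike-in conversion rates
Rscript analysis/03_call_sites.R   # calling, KO subtraction, deconvolution
Rscript analysis/04_landscape.R    # contexts, regions, TE, histone marks
Rscript analysis/05_association.R  # exclusivity, expression association
```

Selected output from a run (seed 1):

```
DEA     fully-5mC  conversion 0.9980 [0.9977, 0.9983]
DEA     unmodified conversion 0.9979 [0.9976, 0.9982]
TET-BS  fully-5mC  conversion 0.9803 [0.9795, 0.9812]
contexts where DEA converts 5mC significantly better than TET-BS: CG, CHG, CHH
5gmC: 576 candidates, 0 removed by KO, 576 confident sites
recovery: precision 1.000, recall 1.000
5mC ratio RMSE vs planted fraction (depth >= 30): 0.0083
5gmC context composition: CHH 69.6%, CHG 15.6%, CG 14.8%
overlap: 576 5gmC, 22097 5mC, 157 shared; 5gmC exclusive fraction 0.73
5gmC first third of gene body vs FPKM: rho 0.382 (p = 9e-19)
downregulated on knockout: 20.2% of 5gmC genes vs 13.8% of others (p = 0.14)
```

Reading this: the DEA chemistry converts both spike-in classes at ≥99.7%
so the (>10, >17%) filter is essentially false-positive-free; the planted
5gmC sites are recovered perfectly at 100× depth; called 5gmC is
CHH-preferential while deconvolved 5mC is CpG-heavy; most 5gmC sites do
not coincide with a called 5mC site; and 5gmC in the first third of the
gene body tracks expression positively, as the generator encodes.

Tables are written under `results/tables/`; simulated inputs under
`results/sim/`. See `vignettes/deaseq-methods.Rmd` for the model,
parameter choices and limitations.

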