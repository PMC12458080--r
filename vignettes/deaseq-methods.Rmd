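---
title: "Methods: deaminase-assisted 5gmC profiling and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deaminase-assisted 5gmC profiling and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

5-glyceryl-methylcytosine (5gmC) is a hypermodified cytosine produced from
5-methylcytosine (5mC) by the vitamin-C-dependent dioxygenase CMD1 in
*Chlamydomonas reinhardtii*. It occurs at parts-per-million abundance among
genomic cytosines, so distinguishing it from 5mC and unmodified C requires a
conversion chemistry with a very low residual error. Three chemistries are
modelled, each summarised by the probability of reading T after treatment
and PCR, per true base state and cytosine context:

* **DEA-seq** — a DNA deaminase converts both C and 5mC to U/T; the bulky
  glyceryl group of 5gmC blocks deamination. Unconverted cytosines in a
  DEA-seq library therefore mark 5gmC. Residual non-conversion of C and 5mC
  is ~0.2%, uniform across contexts.
* **TET-BS-seq** — TET oxidation of 5mC followed by bisulfite conversion;
  5gmC resists both steps. The two-step conversion leaves ~3% of 5mC
  unconverted, and the escape is context-dependent.
* **WGBS** — plain bisulfite: C converts, both 5mC and 5gmC are protected.
  The 5mC signal is therefore the WGBS unconverted ratio minus the confident
  5gmC ratio (BS-minus-DEA deconvolution).

Per cytosine with molecular modification fractions `f_gmc` and `f_mc`
(`f_gmc + f_mc <= 1`), the probability that a read shows C is

```
p_C = f_gmc * (1 - pT_5gmC) + f_mc * (1 - pT_5mC) + (1 - f_gmc - f_mc) * (1 - pT_C)
```

and the unconverted count at sequencing depth *d* is Binomial(*d*, `p_C`).

## Site calling

Confident 5gmC sites satisfy two strict inequalities — unconverted count
**> 10** and unconverted ratio **> 17%** — followed by subtraction of every
position also called, with identical thresholds, in a Dnmt1-knockout
control (which carries neither 5mC nor 5gmC; anything called there is
background). Subtraction is positional exclusion, not ratio arithmetic:
"signals detected in the knockout" are read as a blacklist. Removed sites
stay in the audit table with a flag.

The threshold pair itself is chosen by gradient testing
(`gradient_select()`): every grid point is scored by the number of called
sites per method, the abundance in ppm, and the exact-position Jaccard
overlap between the DEA-seq and TET-BS-seq calls; the selected point
maximizes overlap among points whose abundance lies within a factor (default
0.5-2) of the expected ppm. The full grid is always emitted so the choice
is auditable.

Why these thresholds are safe for DEA chemistry: at 0.2% residual
non-conversion and 100x depth, a false call needs at least 18 unconverted
reads, and P(X >= 18; Binomial(100, 0.002)) is about 7e-30 — far below one
expected false call even across 1e6 cytosines. The tests verify both the
zero observed false-call count and this independent binomial-tail bound.

Abundance is mass-based: `ppm = 1e6 * sum(unconverted at called sites) /
sum(depth over all cytosines)`, paralleling the mole-fraction scale of mass
spectrometry ("ppm of total cytosines"). A site-count variant would differ
by the mean per-site modification fraction.

Deconvolved 5mC is `clamp(wgbs_ratio - gmc_ratio, 0, 1)`; negative mass
before clamping estimates residual noise and is reported as a QC figure.

## The synthetic-chemistry simulator

Every stage is validated against a generator whose defaults encode the
study conditions rather than convenient values:

* GC-rich genome (GC 0.64, checked to ±1%), non-overlapping genes with
  exon/intron structure, TE intervals in intergenic space, histone-mark
  intervals (H3K9me1/H3K4me3/H3K9me3).
* 5mC planted per context (CG 0.05, CHG 0.01, CHH 0.012 — CpG most
  enriched per context, as observed), boosted inside H3K9me1 intervals
  (x3) to emulate the repressive-chromatin association. Per-site molecular
  fractions are Beta-distributed, skewed high at CG.
* 5gmC planted at 10 ppm of cytosines by default, with CHH-heavy context
  weights (0.15/0.15/0.7), a x3 preference for intronic cytosines, and 60%
  of sites exclusive of 5mC. The planted count is the rounded target rather
  than a Poisson draw, because at ~10 sites per 1e6 cytosines Poisson
  scatter would routinely miss the configured density by more than the
  tolerated 20%. Exclusive sites draw `f_gmc ~ U(0.5, 1)`; shared sites
  draw `f_gmc ~ U(0.6, 0.75)` with residual 5mC `f_mc >= 0.25` — shared
  sites represent demethylation in progress, and a residual-5mC floor at
  the calling boundary would make the called-level exclusivity a biased
  estimate of the planted parameter by construction.
* Depth is negative-binomial with mean 100 and size 20 (the study reports
  95-145x coverage).
* DEA non-conversion 0.002 for C and 5mC in every context; WGBS C
  non-conversion 0.002; TET-BS C non-conversion 0.004 and 5mC escape with
  context means CG 0.045 / CHG 0.03 / CHH 0.015 (mean 3%). 5gmC protection
  is complete by default, with an over-conversion knob exposed (no
  quantitative loss has been measured; mass spectrometry shows essentially
  all 5gmC surviving treatment).
* **Per-site TET-BS escape variability.** TET-BS 5mC escape is drawn per
  site from a Beta distribution around the context mean (precision
  `phi = 5`), not held constant. A constant 3% escape at 100x depth almost
  never clears the ratio > 17% filter (binomial tail ~1e-7), whereas the
  observed behaviour of TET-BS — spurious 5gmC calls concentrated at
  heavily methylated CpG sites — requires some sites to convert much worse
  than average. Site-to-site variability in oxidation efficiency is the
  natural mechanism; DEA keeps a constant residual (its deamination is
  uniform across contexts). This is what makes the cross-chemistry
  comparison meaningful: on identical truth, the TET-BS pathway produces
  strictly more false 5gmC calls at high-5mC CpG sites than DEA.
* Spike-ins: the bundled 480-bp fully-5mC amplicon template (every C on
  both strands at fraction 1, as PCR with 5-methyl-dCTP produces) and a
  synthetic lambda-like unmodified control generated deterministically — it
  stands in for unmodified phage DNA and is labelled synthetic throughout.
* Expression: log-FPKM is linear in two standardized gene-level
  covariates — mean true 5gmC fraction over the first third of the gene
  body (coefficient +1) and mean true 5mC fraction over the body
  (coefficient -1) — plus N(0, 1) noise.
* The Dnmt1-KO sample is the same cytosine universe with every state C,
  plus an optional injector of spurious high-ratio sites to exercise the
  subtraction path.

Identical (config, seed) produces bit-identical output everywhere.

What the simulator does **not** emulate: read-level artefacts (alignment
error, PCR duplicates, sequencing error beyond conversion chemistry),
bisulfite-induced degradation, strand-asymmetric coverage, and real genome
composition (repeat families, isochore structure, linked CpG islands).
Passing tests therefore demonstrate that the pipeline's arithmetic,
thresholds and statistics behave as specified under controlled chemistry —
not that the biological percentages of any real genome are reproduced.
The headline genome-scale percentages of the source study (context shares,
TSS-proximal share, TE-flank share, histone-mark overlap, knockout-response
proportions) require the deposited sequencing data and the reference
genome, and are exercised here only as structural smoke tests.

## Analysis conventions

* Internal interval coordinates are 0-based half-open; per-cytosine
  positions stay 1-based on the reference (the CX-report convention).
  External dialects (GFF3 1-based closed, BED/bedGraph 0-based half-open)
  are converted at the boundary and nowhere else.
* The CX-report "methylated" column is read generically as "unconverted";
  its meaning is fixed by the sample's chemistry, not by the file.
* Minus-strand cytosines are independent records; symmetric CpG counts are
  never pooled (the extractors report per cytosine, and the study gives no
  indication of pooling). Spike-in strata pool strands.
* One transcript per gene — the one with the largest summed exon length —
  for all gene-level analyses.
* Context is read from the two bases 3' of the C on its own strand; CG
  needs only the next base, so a chromosome end or N only makes a window
  AMBIG when it hides a decisive base.
* Feature precedence is promoter > exon > intron > downstream >
  distal_intergenic, with the promoter an orientation-aware 2000-bp window
  (including the TSS base) and downstream 300 bp past the TES; one window
  definition is used everywhere. "Within 3 kb of the TSS" counts both
  directions. TE flanks are closed at exactly 1000 bp and nested TEs are
  merged before zoning.
* Method overlap is exact (chrom, pos, strand) identity; no proximity
  window.
* Correlations are Spearman by default (FPKM is heavily skewed); Pearson
  is a flag. Region summaries use both the mean and the max of the ratio
  over covered cytosines, with 0 for uncovered regions. The gene-body
  segmentation is promoter, three body thirds, downstream; "gene contains
  5gmC" means at least one confident site in that five-region universe.
* Two-group comparisons (chemistry conversion rates, knockout-response
  proportions) use exact tests (binomial / Fisher); k-mer enrichment is
  exact binomial against the genome background of C-centred windows with
  Benjamini-Hochberg control at 0.05. Clopper-Pearson intervals accompany
  every conversion rate (the source reports none; intervals make threshold
  audits possible).
* Statistical calling (binomial tests against the spike-in non-conversion
  rate) is deliberately not the primary mode — the method uses hard
  thresholds; the exact-test machinery is exposed only as QC annotation.

## Problem sizes

The bundled analyses and tests run at deliberately desk-sized scales,
chosen once: unit fixtures of 10-2e4 cytosines; chemistry-level checks at
1e5-1e6 simulated cytosines (enough for the binomial-tail and recovery
properties to be sharp); and a shared 1.5-Mb, 500-gene, ~1e6-cytosine study
for landscape and association analyses. For gene-level association the
5gmC density is raised to 600 ppm so that a meaningful fraction of the 500
genes carry the mark: at the native 10 ppm (~10 sites genome-wide, ~0.5% of
genes marked) no correlation is estimable from 500 genes by construction,
which is itself a documented property of the native abundance, not a
failure of the method.

## Known limitations

* The chemistry model treats conversion errors as independent across reads
  and sites (given the per-site escape draw); correlated failures within a
  fragment are not modelled.
* KO subtraction assumes the knockout and wild-type libraries share the
  coordinate universe; coverage gaps in the KO reduce its power silently
  (by design, candidates without a KO call are kept).
* The deconvolution treats the called 5gmC ratio as noise-free when
  subtracting; at depth 100 this contributes ~0.04-0.06 to the standard
  error of a single site's 5mC estimate, which the recovery tests absorb.
* Gradient selection scores overlap by site identity only; a
  ratio-correlation overlap score could behave differently near threshold
  boundaries.
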