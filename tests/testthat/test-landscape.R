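test_that("context classification follows the CG/CHG/CHH definitions", {
  g <- genome_ref(c(chr1 = "ACGT", chr2 = "ACCG", chr3 = "TTCGAA",
                    chr4 = "ACGC", chr5 = "GTAA"))
  expect_equal(as.list(classify_context(g, "chr1", 2, "+")),
               list(context = "CG", trinucleotide = "CGT"))
  expect_equal(as.list(classify_context(g, "chr2", 2, "+")),
               list(context = "CHG", trinucleotide = "CCG"))
  ## C on the minus strand (reference G at 1-based 4): read on reverse
  ## complement, triplet CGA -> CG
  expect_equal(as.list(classify_context(g, "chr3", 4, "-")),
               list(context = "CG", trinucleotide = "CGA"))
  ## chromosome-end truncation in a decisive position is AMBIG
  expect_equal(classify_context(g, "chr4", 4, "+")$context, "AMBIG")
  expect_equal(classify_context(g, "chr5", 1, "-")$context, "AMBIG")
  ## non-C base is a domain error
  expect_error(classify_context(g, "chr1", 1, "+"), "not C")
})

test_that("context classifier agrees with brute force over all 5-mers", {
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases, bases), 1, paste,
                 collapse = "")
  genome <- genome_ref(setNames(kmers, paste0("w", seq_along(kmers))))
  for (strand in c("+", "-")) {
    centre_base <- if (strand == "+") "C" else "G"
    sel <- substr(kmers, 3, 3) == centre_base
    res <- classify_context(genome, paste0("w", which(sel)),
                            rep(3L, sum(sel)), rep(strand, sum(sel)))
    expected_tri <- vapply(kmers[sel], function(k) {
      if (strand == "+") substr(k, 3, 5) else oracle_revcomp(substr(k, 1, 3))
    }, character(1))
    expected_ctx <- vapply(expected_tri, oracle_context, character(1))
    expect_equal(res$trinucleotide, unname(expected_tri))
    expect_equal(res$context, unname(expected_ctx))
  }
})

## two genes: gA (+) with one intron; gB (+) whose promoter window reaches
## into gA's intron
demo_genes <- function() {
  g <- data.table(gene_id = c("gA", "gB"),
                  transcript_id = c("gA.t1", "gB.t1"),
                  chrom = "chr1", strand = "+",
                  start = c(1000L, 6000L), end = c(5000L, 9000L))
  ex <- data.table(gene_id = c("gA", "gA", "gB"),
                   start = c(1000L, 4000L, 6000L),
                   end = c(2000L, 5000L, 9000L))
  gene_models(g, ex)
}

test_that("feature annotation applies the precedence order", {
  gm <- demo_genes()
  sites <- data.table(chrom = "chr1",
                      pos = c(501L,    # 500 bp upstream of gA TSS -> promoter
                              1500L,   # inside gA exon 1
                              3000L,   # gA intron, far from gB promoter
                              4500L,   # gA exon 2 BUT within 2kb of gB TSS
                              5200L,   # gA downstream (<=300) and gB promoter
                              9200L,   # gB downstream
                              9800L),  # beyond downstream window
                      strand = "+")
  f <- as.character(annotate_feature(sites, gm))
  expect_equal(f, c("promoter", "exon", "intron", "promoter", "promoter",
                    "downstream", "distal_intergenic"))
  ## categories partition: counts sum to the site count, runs identical
  expect_equal(sum(table(annotate_feature(sites, gm))), nrow(sites))
  expect_identical(annotate_feature(sites, gm), annotate_feature(sites, gm))
  ## no genes at all -> everything distal
  empty <- gene_models(gm$genes[0], gm$exons[0])
  expect_true(all(annotate_feature(sites, empty) == "distal_intergenic"))
})

test_that("TSS distances are signed, orientation-aware and binned", {
  gm <- demo_genes()
  at_tss <- data.table(chrom = "chr1", pos = c(1001L, 6001L), strand = "+")
  tp <- tss_distance_profile(at_tss, gm)
  expect_equal(tp$within_window_fraction, 1)
  central <- tp$table[tp$table$bin_start <= 0 & tp$table$bin_end > 0]
  expect_equal(central$n, 2L)

  expect_error(tss_distance_profile(at_tss, gene_models(gm$genes[0], gm$exons[0])),
               "no gene models")
  empty <- tss_distance_profile(at_tss[0], gm)
  expect_true(is.na(empty$within_window_fraction))
})

test_that("uniform sites give the analytic within-window fraction", {
  ## one gene per 50 kb; sites pseudo-uniform -> ~6000/50000 within 3 kb
  n_chrom <- 4L
  gm <- gene_models(
    data.table(gene_id = sprintf("g%d", 1:n_chrom),
               transcript_id = sprintf("g%d.t1", 1:n_chrom),
               chrom = sprintf("chr%d", 1:n_chrom), strand = "+",
               start = 25000L, end = 26000L),
    data.table(gene_id = sprintf("g%d", 1:n_chrom), start = 25000L, end = 26000L))
  sites <- rbindlist(lapply(1:n_chrom, function(i)
    data.table(chrom = sprintf("chr%d", i), pos = seq(1L, 50000L, by = 37L),
               strand = "+")))
  tp <- tss_distance_profile(sites, gm)
  expect_lt(abs(tp$within_window_fraction - 6000 / 50000), 0.01)
})

test_that("TE zones respect the closed 1-kb flank boundary", {
  te <- interval_set(data.table(chrom = "chr1", start = 10000L, end = 12000L), "TE")
  sites <- data.table(chrom = "chr1",
                      pos = c(11000L,          # TE midpoint
                              10001L - 999L,   # 999 bp before start -> flank
                              10001L - 1000L,  # exactly 1000 -> flank (closed)
                              10001L - 1001L,  # 1001 bp -> outside
                              13000L,          # 1000 past end -> flank
                              13001L),         # 1001 past end -> outside
                      strand = "+", ratio = 0.5)
  z <- as.character(te_overlap(sites, te)$zones)
  expect_equal(z, c("inside", "flank", "flank", "outside", "flank", "outside"))
})

test_that("TE zone fractions and ratios are counting arithmetic", {
  te <- interval_set(data.table(chrom = "chr1", start = 50000L, end = 51000L), "TE")
  flank_pos <- as.integer(seq(49100, 49900, length.out = 17))
  out_pos <- as.integer(seq(1000, 40000, length.out = 83))
  sites <- data.table(chrom = "chr1", pos = c(flank_pos, out_pos), strand = "+",
                      ratio = c(rep(0.9, 17), rep(0.1, 83)))
  res <- te_overlap(sites, te)
  summ <- res$summary
  expect_equal(summ[summ$zone == "flank"]$fraction, 0.17)
  expect_equal(summ[summ$zone == "flank"]$mean_ratio, 0.9)
  expect_equal(summ[summ$zone == "outside"]$mean_ratio, 0.1)
  ## zones partition chromosome length for disjoint intervals
  expect_equal(sum(summ$n), nrow(sites))
})

test_that("histone-mark overlap reports fractions and level contrasts", {
  marks <- list(H3K4me3 = interval_set(
    data.table(chrom = "chr1", start = 100L, end = 200L), "H3K4me3"))
  inside <- data.table(chrom = "chr1", pos = 101:150, strand = "+", ratio = 0.9)
  res_all <- mark_overlap(inside, marks)
  expect_equal(res_all$fraction_inside, 1)

  mixed <- rbind(inside,
                 data.table(chrom = "chr1", pos = 1001:1050, strand = "+",
                            ratio = 0.1))
  res <- mark_overlap(mixed, marks)
  expect_equal(res$mean_ratio_inside, 0.9)
  expect_equal(res$mean_ratio_outside, 0.1)

  ## empty interval set: fraction 0 and guarded means
  res0 <- mark_overlap(mixed, list(H3K9me3 = interval_set(
    data.table(chrom = character(), start = integer(), end = integer()),
    "H3K9me3")))
  expect_equal(res0$fraction_inside, 0)
  expect_true(is.na(res0$mean_ratio_inside))
})

test_that("planted 5mC enrichment inside H3K9me1 is recovered", {
  cfg <- sim_config(genome_length = 300000L, n_chrom = 1L, n_genes = 30L,
                    mark_count = 20L, mc_h3k9me1_boost = 5)
  ref <- simulate_reference(cfg, seed = 17)
  truth <- plant_modifications(ref, cfg, seed = 17)
  mc_sites <- truth[truth$f_mc > 0]
  mc_sites$ratio <- mc_sites$f_mc
  res <- mark_overlap(mc_sites, ref$marks["H3K9me1"])
  genome_frac <- sum(ref$marks$H3K9me1$intervals$end -
                       ref$marks$H3K9me1$intervals$start) / 300000
  expect_gt(res$fraction_inside, genome_frac)  # boosted occupancy
})

test_that("k-mer enrichment finds planted contexts and controls type I", {
  cfg <- sim_config(genome_length = 150000L, n_chrom = 1L, n_genes = 0L,
                    te_count = 0L, mark_count = 0L)
  ref <- simulate_reference(cfg, seed = 23)
  cyt <- genome_cytosines(ref$genome)

  expect_error(kmer_context_freq(cyt[1:10], ref$genome, k = 4), "odd")

  ## planted CAC-trinucleotide sites: every window centred on the C ends in
  ## "AC", so at k=5 the enriched k-mers are exactly the ?.CAC family
  cac <- cyt[cyt$trinucleotide == "CAC"]
  set.seed(1)
  planted <- cac[sample(nrow(cac), 300)]
  km <- kmer_context_freq(planted, ref$genome, k = 5)
  enr <- km[km$enriched == TRUE]
  expect_gt(nrow(enr), 0)
  expect_true(all(substr(enr$kmer, 3, 5) == "CAC"))
  ## conservation at k=3: rows sum to the usable site count
  km3 <- kmer_context_freq(planted, ref$genome, k = 3)
  expect_equal(sum(km3$n_sites), 300L)

  ## null draw from all cytosines: nothing significant at FDR 0.05
  set.seed(1)
  nullsites <- cyt[sample(nrow(cyt), 1000)]
  km0 <- kmer_context_freq(nullsites, ref$genome, k = 3)
  expect_equal(sum(km0$enriched), 0L)
})
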