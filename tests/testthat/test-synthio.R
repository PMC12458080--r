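test_that("reference simulation is deterministic and honours GC target", {
  cfg <- sim_config(genome_length = 100000L, n_chrom = 1L, n_genes = 20L)
  a <- simulate_reference(cfg, seed = 7)
  b <- simulate_reference(cfg, seed = 7)
  expect_identical(a$genome$seqs, b$genome$seqs)
  expect_identical(as.data.frame(a$genes$genes), as.data.frame(b$genes$genes))
  expect_identical(as.data.frame(a$tes$intervals), as.data.frame(b$tes$intervals))

  cfg2 <- sim_config(genome_length = 1000000L, n_chrom = 1L, n_genes = 0L,
                     te_count = 0L, mark_count = 0L)
  big <- simulate_reference(cfg2, seed = 1)
  gc <- mean(strsplit(big$genome$seqs[[1]], "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.63)
  expect_lte(gc, 0.65)
  expect_equal(nrow(big$genes$genes), 0L)  # degenerate: no genes, valid genome
})

test_that("genes and intervals stay within bounds and do not overlap", {
  cfg <- sim_config(genome_length = 200000L, n_chrom = 2L, n_genes = 40L)
  ref <- simulate_reference(cfg, seed = 2)
  g <- ref$genes$genes
  expect_true(all(g$start >= 0 & g$end <= cfg$genome_length %/% cfg$n_chrom))
  for (cn in unique(g$chrom)) {
    gg <- g[g$chrom == cn][order(start)]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= head(gg$end, -1)))
  }
  te <- ref$tes$intervals
  expect_true(all(te$start >= 0 & te$end <= cfg$genome_length %/% cfg$n_chrom))
})

test_that("modification planting matches configured density and exclusivity", {
  cfg <- sim_config(genome_length = 200000L, n_chrom = 2L, n_genes = 40L,
                    gmc_ppm = 100)
  ref <- simulate_reference(cfg, seed = 5)
  truth <- plant_modifications(ref, cfg, seed = 5)
  n_cyt <- nrow(truth)
  n_gmc <- sum(truth$state == "5gmC")
  target <- round(cfg$gmc_ppm * n_cyt / 1e6)
  expect_lte(abs(n_gmc - target) / target, 0.2)     # realized density
  shared <- sum(truth$f_gmc > 0 & truth$f_mc > 0)
  excl_frac <- 1 - shared / n_gmc
  expect_lte(abs(excl_frac - cfg$gmc_exclusive_fraction), 0.1)
  ## 5mC CpG rate exceeds CHH rate under defaults
  rate <- truth[, mean(f_mc > 0), by = context]
  expect_gt(rate[context == "CG"]$V1, rate[context == "CHH"]$V1)
  ## determinism
  truth2 <- plant_modifications(ref, cfg, seed = 5)
  expect_identical(as.data.frame(truth), as.data.frame(truth2))
})

test_that("forced exclusivity and all-zero planting behave as limits", {
  cfg <- sim_config(genome_length = 100000L, n_chrom = 1L, n_genes = 10L,
                    gmc_ppm = 200, gmc_exclusive_fraction = 1)
  ref <- simulate_reference(cfg, seed = 9)
  truth <- plant_modifications(ref, cfg, seed = 9)
  expect_equal(sum(truth$f_gmc > 0 & truth$f_mc > 0), 0L)

  cfg0 <- sim_config(genome_length = 50000L, n_chrom = 1L, n_genes = 5L,
                     p_mc = c(CG = 0, CHG = 0, CHH = 0), gmc_ppm = 1e-9)
  ref0 <- simulate_reference(cfg0, seed = 9)
  truth0 <- plant_modifications(ref0, cfg0, seed = 9)
  expect_true(all(truth0$state == "C"))
  expect_true(all(truth0$f_mc == 0 & truth0$f_gmc == 0))
})

test_that("count simulation conserves depth and is deterministic", {
  truth <- make_truth(5000, state = "5mC", f_mc = 0.5)
  prof <- chemistry_profile("DEA")
  rec <- simulate_counts(truth, prof, seed = 3, depth = 77)
  expect_true(all(rec$n_unconverted + rec$n_converted == 77L))
  rec2 <- simulate_counts(truth, prof, seed = 3, depth = 77)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  cfg <- sim_config()
  nb <- simulate_counts(truth, prof, cfg, seed = 3)
  expect_true(all(nb$n_unconverted >= 0 & nb$n_converted >= 0))
})

test_that("empirical unconverted fraction matches the chemistry model", {
  ## >= 1e5 observations per case; agreement within 3 binomial SE
  cases <- list(
    list(prof = chemistry_profile("DEA"), state = "C", f_mc = 0, f_gmc = 0,
         p = 0.002),
    list(prof = chemistry_profile("DEA"), state = "5gmC", f_mc = 0, f_gmc = 1,
         p = 1),
    list(prof = chemistry_profile("WGBS"), state = "5mC", f_mc = 1, f_gmc = 0,
         p = 1),
    list(prof = chemistry_profile("WGBS"), state = "5mC", f_mc = 0.37,
         f_gmc = 0, p = 0.37 * 1 + 0.63 * 0.002)
  )
  for (cs in cases) {
    truth <- make_truth(2000, state = cs$state, f_mc = cs$f_mc,
                        f_gmc = cs$f_gmc, context = "CG")
    rec <- simulate_counts(truth, cs$prof, seed = 11, depth = 50)
    n_obs <- sum(rec$n_unconverted + rec$n_converted)
    phat <- sum(rec$n_unconverted) / n_obs
    se <- sqrt(cs$p * (1 - cs$p) / n_obs)
    expect_lte(abs(phat - cs$p), max(3 * se, 1e-12))
  }
})

test_that("fully protected and fully converted limits are exact", {
  ## protected 5gmC at f=1 keeps every read as C
  t_gmc <- make_truth(100, state = "5gmC", f_gmc = 1)
  rec <- simulate_counts(t_gmc, chemistry_profile("DEA"), seed = 1, depth = 50)
  expect_true(all(rec$n_unconverted == 50L))
  ## bisulfite leaves 5mC untouched at f=1
  t_mc <- make_truth(100, state = "5mC", f_mc = 1)
  rec2 <- simulate_counts(t_mc, chemistry_profile("WGBS"), seed = 1, depth = 80)
  expect_true(all(rec2$n_unconverted == 80L))
})

test_that("spike-in set carries the bundled template and full-5mC truth", {
  sp <- make_spikeins()
  expect_equal(nchar(sp$sequences[["spikein_5mC"]]), 480L)
  expect_equal(substr(sp$sequences[["spikein_5mC"]], 1, 24),
               "GAATTCTTGCAGCACTAGTGCATC")
  amp <- sp$truth[sp$truth$chrom == "spikein_5mC"]
  expect_true(all(amp$state == "5mC" & amp$f_mc == 1))
  lam <- sp$truth[sp$truth$chrom == "spikein_lambda"]
  expect_true(all(lam$state == "C" & lam$f_mc == 0))
  ## the control is a bundled constant: identical across calls
  expect_identical(sp$sequences, make_spikeins()$sequences)
})

test_that("expression link is null when coefficients are zero", {
  fx <- assoc_fixture()
  cfg0 <- sim_config(genome_length = 1500000L, n_chrom = 4L, n_genes = 500L,
                     gmc_ppm = 600, expr_coef_gmc = 0, expr_coef_mc = 0)
  expr0 <- simulate_expression(fx$truth, fx$ref$genes, cfg0, seed = 21)
  g <- fx$ref$genes$genes
  first_third <- data.table(
    gene_id = g$gene_id, chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start, g$end - (g$end - g$start) %/% 3L),
    end = ifelse(g$strand == "+", g$start + (g$end - g$start) %/% 3L, g$end))
  cov_g <- deaseq:::region_mean(fx$truth, first_third, "f_gmc")
  rho <- suppressWarnings(cor(expr0$fpkm, cov_g, method = "spearman"))
  expect_lt(abs(rho), 0.1)
})

test_that("expression link recovers configured coefficient signs", {
  fx <- assoc_fixture()
  g <- fx$ref$genes$genes
  first_third <- data.table(
    gene_id = g$gene_id, chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start, g$end - (g$end - g$start) %/% 3L),
    end = ifelse(g$strand == "+", g$start + (g$end - g$start) %/% 3L, g$end))
  cov_g <- deaseq:::region_mean(fx$truth, first_third, "f_gmc")
  cov_m <- deaseq:::region_mean(fx$truth, g[, .(gene_id, chrom, start, end)],
                                "f_mc")
  ct_g <- suppressWarnings(
    cor.test(fx$expr$fpkm, cov_g, method = "spearman", exact = FALSE))
  ct_m <- suppressWarnings(
    cor.test(fx$expr$fpkm, cov_m, method = "spearman", exact = FALSE))
  expect_gt(ct_g$estimate, 0)
  expect_lt(ct_g$p.value, 0.05)
  expect_lt(ct_m$estimate, 0)
})
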