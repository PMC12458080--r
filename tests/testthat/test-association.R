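test_that("site overlap accounting closes on degenerate inputs", {
  a <- data.table(chrom = "chr1", pos = 1:5, strand = "+", ratio = 0.5)
  b <- data.table(chrom = "chr1", pos = 6:9, strand = "+", ratio = 0.5)
  ov <- site_overlap(a, b)
  expect_equal(ov$n_shared, 0L)
  expect_equal(ov$gmc_exclusive_fraction, 1)
  expect_equal(ov$mc_exclusive_fraction, 1)
  expect_equal(ov$n_shared + ov$n_gmc_exclusive, ov$n_gmc)
  expect_equal(ov$n_shared + ov$n_mc_exclusive, ov$n_mc)

  same <- site_overlap(a, a)
  expect_equal(same$jaccard, 1)
  expect_equal(same$gmc_exclusive_fraction, 0)
})

test_that("called-site exclusivity recovers the planted fraction", {
  fx <- assoc_fixture()
  expect_gte(nrow(fx$gmc), 500L)
  ov <- site_overlap(fx$gmc, fx$mc)
  expect_gte(ov$gmc_exclusive_fraction, 0.55)
  expect_lte(ov$gmc_exclusive_fraction, 0.65)
  ## accounting closes on real data too
  expect_equal(ov$n_shared + ov$n_gmc_exclusive, ov$n_gmc)
  ## shared sites carry higher 5gmC level than exclusive ones (generator
  ## draws shared fractions high)
  expect_gt(ov$gmc_ratio_shared$mean, 0)
})

test_that("expression groups are stable-ordered quantiles", {
  e <- data.table(gene_id = sprintf("g%02d", 1:8), fpkm = c(8, 7, 6, 5, 4, 3, 2, 1))
  q <- expression_quartiles(e, 0.25)
  expect_equal(q$high, c("g01", "g02"))
  expect_equal(q$low, c("g08", "g07"))

  ties <- data.table(gene_id = sprintf("g%02d", 1:8), fpkm = 1)
  qt <- expression_quartiles(ties, 0.25)
  expect_equal(qt$high, c("g01", "g02"))  # stable id order
  expect_equal(length(qt$low), 2L)

  expect_error(expression_quartiles(e, 0.6), "parameter error")

  set.seed(4)
  big <- data.table(gene_id = sprintf("g%04d", 1:1000),
                    fpkm = exp(rnorm(1000)))
  qb <- expression_quartiles(big, 0.25)
  expect_gte(min(big[gene_id %in% qb$high]$fpkm),
             max(big[gene_id %in% qb$low]$fpkm))
})

## single-gene models for metagene geometry checks
one_gene <- function(strand = "+") {
  gene_models(data.table(gene_id = "g1", transcript_id = "g1.t1",
                         chrom = "chr1", strand = strand,
                         start = 5000L, end = 11000L),
              data.table(gene_id = "g1", start = 5000L, end = 11000L))
}

test_that("metagene profile is flat for uniform signal and bounded", {
  gm <- one_gene()
  rec <- make_records("chr1", seq(4001L, 12000L, by = 7L), "+", nu = 5L, nc = 5L)
  mg <- metagene_profile(rec, gm)
  prof <- mg$profiles$all
  expect_equal(mg$n_bins, 100L)
  covered <- !is.na(prof)
  expect_true(all(abs(prof[covered] - 0.5) < 1e-9))
  expect_true(all(prof[covered] >= 0 & prof[covered] <= 1))
})

test_that("metagene profile tracks a 5'-loaded step and strand symmetry", {
  gm_plus <- one_gene("+")
  pos <- seq(5001L, 11000L, by = 3L)
  nu <- ifelse(pos <= 8000L, 10L, 0L)   # signal only in the first body half
  rec_plus <- make_records("chr1", pos, "+", nu = nu, nc = 10L - nu)
  mp <- metagene_profile(rec_plus, gm_plus)$profiles$all
  body <- mp[21:80]
  expect_gt(mean(body[1:25], na.rm = TRUE), mean(body[36:60], na.rm = TRUE))

  ## equivalent minus-strand gene with mirrored signal gives the same profile
  gm_minus <- one_gene("-")
  nu_m <- ifelse(pos > 8000L, 10L, 0L)  # 5' half in transcription orientation
  rec_minus <- make_records("chr1", pos, "+", nu = nu_m, nc = 10L - nu_m)
  mm <- metagene_profile(rec_minus, gm_minus)$profiles$all
  expect_equal(mm, mp)
})

test_that("metagene profile is invariant under gene order permutation", {
  fx <- assoc_fixture()
  gm <- fx$ref$genes
  set.seed(2)
  perm <- gene_models(gm$genes[sample(nrow(gm$genes))], gm$exons)
  a <- metagene_profile(fx$dea, gm)
  b <- metagene_profile(fx$dea, perm)
  expect_equal(a$profiles$all, b$profiles$all)
})

test_that("segment correlation recovers the generated expression link", {
  fx <- assoc_fixture()
  sc_g <- segment_correlation(fx$dea, fx$ref$genes, fx$expr)
  ft <- sc_g[sc_g$region == "body_first_third" & sc_g$stat == "mean"]
  expect_gt(ft$estimate, 0)
  expect_lt(ft$p_value, 0.05)

  sc_m <- segment_correlation(fx$wgbs, fx$ref$genes, fx$expr)
  ftm <- sc_m[sc_m$region == "body_first_third" & sc_m$stat == "mean"]
  expect_lt(ftm$estimate, 0)
})

test_that("segment correlation flags degenerate and unstable inputs", {
  gm <- one_gene()
  rec <- make_records("chr1", seq(5001L, 11000L, by = 11L), "+", nu = 5L, nc = 5L)
  e <- data.table(gene_id = "g1", fpkm = 3.2)
  sc <- segment_correlation(rec, gm, e)
  expect_true(all(sc$flag %in% c("degenerate", "unstable")))

  ## constant modification across genes is degenerate even with many genes
  fx <- assoc_fixture()
  const <- copy(fx$dea)[, `:=`(n_unconverted = 5L, n_converted = 5L)]
  scc <- segment_correlation(const, fx$ref$genes, fx$expr)
  expect_true(all(scc[scc$stat == "mean"]$flag == "degenerate"))
})

test_that("knockout-response proportions and exact test behave", {
  de <- data.table(gene_id = sprintf("g%02d", 1:20),
                   status = c(rep("down", 3), rep("ns", 7), rep("down", 2),
                              rep("up", 1), rep("ns", 7)))
  withg <- sprintf("g%02d", 1:10)
  without <- sprintf("g%02d", 11:20)
  r <- de_proportions(withg, without, de)
  expect_equal(r$table$frac_down, c(0.3, 0.2))

  expect_error(de_proportions(withg, withg, de), "partition error")

  r0 <- de_proportions(character(0), without, de)
  expect_true(is.na(r0$table$frac_down[1]))
  expect_match(r0$flag, "empty group")
})

test_that("generated knockout-response rates are recovered at scale", {
  ids <- sprintf("g%05d", 1:5000)
  has_gmc <- rep(c(TRUE, FALSE), each = 2500)
  de <- simulate_de_table(ids, has_gmc, p_down = c(0.2, 0.14), seed = 6)
  r <- de_proportions(ids[has_gmc], ids[!has_gmc], de)
  expect_lte(abs(r$table$frac_down[1] - 0.2), 0.03)
  expect_lte(abs(r$table$frac_down[2] - 0.14), 0.03)
  expect_gt(r$table$frac_down[1], r$table$frac_down[2])
  expect_lt(r$test_down, 0.05)
})
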