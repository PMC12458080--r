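## Synthetic-chemistry simulator: genome, annotation, planted modification
## states, spike-ins, conversion counts under each chemistry, and expression
## values linked to gene-body modification. Everything is deterministic given
## (config, seed).

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a GC-rich genome (GC 0.64), 5mC planted preferentially at CpG, sparse
#' 5gmC at ~10 ppm of cytosines with CHH-preferential context weights and an
#' intron bias, ~60% of 5gmC sites mutually exclusive of 5mC, per-site 5gmC
#' molecular fraction in [0.5, 1), and negative-binomial depth around 100x.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_length = 200000L, n_chrom = 2L, gc = 0.64,
    n_genes = 40L,
    exon_count_range = c(2L, 5L), exon_len_range = c(150L, 400L),
    intron_len_range = c(100L, 400L), intergenic_mean = 800,
    te_count = 15L, te_len_range = c(500L, 1500L),
    marks = c("H3K9me1", "H3K4me3", "H3K9me3"),
    mark_count = 12L, mark_len_range = c(500L, 2000L),
    p_mc = c(CG = 0.05, CHG = 0.01, CHH = 0.012),
    mc_h3k9me1_boost = 3,
    f_mc_beta = list(CG = c(8, 2), CHG = c(5, 5), CHH = c(4, 6)),
    gmc_ppm = 10,
    gmc_context_weights = c(CG = 0.15, CHG = 0.15, CHH = 0.7),
    gmc_exclusive_fraction = 0.6,
    gmc_intron_bias = 3,
    gmc_f_range = c(0.5, 1),
    gmc_shared_f_range = c(0.6, 0.75),
    shared_mc_f_min = 0.25,
    depth_mean = 100, depth_size = 20,
    ko_noise_sites = 0L, ko_noise_ratio_range = c(0.2, 0.5),
    expr_coef_gmc = 1, expr_coef_mc = -1, expr_noise_sd = 1, expr_log_mean = 2
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  probs <- c(cfg$gc, cfg$p_mc, cfg$gmc_exclusive_fraction, cfg$gmc_context_weights)
  if (any(probs < 0 | probs > 1)) stop("config error: probability outside [0,1]")
  if (cfg$gmc_ppm <= 0) stop("config error: gmc_ppm must be > 0")
  structure(cfg, class = "sim_config")
}

## random sequence with target GC
random_sequence <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a reference: genome, gene models, TE and histone-mark intervals
#'
#' Genes are packed left to right with geometric intergenic gaps and are
#' non-overlapping; TEs are placed in intergenic space; histone-mark
#' intervals are placed uniformly. All intervals lie within chromosome
#' bounds. Identical (config, seed) gives byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return list(genome, genes, tes, marks): a [genome_ref()], a
#'   [gene_models()], an [interval_set()] of TEs and a named list of
#'   [interval_set()] per histone mark.
#' @export
simulate_reference <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  chrom_len <- rep(config$genome_length %/% config$n_chrom, config$n_chrom)
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  seqs <- setNames(vapply(chrom_len, random_sequence, character(1), gc = config$gc),
                   chroms)
  genome <- genome_ref(seqs)

  genes_l <- list(); exons_l <- list()
  gi <- 0L
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  for (ci in seq_along(chroms)) {
    cursor <- 0L
    placed <- 0L
    while (placed < per_chrom[ci]) {
      gap <- rgeom(1, 1 / config$intergenic_mean) + 50L
      n_ex <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]), 1)
      ex_len <- sample(seq(config$exon_len_range[1], config$exon_len_range[2]), n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1)
        sample(seq(config$intron_len_range[1], config$intron_len_range[2]),
               n_ex - 1, replace = TRUE) else integer(0)
      span <- sum(ex_len) + sum(in_len)
      if (span > chrom_len[ci])
        stop("config error: gene span exceeds chromosome length")
      start <- cursor + gap
      if (start + span > chrom_len[ci]) {
        stop("config error: cannot pack ", config$n_genes,
             " genes into the genome; increase genome_length")
      }
      gi <- gi + 1L
      ex_start <- start + c(0L, cumsum(ex_len + c(in_len, 0L))[-n_ex])
      strand <- sample(c("+", "-"), 1)
      genes_l[[gi]] <- data.table(gene_id = sprintf("gene%03d", gi),
                                  transcript_id = sprintf("gene%03d.t1", gi),
                                  chrom = chroms[ci], strand = strand,
                                  start = start, end = start + span)
      exons_l[[gi]] <- data.table(gene_id = sprintf("gene%03d", gi),
                                  start = as.integer(ex_start),
                                  end = as.integer(ex_start + ex_len))
      cursor <- start + span
      placed <- placed + 1L
    }
  }
  genes <- if (gi > 0L) gene_models(rbindlist(genes_l), rbindlist(exons_l)) else
    gene_models(data.table(gene_id = character(), transcript_id = character(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer()),
                data.table(gene_id = character(), start = integer(), end = integer()))

  place_intervals <- function(n, len_range, avoid = NULL) {
    out <- list(); tries <- 0L; k <- 0L
    while (k < n && tries < n * 200L) {
      tries <- tries + 1L
      ci <- sample(seq_along(chroms), 1)
      len <- sample(seq(len_range[1], len_range[2]), 1)
      if (len >= chrom_len[ci]) next
      s <- sample.int(chrom_len[ci] - len, 1) - 1L
      cand <- data.table(chrom = chroms[ci], start = s, end = s + len)
      clash <- FALSE
      if (!is.null(avoid) && nrow(avoid) > 0L)
        clash <- avoid[chrom == cand$chrom & start < cand$end & end > cand$start, .N] > 0L
      if (!clash && k > 0L) {
        prev <- rbindlist(out)
        clash <- prev[chrom == cand$chrom & start < cand$end & end > cand$start, .N] > 0L
      }
      if (!clash) { k <- k + 1L; out[[k]] <- cand }
    }
    if (k == 0L) data.table(chrom = character(), start = integer(), end = integer())
    else rbindlist(out)
  }
  gene_spans <- if (nrow(genes$genes) > 0L)
    genes$genes[, .(chrom, start, end)] else NULL
  tes <- interval_set(place_intervals(config$te_count, config$te_len_range,
                                      avoid = gene_spans), "TE")
  marks <- lapply(config$marks, function(mk)
    interval_set(place_intervals(config$mark_count, config$mark_len_range), mk))
  names(marks) <- config$marks
  list(genome = genome, genes = genes, tes = tes, marks = marks)
}

## membership of 1-based positions in an interval_set (0-based half-open)
in_intervals <- function(chrom, pos, iset) {
  if (nrow(iset$intervals) == 0L) return(rep(FALSE, length(pos)))
  gr_q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  gr_s <- GenomicRanges::GRanges(iset$intervals$chrom,
                                 IRanges::IRanges(iset$intervals$start + 1L,
                                                  iset$intervals$end))
  IRanges::overlapsAny(gr_q, gr_s)
}

#' Plant ground-truth modification states
#'
#' Plants 5mC per-context (CpG-preferential under defaults, boosted inside
#' H3K9me1 intervals) and sparse 5gmC at the configured ppm of cytosines
#' with CHH-preferential context weights and an intron bias. A configured
#' fraction of 5gmC sites is exclusive of 5mC; the remainder share their
#' cytosine with 5mC (f_mc + f_gmc <= 1), which is what WGBS-minus-DEA
#' deconvolution sees as overlapping sites.
#'
#' @param reference Output of [simulate_reference()].
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return data.table over every cytosine: chrom, pos, strand, context,
#'   trinucleotide, state in {C, 5mC, 5gmC}, f_mc, f_gmc.
#' @export
plant_modifications <- function(reference, config = sim_config(), seed = 1) {
  set.seed(seed)
  cyt <- genome_cytosines(reference$genome)
  cyt[, `:=`(f_mc = 0, f_gmc = 0)]
  plantable <- cyt$context %in% chem_contexts

  ## 5mC: per-context probability, boosted inside H3K9me1 intervals
  p <- rep(0, nrow(cyt))
  p[plantable] <- config$p_mc[cyt$context[plantable]]
  if ("H3K9me1" %in% names(reference$marks) && config$mc_h3k9me1_boost != 1) {
    inmark <- in_intervals(cyt$chrom, cyt$pos, reference$marks[["H3K9me1"]])
    p[inmark] <- pmin(p[inmark] * config$mc_h3k9me1_boost, 0.95)
  }
  is_mc <- rbinom(nrow(cyt), 1L, p) == 1L
  for (ctx in chem_contexts) {
    sel <- which(is_mc & cyt$context == ctx)
    if (length(sel) > 0L) {
      ab <- config$f_mc_beta[[ctx]]
      cyt$f_mc[sel] <- rbeta(length(sel), ab[1], ab[2])
    }
  }

  ## 5gmC: ppm-scale site count, context-weighted, intron-biased
  ## deterministic target count: at ppm scale a Poisson draw would routinely
  ## miss the configured density by more than the tolerated 20%
  n_cyt <- nrow(cyt)
  n_gmc <- as.integer(round(config$gmc_ppm * n_cyt / 1e6))
  if (n_gmc > 0L) {
    w <- config$gmc_context_weights / sum(config$gmc_context_weights)
    n_ctx <- as.integer(rmultinom(1, n_gmc, w[chem_contexts]))
    names(n_ctx) <- chem_contexts
    intron_gr <- if (nrow(reference$genes$introns) > 0L) {
      g2c <- setNames(reference$genes$genes$chrom, reference$genes$genes$gene_id)
      interval_set(data.table(chrom = g2c[reference$genes$introns$gene_id],
                              start = reference$genes$introns$start,
                              end = reference$genes$introns$end), "intron")
    } else NULL
    in_intr <- if (!is.null(intron_gr))
      in_intervals(cyt$chrom, cyt$pos, intron_gr) else rep(FALSE, n_cyt)
    n_excl <- round(n_gmc * config$gmc_exclusive_fraction)
    picked <- integer(0)
    for (ctx in chem_contexts) {
      need <- n_ctx[[ctx]]
      if (need == 0L) next
      pool <- which(cyt$context == ctx)
      if (length(pool) < need)
        stop("config error: requested ppm exceeds available ", ctx, " sites")
      wts <- ifelse(in_intr[pool], config$gmc_intron_bias, 1)
      picked <- c(picked, sample(pool, need, prob = wts))
    }
    picked <- sample(picked)  # shuffle before exclusive/shared split
    excl <- head(picked, n_excl)
    shared <- tail(picked, length(picked) - n_excl)
    cyt$f_gmc[excl] <- runif(length(excl), config$gmc_f_range[1], config$gmc_f_range[2])
    cyt$f_mc[excl] <- 0
    if (length(shared) > 0L) {
      fg <- runif(length(shared), config$gmc_shared_f_range[1],
                  config$gmc_shared_f_range[2])
      cyt$f_gmc[shared] <- fg
      cyt$f_mc[shared] <- runif(length(shared), config$shared_mc_f_min,
                                pmax(config$shared_mc_f_min, 1 - fg))
    }
  }
  cyt[, state := fifelse(f_gmc > 0, "5gmC", fifelse(f_mc > 0, "5mC", "C"))]
  setcolorder(cyt, c("chrom", "pos", "strand", "context", "trinucleotide",
                     "state", "f_mc", "f_gmc"))
  cyt[]
}

#' Simulate conversion counts under a chemistry
#'
#' Per cytosine, depth d is drawn from a negative-binomial depth model and
#' the unconverted count from Binomial(d, p_C) with
#' p_C = f_gmc (1 - pT_5gmC) + f_mc (1 - pT_5mC) + (1 - f_gmc - f_mc)(1 - pT_C).
#' For TET-BS the per-site 5mC escape is Beta-distributed around the
#' profile's context mean (precision `site_phi`), modelling site-to-site
#' variability in oxidation efficiency.
#'
#' @param truth Truth table from [plant_modifications()] (or spike-in truth).
#' @param profile A [chemistry_profile()].
#' @param config A [sim_config()] (depth model) or NULL with `depth` given.
#' @param seed Integer RNG seed.
#' @param depth Optional fixed depth (scalar or vector), overriding the
#'   negative-binomial model.
#' @return Cytosine records: chrom, pos, strand, n_unconverted, n_converted,
#'   context, trinucleotide.
#' @export
simulate_counts <- function(truth, profile, config = sim_config(), seed = 1,
                            depth = NULL) {
  set.seed(seed)
  n <- nrow(truth)
  d <- if (!is.null(depth)) rep_len(as.integer(depth), n) else
    rnbinom(n, mu = config$depth_mean, size = config$depth_size)
  pT_C <- profile_p_T(profile, "C", truth$context)
  pT_g <- profile_p_T(profile, "5gmC", truth$context)
  pT_m <- profile_p_T(profile, "5mC", truth$context)
  if (is.finite(profile$site_phi)) {
    has_mc <- which(truth$f_mc > 0)
    if (length(has_mc) > 0L) {
      esc_mean <- 1 - pT_m[has_mc]
      ok <- esc_mean > 0 & esc_mean < 1
      esc <- esc_mean
      esc[ok] <- rbeta(sum(ok), esc_mean[ok] * profile$site_phi,
                       (1 - esc_mean[ok]) * profile$site_phi)
      pT_m[has_mc] <- 1 - esc
    }
  }
  p_unconv <- truth$f_gmc * (1 - pT_g) + truth$f_mc * (1 - pT_m) +
    (1 - truth$f_gmc - truth$f_mc) * (1 - pT_C)
  if (any(p_unconv < -1e-9 | p_unconv > 1 + 1e-9))
    stop("profile error: unconverted probability outside [0,1]")
  p_unconv <- pmin(pmax(p_unconv, 0), 1)
  nu <- rbinom(n, d, p_unconv)
  data.table(chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
             n_unconverted = nu, n_converted = d - nu,
             context = truth$context, trinucleotide = truth$trinucleotide)
}

## The fully-methylated spike-in amplicon template: 480 bp, PCR-amplified
## with 5-methyl-dCTP so every C on both strands is 5mC.
spikein_template_480 <- paste0(
  "GAATTCTTGCAGCACTAGTGCATCTATAAGTTATCTCAAATCAAGAAATCAGTCTAATGA",
  "GAATTTCAATAACTTCAGCAATTTAAGCTGCATGCATCAGTGTCATCGTTATTTTTTTTT",
  "TGAGACGTAGTCATGCTCTGTTGCTGAGTCTGCAGTACAGTGACGAGATATCGACTCAGC",
  "ACAACATCTGCATCACATGTTCAAGCGATTCTCATGCTTCAGCTTGCAGAGTAGCTGTCA",
  "CTACAGACACTGAGCAGCATGCGTGACTAATTTTTGTATTTTTAGTAGAGAGTGCATTTC",
  "GTCATGTTGTACAGTCTAGTTTCAAACTCATGACTTCAGTTGATCTAACTGACACGATCT",
  "CAGAATTTACTGTCATTACAGTACTGTCACACAGTGACAGTCATTTTTCTTAATTTTTAA",
  "AAATATTAAAGTTTTATCTCATTCGTGTTGAAGCATATTCGTGATTTAAAAGTTGCAAAG")

#' Spike-in control set
#'
#' The fully-5mC spike-in is the bundled 480-bp amplicon template (every C
#' on both strands carries 5mC at fraction 1). The unmodified control is a
#' synthetic lambda-like sequence generated deterministically (it stands in
#' for unmodified phage lambda DNA; all its cytosines are unmodified C).
#'
#' @param lambda_length Length of the synthetic unmodified control.
#' @return list of class `spikein_set`: `sequences` (named character),
#'   `classes` (chrom -> class), `truth` (cytosine-level truth table).
#' @export
make_spikeins <- function(lambda_length = 2000L) {
  seed_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(480L)  # fixed: the control is a bundled constant, not a draw
  lambda <- random_sequence(lambda_length, gc = 0.5)
  if (!is.null(seed_state)) assign(".Random.seed", seed_state, envir = globalenv())
  seqs <- c(spikein_5mC = spikein_template_480, spikein_lambda = lambda)
  genome <- genome_ref(seqs)
  truth <- genome_cytosines(genome)
  truth[, `:=`(f_mc = fifelse(chrom == "spikein_5mC", 1, 0), f_gmc = 0)]
  truth[, state := fifelse(f_mc > 0, "5mC", "C")]
  structure(list(sequences = seqs,
                 classes = c(spikein_5mC = "fully-5mC",
                             spikein_lambda = "unmodified"),
                 truth = truth[]),
            class = "spikein_set")
}

#' Simulate spike-in conversion counts
#'
#' @param spikeins A [make_spikeins()] set.
#' @param profile A [chemistry_profile()].
#' @param seed Integer RNG seed.
#' @param total_observations Approximate total base observations per class;
#'   converted into a uniform per-cytosine depth.
#' @return Cytosine records over the spike-in sequences.
#' @export
simulate_spikein_counts <- function(spikeins, profile, seed = 1,
                                    total_observations = 1e5) {
  truth <- spikeins$truth
  d <- integer(nrow(truth))
  for (cl in unique(spikeins$classes)) {
    sel <- truth$chrom %in% names(spikeins$classes)[spikeins$classes == cl]
    d[sel] <- as.integer(ceiling(total_observations / sum(sel)))
  }
  simulate_counts(truth, profile, seed = seed, depth = d)
}

#' Simulate a knockout-control sample
#'
#' The Dnmt1-KO strain carries neither 5mC nor 5gmC: its truth is the same
#' cytosine universe with every state C. An optional noise injector plants
#' spurious unconverted signal at a few random sites to exercise KO
#' subtraction.
#'
#' @param truth Wild-type truth table (only the cytosine universe is used).
#' @param profile A [chemistry_profile()].
#' @param config A [sim_config()]; `ko_noise_sites` and
#'   `ko_noise_ratio_range` control the injector.
#' @param seed Integer RNG seed.
#' @return Cytosine records for the KO sample.
#' @export
simulate_ko_sample <- function(truth, profile, config = sim_config(), seed = 1) {
  ko_truth <- copy(truth)
  ko_truth[, `:=`(state = "C", f_mc = 0, f_gmc = 0)]
  rec <- simulate_counts(ko_truth, profile, config, seed = seed)
  if (config$ko_noise_sites > 0L) {
    set.seed(seed + 7L)
    idx <- sample(nrow(rec), min(config$ko_noise_sites, nrow(rec)))
    dpt <- rec$n_unconverted[idx] + rec$n_converted[idx]
    r <- runif(length(idx), config$ko_noise_ratio_range[1],
               config$ko_noise_ratio_range[2])
    nu <- pmin(as.integer(round(dpt * r)), dpt)
    rec[idx, `:=`(n_unconverted = nu, n_converted = dpt - nu)]
  }
  rec
}

#' Simulate expression linked to gene-body modification
#'
#' log-FPKM is a linear model on two standardized gene-level covariates:
#' mean true 5gmC fraction over the first third of the gene body (positive
#' coefficient under defaults) and mean true 5mC fraction over the gene body
#' (negative coefficient), plus Gaussian noise.
#'
#' @param truth Truth table from [plant_modifications()].
#' @param genes A [gene_models()].
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return data.table(gene_id, fpkm) with one record per gene.
#' @export
simulate_expression <- function(truth, genes, config = sim_config(), seed = 1) {
  set.seed(seed)
  g <- genes$genes
  if (nrow(g) == 0L) return(data.table(gene_id = character(), fpkm = numeric()))
  first_third <- g[, .(gene_id, chrom,
                       start = ifelse(strand == "+", start,
                                      end - (end - start) %/% 3L),
                       end = ifelse(strand == "+", start + (end - start) %/% 3L,
                                    end))]
  cov_g <- region_mean(truth, first_third, "f_gmc")
  cov_m <- region_mean(truth, g[, .(gene_id, chrom, start, end)], "f_mc")
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
  logf <- config$expr_log_mean + config$expr_coef_gmc * zs(cov_g) +
    config$expr_coef_mc * zs(cov_m) + rnorm(nrow(g), sd = config$expr_noise_sd)
  data.table(gene_id = g$gene_id, fpkm = exp(logf))
}

## mean of a truth column over cytosines in per-gene regions (0 if none)
region_mean <- function(truth, regions, column) {
  out <- rep(0, nrow(regions))
  if (nrow(truth) == 0L) return(out)
  gr_q <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$pos, truth$pos))
  keep <- regions$end > regions$start
  if (!any(keep)) return(out)
  gr_s <- GenomicRanges::GRanges(regions$chrom[keep],
                                 IRanges::IRanges(regions$start[keep] + 1L,
                                                  regions$end[keep]))
  hits <- GenomicRanges::findOverlaps(gr_q, gr_s)
  if (length(hits) == 0L) return(out)
  dt <- data.table(val = truth[[column]][S4Vectors::queryHits(hits)],
                   reg = S4Vectors::subjectHits(hits))
  agg <- dt[, .(m = mean(val)), by = reg]
  out[which(keep)[agg$reg]] <- agg$m
  out
}

#' Simulate a differential-expression call table
#'
#' Assigns up/down/ns status per gene with group-specific down-regulation
#' probabilities, emulating the knockout-response contrast between genes
#' with and without 5gmC.
#'
#' @param gene_ids Character vector of gene IDs.
#' @param has_gmc Logical vector: gene carries 5gmC.
#' @param p_down Probability of "down" for c(with, without) 5gmC groups.
#' @param p_up Probability of "up" for c(with, without) groups.
#' @param seed Integer RNG seed.
#' @return data.table(gene_id, status) with status in {up, down, ns}.
#' @export
simulate_de_table <- function(gene_ids, has_gmc,
                              p_down = c(0.20, 0.14), p_up = c(0.005, 0.05),
                              seed = 1) {
  set.seed(seed)
  pd <- ifelse(has_gmc, p_down[1], p_down[2])
  pu <- ifelse(has_gmc, p_up[1], p_up[2])
  u <- runif(length(gene_ids))
  status <- fifelse(u < pd, "down", fifelse(u < pd + pu, "up", "ns"))
  data.table(gene_id = gene_ids, status = status)
}
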