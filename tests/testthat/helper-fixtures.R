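library(data.table)

## one record table built from parallel vectors
make_records <- function(chrom, pos, strand, nu, nc, context = "CHH",
                         tri = "CAT") {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             n_unconverted = as.integer(nu), n_converted = as.integer(nc),
             context = rep_len(context, length(pos)),
             trinucleotide = rep_len(tri, length(pos)))
}

## a bare truth table (no genome needed) for chemistry-level simulations
make_truth <- function(n, state = "C", f_mc = 0, f_gmc = 0, context = "CHH") {
  data.table(chrom = "chrT", pos = seq_len(n), strand = "+",
             context = rep_len(context, n), trinucleotide = "CNN",
             state = rep_len(state, n), f_mc = rep_len(f_mc, n),
             f_gmc = rep_len(f_gmc, n))
}

## medium synthetic study shared across association/landscape tests: 500
## genes, elevated 5gmC density so gene-level analyses have signal. Built
## once per test run.
.fixture_env <- new.env(parent = emptyenv())

assoc_fixture <- function() {
  if (!is.null(.fixture_env$assoc)) return(.fixture_env$assoc)
  cfg <- sim_config(genome_length = 1500000L, n_chrom = 4L, n_genes = 500L,
                    gmc_ppm = 600)
  ref <- simulate_reference(cfg, seed = 3)
  truth <- plant_modifications(ref, cfg, seed = 3)
  dea <- simulate_counts(truth, chemistry_profile("DEA"), cfg, seed = 3)
  wgbs <- simulate_counts(truth, chemistry_profile("WGBS"), cfg, seed = 4)
  gmc <- call_gmc_sites(dea, sample_id = "DEA")
  dec <- deconvolve_mc(wgbs, gmc)
  mc <- call_mc_sites(dec)
  expr <- simulate_expression(truth, ref$genes, cfg, seed = 5)
  .fixture_env$assoc <- list(cfg = cfg, ref = ref, truth = truth, dea = dea,
                             wgbs = wgbs, gmc = gmc, dec = dec, mc = mc,
                             expr = expr)
  .fixture_env$assoc
}

## brute-force context oracle on a strand-oriented trinucleotide, written
## directly from the CG/CHG/CHH definitions (independent of the package path)
oracle_context <- function(tri) {
  b2 <- substr(tri, 2, 2); b3 <- substr(tri, 3, 3)
  if (b2 == "G") return("CG")
  if (!b2 %in% c("A", "C", "T")) return("AMBIG")
  if (b3 == "G") return("CHG")
  if (b3 %in% c("A", "C", "T")) return("CHH")
  "AMBIG"
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
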