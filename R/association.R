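## Co-occurrence of 5mC and 5gmC and their relationships with
## transcription: exact positional overlap, expression quartiles, metagene
## profiles over scaled gene bodies, per-region rank correlations and
## knockout-response proportions.

#' Exact positional overlap of 5gmC and 5mC site sets
#'
#' Shared sites are exact (chrom, pos, strand) matches. Modification-ratio
#' summaries are computed separately for shared and exclusive sites of each
#' modification; a context x feature breakdown is included when the site
#' tables carry `context`/`feature` columns.
#'
#' @param gmc_sites,mc_sites Site tables with a `ratio` column.
#' @return list of class `overlap_report`: counts, Jaccard, per-group ratio
#'   summaries, optional breakdowns.
#' @export
site_overlap <- function(gmc_sites, mc_sites) {
  g <- as.data.table(gmc_sites); m <- as.data.table(mc_sites)
  kg <- site_key(g$chrom, g$pos, g$strand)
  km <- site_key(m$chrom, m$pos, m$strand)
  shared_keys <- intersect(kg, km)
  n_shared <- length(shared_keys)
  summarise <- function(r) {
    if (length(r) == 0L)
      return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_))
    list(n = length(r), mean = mean(r), sd = sd(r), median = median(r))
  }
  g_shared <- kg %in% shared_keys
  m_shared <- km %in% shared_keys
  breakdown <- function(dt, shared) {
    if (!all(c("context", "feature") %in% names(dt))) return(NULL)
    dt2 <- copy(dt)[, grp := fifelse(shared, "shared", "exclusive")]
    dt2[, .N, by = .(grp, context, feature)]
  }
  un <- length(union(kg, km))
  structure(list(
    n_gmc = nrow(g), n_mc = nrow(m), n_shared = n_shared,
    n_gmc_exclusive = nrow(g) - n_shared, n_mc_exclusive = nrow(m) - n_shared,
    gmc_exclusive_fraction = if (nrow(g) > 0L) (nrow(g) - n_shared) / nrow(g) else NA_real_,
    mc_exclusive_fraction = if (nrow(m) > 0L) (nrow(m) - n_shared) / nrow(m) else NA_real_,
    jaccard = if (un > 0L) n_shared / un else NA_real_,
    gmc_ratio_shared = summarise(g$ratio[g_shared]),
    gmc_ratio_exclusive = summarise(g$ratio[!g_shared]),
    mc_ratio_shared = summarise(m$ratio[m_shared]),
    mc_ratio_exclusive = summarise(m$ratio[!m_shared]),
    gmc_breakdown = breakdown(g, g_shared),
    mc_breakdown = breakdown(m, m_shared)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:", x$n_gmc, "5gmC sites,", x$n_mc, "5mC sites,",
      x$n_shared, "shared (Jaccard", round(x$jaccard, 3), ")\n",
      "5gmC exclusive fraction:", round(x$gmc_exclusive_fraction, 3), "\n")
  invisible(x)
}

#' Expression quartile (or quantile) groups
#'
#' Ranks genes by FPKM and returns the top and bottom fraction `q`; ties
#' are broken by stable gene-id order. Group size is floor(n q).
#'
#' @param expression data.table(gene_id, fpkm).
#' @param q Group fraction in (0, 0.5].
#' @return list(high, low): character vectors of gene IDs.
#' @export
expression_quartiles <- function(expression, q = 0.25) {
  if (q <= 0 || q > 0.5) stop("parameter error: q must be in (0, 0.5]")
  e <- as.data.table(expression)
  n_grp <- floor(nrow(e) * q)
  hi <- e[order(-fpkm, gene_id)][seq_len(n_grp)]
  lo <- e[order(fpkm, gene_id)][seq_len(n_grp)]
  list(high = hi$gene_id, low = lo$gene_id)
}

#' Metagene profile over scaled gene bodies
#'
#' Gene bodies are linearly rescaled to `body_bins` bins; fixed-width flank
#' bins of `flank_binwidth` bp cover `flank_bp` on each side. The profile is
#' the per-bin mean of the record modification ratio over covered cytosines,
#' orientation-aware (minus-strand genes are reversed). Genes shorter than
#' `body_bins` bp are skipped and counted.
#'
#' @param records Cytosine records (ratio = unconverted/depth is computed).
#' @param genes A [gene_models()].
#' @param groups Named list of gene-id vectors (e.g. expression quartiles);
#'   NULL profiles all genes as one group.
#' @param body_bins,flank_bp,flank_binwidth Binning parameters.
#' @param min_depth Minimum record depth to contribute.
#' @return list of class `metagene_profile`: `profiles` (named list of
#'   numeric vectors, length 2*flank_bins+body_bins, NA where uncovered),
#'   `n_bins`, `flank_bins`, `body_bins`, `skipped`.
#' @export
metagene_profile <- function(records, genes, groups = NULL, body_bins = 60L,
                             flank_bp = 1000L, flank_binwidth = 50L,
                             min_depth = 1L) {
  flank_bins <- flank_bp %/% flank_binwidth
  n_bins <- 2L * flank_bins + body_bins
  if (is.null(groups)) groups <- list(all = genes$genes$gene_id)
  rec <- as.data.table(records)
  rec[, depth := n_unconverted + n_converted]
  rec <- rec[depth >= min_depth]
  rec[, ratio := n_unconverted / depth]
  g <- genes$genes
  skipped <- 0L
  ## accumulate (bin, ratio) contributions per gene
  acc <- vector("list", nrow(g))
  gr_rec <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$pos, rec$pos))
  span <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(pmax(g$start - flank_bp, 0L) + 1L,
                                                  g$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(gr_rec, span)
  hl <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (gi in as.integer(names(hl))) {
    glen <- g$end[gi] - g$start[gi]
    if (glen < body_bins) { skipped <- skipped + 1L; next }
    ridx <- hl[[as.character(gi)]]
    p0 <- rec$pos[ridx] - 1L
    rel <- p0 - g$start[gi]
    bin <- integer(length(rel))
    up <- rel < 0L
    dn <- rel >= glen
    body <- !up & !dn
    bin[up] <- flank_bins - ((-rel[up] - 1L) %/% flank_binwidth)   # rel in [-flank,-1]
    bin[body] <- flank_bins + 1L + as.integer(rel[body] / glen * body_bins)
    bin[body] <- pmin(bin[body], flank_bins + body_bins)
    bin[dn] <- flank_bins + body_bins + 1L + ((rel[dn] - glen) %/% flank_binwidth)
    keep <- bin >= 1L & bin <= n_bins
    bin <- bin[keep]
    if (g$strand[gi] == "-") bin <- n_bins + 1L - bin
    acc[[gi]] <- data.table(gene_id = g$gene_id[gi], bin = bin,
                            ratio = rec$ratio[ridx][keep])
  }
  contrib <- rbindlist(acc[!vapply(acc, is.null, logical(1))])
  profiles <- lapply(groups, function(ids) {
    v <- rep(NA_real_, n_bins)
    if (nrow(contrib) > 0L) {
      sub <- contrib[gene_id %in% ids]
      if (nrow(sub) > 0L) {
        agg <- sub[, .(m = mean(ratio)), by = bin]
        v[agg$bin] <- agg$m
      }
    }
    v
  })
  structure(list(profiles = profiles, n_bins = n_bins, flank_bins = flank_bins,
                 body_bins = body_bins, skipped = skipped),
            class = "metagene_profile")
}

#' Gene-region definitions for correlation analyses
#'
#' Promoter (`promoter_bp` upstream of the TSS), first/middle/last third of
#' the gene body (transcription orientation), and downstream
#' (`downstream_bp` past the TES).
#'
#' @param genes A [gene_models()].
#' @param config An [annotation_config()].
#' @return data.table(gene_id, region, chrom, start, end), 0-based half-open.
#' @export
gene_regions <- function(genes, config = annotation_config()) {
  g <- genes$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    s <- g$start[i]; e <- g$end[i]; plus <- g$strand[i] == "+"
    len <- e - s
    b <- s + round(len * c(0, 1, 2, 3) / 3)
    thirds <- if (plus)
      data.table(region = c("body_first_third", "body_middle_third", "body_last_third"),
                 start = b[1:3], end = b[2:4])
    else
      data.table(region = c("body_last_third", "body_middle_third", "body_first_third"),
                 start = b[1:3], end = b[2:4])
    prom <- if (plus) data.table(region = "promoter",
                                 start = max(s - config$promoter_bp, 0L), end = s + 1L)
      else data.table(region = "promoter", start = e - 1L,
                      end = e + config$promoter_bp)
    down <- if (plus) data.table(region = "downstream", start = e,
                                 end = e + config$downstream_bp)
      else data.table(region = "downstream",
                      start = max(s - config$downstream_bp, 0L), end = s)
    out <- rbind(prom, thirds, down)
    out[, `:=`(gene_id = g$gene_id[i], chrom = g$chrom[i])]
    out
  })
  rbindlist(rows)[, .(gene_id, region, chrom, start, end)]
}

#' Rank correlation between expression and region-level modification
#'
#' Per gene and region, the record modification ratio is summarised as both
#' the mean and the maximum over covered cytosines (0 where no cytosine is
#' covered), then rank-correlated (Spearman by default) with FPKM across
#' genes.
#'
#' @param records Cytosine records.
#' @param genes A [gene_models()].
#' @param expression data.table(gene_id, fpkm).
#' @param config An [annotation_config()].
#' @param method "spearman" (default) or "pearson".
#' @param min_depth Minimum record depth to contribute.
#' @return data.table: region, stat ("mean"/"max"), estimate, p_value, n,
#'   flag ("" / "unstable" when n < 10 / "degenerate" when the summary is
#'   constant).
#' @export
segment_correlation <- function(records, genes, expression,
                                config = annotation_config(),
                                method = c("spearman", "pearson"),
                                min_depth = 1L) {
  method <- match.arg(method)
  rec <- as.data.table(records)
  rec[, depth := n_unconverted + n_converted]
  rec <- rec[depth >= min_depth]
  rec[, ratio := n_unconverted / depth]
  regions <- gene_regions(genes, config)
  e <- as.data.table(expression)
  ## overlap records with regions
  keep <- regions$end > regions$start
  regions <- regions[keep]
  gr_rec <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$pos, rec$pos))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_rec, gr_reg)
  dt <- data.table(ridx = S4Vectors::queryHits(hits),
                   gene_id = regions$gene_id[S4Vectors::subjectHits(hits)],
                   region = regions$region[S4Vectors::subjectHits(hits)])
  dt[, ratio := rec$ratio[ridx]]
  agg <- dt[, .(mean = mean(ratio), max = max(ratio)), by = .(gene_id, region)]
  region_names <- c("promoter", "body_first_third", "body_middle_third",
                    "body_last_third", "downstream")
  rows <- list()
  for (rg in region_names) {
    base <- data.table(gene_id = e$gene_id, fpkm = e$fpkm)
    sub <- agg[region == rg]
    base <- merge(base, sub[, .(gene_id, mean, max)], by = "gene_id", all.x = TRUE)
    base[is.na(mean), mean := 0]
    base[is.na(max), max := 0]
    for (st in c("mean", "max")) {
      x <- base[[st]]
      flag <- ""
      if (nrow(base) < 10L) flag <- "unstable"
      if (length(unique(x)) < 2L || length(unique(base$fpkm)) < 2L) {
        rows[[length(rows) + 1L]] <- data.table(region = rg, stat = st,
                                                estimate = NA_real_,
                                                p_value = NA_real_,
                                                n = nrow(base), flag = "degenerate")
        next
      }
      ct <- suppressWarnings(cor.test(x, base$fpkm, method = method, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.table(region = rg, stat = st,
                                              estimate = unname(ct$estimate),
                                              p_value = ct$p.value,
                                              n = nrow(base), flag = flag)
    }
  }
  rbindlist(rows)
}

#' Knockout-response proportions for genes with and without 5gmC
#'
#' Per group: fraction and count of genes down- and up-regulated in the
#' knockout contrast, with Fisher's exact test between groups for each
#' direction.
#'
#' @param genes_with,genes_without Character vectors of gene IDs (disjoint).
#' @param de_table data.table(gene_id, status) with status in
#'   {up, down, ns}.
#' @return list: `table` (per-group counts and fractions), `test_down`,
#'   `test_up` (p-values), `flag`.
#' @export
de_proportions <- function(genes_with, genes_without, de_table) {
  if (length(intersect(genes_with, genes_without)) > 0L)
    stop("partition error: gene(s) present in both groups")
  de <- as.data.table(de_table)
  count_grp <- function(ids) {
    sub <- de[gene_id %in% ids]
    data.table(n = length(ids), n_down = sum(sub$status == "down"),
               n_up = sum(sub$status == "up"))
  }
  w <- count_grp(genes_with); wo <- count_grp(genes_without)
  tab <- data.table(group = c("with_5gmC", "without_5gmC"),
                    n = c(w$n, wo$n),
                    n_down = c(w$n_down, wo$n_down),
                    n_up = c(w$n_up, wo$n_up))
  tab[, `:=`(frac_down = fifelse(n > 0L, n_down / n, NA_real_),
             frac_up = fifelse(n > 0L, n_up / n, NA_real_))]
  flag <- if (any(tab$n == 0L)) "empty group: fractions undefined" else ""
  test <- function(col) {
    if (any(tab$n == 0L)) return(NA_real_)
    m <- matrix(c(tab[[col]][1], tab$n[1] - tab[[col]][1],
                  tab[[col]][2], tab$n[2] - tab[[col]][2]), 2, byrow = TRUE)
    fisher.test(m)$p.value
  }
  list(table = tab[], test_down = test("n_down"), test_up = test("n_up"),
       flag = flag)
}
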