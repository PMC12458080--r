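## Genomic-landscape placement of called sites: functional-region
## categories, TSS-distance profile, TE zones, histone-mark overlap and
## k-mer context enrichment.

#' Annotation distance constants
#'
#' @param promoter_bp Promoter window upstream of the TSS (default 2000 bp;
#'   the window is orientation-aware and includes the TSS base).
#' @param downstream_bp Downstream window past the TES (default 300 bp).
#' @param tss_window TSS-distance histogram half-window (default 3000 bp).
#' @param tss_binwidth Histogram bin width (default 200 bp).
#' @param te_flank TE flank width, closed at exactly this distance
#'   (default 1000 bp).
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_bp = 2000L, downstream_bp = 300L,
                              tss_window = 3000L, tss_binwidth = 200L,
                              te_flank = 1000L) {
  vals <- c(promoter_bp, downstream_bp, tss_window, tss_binwidth, te_flank)
  if (any(vals <= 0)) stop("all annotation windows must be > 0")
  structure(list(promoter_bp = as.integer(promoter_bp),
                 downstream_bp = as.integer(downstream_bp),
                 tss_window = as.integer(tss_window),
                 tss_binwidth = as.integer(tss_binwidth),
                 te_flank = as.integer(te_flank)),
            class = "annotation_config")
}

feature_levels <- c("promoter", "exon", "intron", "downstream", "distal_intergenic")

## per-category GRanges from gene models (0-based half-open -> IRanges)
feature_ranges <- function(genes, config) {
  g <- genes$genes
  mk <- function(chrom, start0, end0) {
    keep <- end0 > start0
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start0[keep] + 1L, end0[keep]))
  }
  pr_start <- ifelse(g$strand == "+", pmax(g$tss - config$promoter_bp, 0L), g$tss)
  pr_end <- ifelse(g$strand == "+", g$tss + 1L, g$tss + 1L + config$promoter_bp)
  dn_start <- ifelse(g$strand == "+", g$tes + 1L, pmax(g$tes - config$downstream_bp, 0L))
  dn_end <- ifelse(g$strand == "+", g$tes + 1L + config$downstream_bp, g$tes)
  g2c <- setNames(g$chrom, g$gene_id)
  list(promoter = mk(g$chrom, pr_start, pr_end),
       exon = mk(g2c[genes$exons$gene_id], genes$exons$start, genes$exons$end),
       intron = if (nrow(genes$introns) > 0L)
         mk(g2c[genes$introns$gene_id], genes$introns$start, genes$introns$end)
       else GenomicRanges::GRanges(),
       downstream = mk(g$chrom, dn_start, dn_end))
}

#' Assign each site to a single functional-region category
#'
#' Categories are promoter (orientation-aware window of `promoter_bp`
#' upstream, including the TSS base), exon, intron, downstream
#' (`downstream_bp` past the TES) and distal_intergenic, resolved by the
#' precedence promoter > exon > intron > downstream > distal_intergenic.
#'
#' @param sites Site table with chrom, pos (1-based), strand.
#' @param genes A [gene_models()].
#' @param config An [annotation_config()].
#' @return factor of categories, one per site.
#' @export
annotate_feature <- function(sites, genes, config = annotation_config()) {
  n <- nrow(sites)
  out <- rep("distal_intergenic", n)
  if (nrow(genes$genes) > 0L && n > 0L) {
    fr <- feature_ranges(genes, config)
    q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    for (cat in c("downstream", "intron", "exon", "promoter"))  # reverse precedence
      if (length(fr[[cat]]) > 0L)
        out[IRanges::overlapsAny(q, fr[[cat]])] <- cat
  }
  factor(out, levels = feature_levels)
}

#' TSS-distance profile
#'
#' Signed, orientation-aware distance of each site to its nearest TSS
#' (negative = upstream of the gene), binned over +/- `tss_window`.
#' The fraction of sites within the window is the headline scalar.
#'
#' @param sites Site table.
#' @param genes A [gene_models()]; error if empty.
#' @param config An [annotation_config()].
#' @return list: `table` (bin_start, bin_end, n, fraction of all sites),
#'   `within_window_fraction`, `n_sites`.
#' @export
tss_distance_profile <- function(sites, genes, config = annotation_config()) {
  if (nrow(genes$genes) == 0L) stop("undefined: no gene models supplied")
  n <- nrow(sites)
  brk <- seq(-config$tss_window, config$tss_window, by = config$tss_binwidth)
  if (n == 0L)
    return(list(table = data.table(bin_start = head(brk, -1), bin_end = brk[-1],
                                   n = 0L, fraction = NA_real_),
                within_window_fraction = NA_real_, n_sites = 0L))
  g <- genes$genes
  dist <- rep(NA_real_, n)
  for (cn in unique(sites$chrom)) {
    gs <- g[chrom == cn]
    si <- which(sites$chrom == cn)
    if (nrow(gs) == 0L || length(si) == 0L) next
    p0 <- sites$pos[si] - 1L
    dmat <- outer(p0, gs$tss, "-")            # reference-direction distance
    j <- apply(abs(dmat), 1L, which.min)
    d <- dmat[cbind(seq_along(si), j)]
    dist[si] <- ifelse(gs$strand[j] == "+", d, -d)
  }
  within <- !is.na(dist) & abs(dist) <= config$tss_window
  h <- hist(pmax(pmin(dist[within], config$tss_window - 0.5),
                 -config$tss_window), breaks = brk, right = FALSE, plot = FALSE)
  list(table = data.table(bin_start = head(brk, -1), bin_end = brk[-1],
                          n = h$counts, fraction = h$counts / n),
       within_window_fraction = mean(within),
       n_sites = n)
}

#' TE-zone classification
#'
#' Each site is inside a (merged) TE, in a flank (within `te_flank` bp of a
#' TE edge, closed at exactly `te_flank`, and not inside any TE), or
#' outside. Reports per-zone fractions and mean modification ratio.
#'
#' @param sites Site table; a `ratio` column is summarised if present.
#' @param tes An [interval_set()] of TEs.
#' @param config An [annotation_config()].
#' @return list: `zones` (factor per site), `summary` (per-zone n, fraction,
#'   mean_ratio).
#' @export
te_overlap <- function(sites, tes, config = annotation_config()) {
  n <- nrow(sites)
  zones <- rep("outside", n)
  if (nrow(tes$intervals) > 0L && n > 0L) {
    te <- GenomicRanges::reduce(
      GenomicRanges::GRanges(tes$intervals$chrom,
                             IRanges::IRanges(tes$intervals$start + 1L,
                                              tes$intervals$end)))
    q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
    fl <- GenomicRanges::setdiff(te + config$te_flank, te)
    zones[IRanges::overlapsAny(q, fl)] <- "flank"
    zones[IRanges::overlapsAny(q, te)] <- "inside"
  }
  zones <- factor(zones, levels = c("inside", "flank", "outside"))
  ratio <- if ("ratio" %in% names(sites)) sites$ratio else rep(NA_real_, n)
  summ <- data.table(zone = levels(zones),
                     n = as.integer(table(zones)),
                     fraction = if (n > 0) as.integer(table(zones)) / n else NA_real_,
                     mean_ratio = vapply(levels(zones), function(z) {
                       r <- ratio[zones == z]
                       if (length(r) == 0 || all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
                     }, numeric(1)))
  list(zones = zones, summary = summ)
}

#' Histone-mark overlap report
#'
#' Per mark: fraction and count of sites inside its intervals, and
#' mean/median modification ratio inside vs outside.
#'
#' @param sites Site table with a `ratio` column.
#' @param marks Named list of [interval_set()], one per mark.
#' @return data.table with one row per mark.
#' @export
mark_overlap <- function(sites, marks) {
  n <- nrow(sites)
  rows <- lapply(names(marks), function(mk) {
    inside <- if (n > 0L) in_intervals(sites$chrom, sites$pos, marks[[mk]])
      else logical(0)
    ri <- sites$ratio[inside]; ro <- sites$ratio[!inside]
    data.table(mark = mk, n_sites = n, n_inside = sum(inside),
               fraction_inside = if (n > 0L) sum(inside) / n else 0,
               mean_ratio_inside = if (length(ri) > 0L) mean(ri) else NA_real_,
               median_ratio_inside = if (length(ri) > 0L) median(ri) else NA_real_,
               mean_ratio_outside = if (length(ro) > 0L) mean(ro) else NA_real_,
               median_ratio_outside = if (length(ro) > 0L) median(ro) else NA_real_)
  })
  rbindlist(rows)
}

## k-mer windows centred on cytosines, read 5'->3' on the site strand
centered_kmers <- function(genome, chrom, pos, strand, k) {
  half <- (k - 1L) %/% 2L
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    s <- genome$seqs[[cn]]
    L <- nchar(s)
    p <- pos[sel]
    lo <- pmax(p - half, 1L); hi <- pmin(p + half, L)
    raw <- substr(rep(s, length(p)), lo, hi)
    raw <- paste0(strrep("N", pmax(half - (p - lo), 0L)), raw,
                  strrep("N", pmax(half - (hi - p), 0L)))
    minus <- strand[sel] == "-"
    if (any(minus)) raw[minus] <- revcomp(raw[minus])
    out[sel] <- raw
  }
  out
}

#' k-mer context frequencies with enrichment against genome background
#'
#' Counts k-mer windows centred on each site (on the site strand) and
#' compares them to the genome-wide background of C-centred k-mers with an
#' exact binomial test per k-mer (alternative: enriched), adjusted by
#' Benjamini-Hochberg.
#'
#' @param sites Site table.
#' @param genome A [genome_ref()].
#' @param k Odd window size (the window must centre on the C).
#' @param alpha FDR level for the `enriched` flag (default 0.05).
#' @return data.table: kmer, n_sites, site_freq, bg_count, bg_freq, p,
#'   padj, enriched. Windows containing N are dropped from both numerator
#'   and background.
#' @export
kmer_context_freq <- function(sites, genome, k = 5L, alpha = 0.05) {
  if (k %% 2L == 0L) stop("k must be odd: the window centres on the C")
  cyt <- genome_cytosines(genome)
  bg <- centered_kmers(genome, cyt$chrom, cyt$pos, cyt$strand, k)
  bg <- bg[!grepl("N", bg, fixed = TRUE)]
  bg_tab <- table(bg)
  sk <- centered_kmers(genome, sites$chrom, sites$pos, sites$strand, k)
  sk <- sk[!grepl("N", sk, fixed = TRUE)]
  n <- length(sk)
  s_tab <- table(sk)
  out <- data.table(kmer = names(s_tab), n_sites = as.integer(s_tab))
  out[, site_freq := n_sites / n]
  out[, bg_count := as.integer(bg_tab[kmer])]
  out[is.na(bg_count), bg_count := 0L]
  out[, bg_freq := bg_count / length(bg)]
  out[, p := vapply(seq_len(.N), function(i)
    binom.test(n_sites[i], n, max(bg_freq[i], 1e-12),
               alternative = "greater")$p.value, numeric(1))]
  out[, padj := p.adjust(p, "BH")]
  out[, enriched := padj < alpha]
  setorder(out, padj, -n_sites)
  out[]
}
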