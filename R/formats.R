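## External format boundaries. Internal interval coordinates are 0-based
## half-open; per-cytosine positions are kept 1-based on the reference (the
## CX-report convention). Conversions happen here and nowhere else.

cx_columns <- c("chrom", "pos", "strand", "n_unconverted", "n_converted",
                "context", "trinucleotide")

#' Read a per-cytosine conversion-count report
#'
#' Reads the tab-separated 7-column per-cytosine dialect emitted by Bismark's
#' methylation extractor (CX report): chromosome, 1-based position, strand,
#' count of unconverted cytosines (reads showing C), count of converted
#' cytosines (reads showing T), context, trinucleotide. The "methylated"
#' column is interpreted generically as "unconverted": its meaning depends on
#' the chemistry of the sample (5mC+5gmC for WGBS, 5gmC only for DEA-seq).
#'
#' @param path Path to a tab-separated file without header.
#' @return data.table with columns chrom, pos, strand, n_unconverted,
#'   n_converted, context, trinucleotide.
#' @export
read_cytosine_report <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      n_unconverted = integer(), n_converted = integer(),
                      context = character(), trinucleotide = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- which(nf < 7L)
  if (length(short) > 0L) {
    i <- short[1]
    stop(sprintf("format error at line %d: missing column %d (%s)",
                 i, nf[i] + 1L, cx_columns[nf[i] + 1L]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7L, byrow = TRUE)
  nu <- suppressWarnings(as.integer(m[, 4]))
  nc <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(nu) | is.na(nc))
  if (length(bad) > 0L)
    stop(sprintf("value error at line %d: counts must be non-negative integers", bad[1]))
  neg <- which(nu < 0L | nc < 0L)
  if (length(neg) > 0L)
    stop(sprintf("value error at line %d: negative count", neg[1]))
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("value error: non-integer position")
  data.table(chrom = m[, 1], pos = pos, strand = m[, 3],
             n_unconverted = nu, n_converted = nc,
             context = m[, 6], trinucleotide = m[, 7])
}

#' Write a per-cytosine conversion-count report
#'
#' @param records data.table as returned by [read_cytosine_report()].
#' @param path Output path.
#' @export
write_cytosine_report <- function(records, path) {
  fwrite(records[, cx_columns, with = FALSE], path, sep = "\t",
         col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gene model container
#'
#' @param genes data.table with columns gene_id, chrom, strand, start, end
#'   (0-based half-open transcript span).
#' @param exons data.table with columns gene_id, start, end (0-based
#'   half-open), non-overlapping within a gene.
#' @return An object of class `gene_models` with elements `genes`, `exons`
#'   and derived `introns`. `genes` gains tss/tes columns: 0-based position
#'   of the first/last transcribed base.
#' @export
gene_models <- function(genes, exons) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  setorder(exons, gene_id, start)
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  chk <- exons[genes, on = "gene_id"]
  if (any(chk$start < chk$i.start | chk$end > chk$i.end, na.rm = TRUE))
    stop("structural error: exon outside its parent transcript span")
  ov <- exons[, any(start[-1] < head(end, -1)), by = gene_id]
  if (any(ov$V1)) stop("overlapping exons within a gene")
  introns <- exons[, {
    if (.N > 1L) list(start = head(end, -1L), end = start[-1L]) else
      list(start = integer(0), end = integer(0))
  }, by = gene_id]
  genes[, `:=`(tss = ifelse(strand == "+", start, end - 1L),
               tes = ifelse(strand == "+", end - 1L, start))]
  structure(list(genes = genes[], exons = exons[], introns = introns[]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "gene(s),", nrow(x$exons), "exon(s),",
      nrow(x$introns), "intron(s)\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports gene/mRNA/exon features and keeps one transcript per gene: the
#' one with the largest summed exon length (ties broken by transcript ID).
#' GFF3 1-based closed coordinates are converted to internal 0-based
#' half-open.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.table(as.data.frame(gr))
  df[, type := as.character(type)]
  mrna <- df[type %in% c("mRNA", "transcript")]
  ex <- df[type == "exon"]
  if (nrow(mrna) == 0L || nrow(ex) == 0L) stop("GFF3 contains no mRNA/exon features")
  mrna[, parent_gene := vapply(Parent, function(p) as.character(p)[1], character(1))]
  ex[, parent_tx := vapply(Parent, function(p) as.character(p)[1], character(1))]
  exlen <- ex[, .(len = sum(width)), by = parent_tx]
  mrna <- merge(mrna, exlen, by.x = "ID", by.y = "parent_tx", all.x = TRUE)
  mrna[is.na(len), len := 0L]
  setorder(mrna, parent_gene, -len, ID)
  keep <- mrna[, .SD[1], by = parent_gene]
  ex <- ex[parent_tx %in% keep$ID]
  genes <- keep[, .(gene_id = parent_gene, transcript_id = ID,
                    chrom = as.character(seqnames), strand = as.character(strand),
                    start = start - 1L, end = end)]
  tx2gene <- setNames(keep$parent_gene, keep$ID)
  exons <- ex[, .(gene_id = tx2gene[parent_tx], start = start - 1L, end = end)]
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- if ("transcript_id" %in% names(g)) g$transcript_id[i] else paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tdeaseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], gid),
      sprintf("%s\tdeaseq\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i], tid, gid))
    ex <- models$exons[gene_id == gid]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines,
        sprintf("%s\tdeaseq\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                g$chrom[i], ex$start[j] + 1L, ex$end[j], g$strand[i], tid, j, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Named interval set (TEs, histone marks)
#'
#' @param intervals data.table with chrom, start, end (0-based half-open).
#' @param label Set label, e.g. "TE" or "H3K9me1".
#' @return Object of class `interval_set`.
#' @export
interval_set <- function(intervals, label = "intervals") {
  intervals <- as.data.table(intervals)[, .(chrom, start, end)]
  if (any(intervals$start >= intervals$end)) stop("interval with start >= end")
  structure(list(intervals = intervals, label = label), class = "interval_set")
}

#' Read an interval set from BED
#'
#' @param path BED file path (0-based half-open, as BED is defined).
#' @param label Label for the set.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, label = "intervals") {
  gr <- rtracklayer::import.bed(path)
  interval_set(data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr)), label)
}

#' Write an interval set to BED
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  dt <- x$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", dt$chrom, dt$start, dt$end, x$label), path)
  invisible(path)
}

#' Write a single-cytosine bedGraph track
#'
#' Emits 0-based half-open single-base intervals carrying the chosen value
#' field, rounded to 4 decimals. Input must be sorted by (chrom, pos).
#'
#' @param sites data.table with chrom, pos (1-based) and the value field.
#' @param value_field Column to write (e.g. "ratio" or "depth").
#' @param path Output path.
#' @export
write_bedgraph <- function(sites, value_field, path) {
  if (!value_field %in% names(sites)) stop("unknown value field: ", value_field)
  if (nrow(sites) > 0L) {
    o <- order(sites$chrom, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stop("ordering error: sites must be sorted by (chrom, pos)")
  }
  writeLines(sprintf("%s\t%d\t%d\t%.4f", sites$chrom, sites$pos - 1L,
                     sites$pos, as.numeric(sites[[value_field]])), path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path.
#' @return data.table with chrom, pos (1-based, single-base intervals), value.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), pos = integer(), value = numeric()))
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  data.table(chrom = dt$chrom, pos = dt$start + 1L, value = dt$value)
}

#' Write / read a site or summary table as TSV
#'
#' @param x data.frame.
#' @param path File path.
#' @export
write_tsv_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) fread(path, sep = "\t")
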