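#' Genome reference container
#'
#' A minimal in-memory genome: a named set of uppercase nucleotide strings.
#' All sequence is validated against the alphabet A/C/G/T/N and chromosome
#' names must be unique.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return An object of class `genome_ref` with elements `seqs` (named
#'   character) and `lengths` (named integer).
#' @export
genome_ref <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == ""))
    stop("chromosome names must be present and unique")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence alphabet outside {A,C,G,T,N} on chromosome(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_ref")
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$seqs), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [genome_ref()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_ref(setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_ref()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## reverse-complement of 3-character windows, vectorised
revcomp3 <- function(x) {
  chartr("ACGTN", "TGCAN",
         paste0(substr(x, 3L, 3L), substr(x, 2L, 2L), substr(x, 1L, 1L)))
}

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

## context from a strand-oriented trinucleotide starting at the C.
## CG needs only the next base; CHG/CHH need two. An N (or a chromosome end,
## padded as N) in a base that is required for the decision gives AMBIG.
context_from_trinucleotide <- function(tri) {
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  ctx <- rep("AMBIG", length(tri))
  ctx[b2 == "G"] <- "CG"
  h2 <- b2 %in% c("A", "C", "T")
  ctx[h2 & b3 == "G"] <- "CHG"
  ctx[h2 & b3 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

#' Classify cytosine context (CG / CHG / CHH)
#'
#' Context is read from the two bases 3' of the cytosine on its own strand:
#' CG if the next base is G; CHG if the next base is H (A/C/T) and the one
#' after is G; CHH if both are H. A window truncated by a chromosome end or
#' containing N in a decisive position is AMBIG.
#'
#' @param genome A [genome_ref()].
#' @param chrom,pos,strand Parallel vectors: chromosome name, 1-based
#'   position of the C on the reference, strand ("+" or "-"). On the minus
#'   strand the reference base must be G (a C on the minus strand).
#' @return A data.table with columns `context` and `trinucleotide` (the
#'   3-mer starting at the C, read 5'->3' on its strand).
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  tri <- character(n)
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    s <- genome$seqs[[cn]]
    if (is.null(s)) stop("unknown chromosome: ", cn)
    L <- nchar(s)
    p <- pos[sel]
    if (any(p < 1L | p > L)) stop("position outside chromosome ", cn)
    plus <- strand[sel] == "+"
    if (any(plus)) {
      pp <- p[plus]
      raw <- substr(rep(s, length(pp)), pp, pp + 2L)
      raw <- paste0(raw, strrep("N", 3L - nchar(raw)))
      if (any(substr(raw, 1L, 1L) != "C"))
        stop("base is not C on + strand at requested position(s) on ", cn)
      tri[sel[plus]] <- raw
    }
    if (any(!plus)) {
      pm <- p[!plus]
      lo <- pmax(pm - 2L, 1L)
      raw <- substr(rep(s, length(pm)), lo, pm)
      raw <- paste0(strrep("N", 3L - nchar(raw)), raw)
      out <- revcomp3(raw)
      if (any(substr(out, 1L, 1L) != "C"))
        stop("base is not C on - strand at requested position(s) on ", cn)
      tri[sel[!plus]] <- out
    }
  }
  data.table(context = context_from_trinucleotide(tri), trinucleotide = tri)
}

#' Enumerate every cytosine in a genome
#'
#' Lists the strand-specific cytosines of both strands (C on the plus strand,
#' G on the reference for the minus strand) with their context and
#' trinucleotide.
#'
#' @param genome A [genome_ref()].
#' @return data.table with columns chrom, pos (1-based reference), strand,
#'   context, trinucleotide; sorted by (chrom, pos, strand).
#' @export
genome_cytosines <- function(genome) {
  out <- vector("list", 2L * length(genome$seqs))
  i <- 0L
  for (cn in names(genome$seqs)) {
    s <- genome$seqs[[cn]]
    for (st in c("+", "-")) {
      base <- if (st == "+") "C" else "G"
      hits <- gregexpr(base, s, fixed = TRUE)[[1]]
      i <- i + 1L
      if (hits[1] == -1L) next
      out[[i]] <- data.table(chrom = cn, pos = as.integer(hits), strand = st)
    }
  }
  cyt <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(cyt) == 0L)
    return(data.table(chrom = character(), pos = integer(), strand = character(),
                      context = character(), trinucleotide = character()))
  ctx <- classify_context(genome, cyt$chrom, cyt$pos, cyt$strand)
  cyt[, `:=`(context = ctx$context, trinucleotide = ctx$trinucleotide)]
  setorder(cyt, chrom, pos, strand)
  cyt[]
}

## site key shared by calling / overlap code
site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")
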