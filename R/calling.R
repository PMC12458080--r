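## Confident-site calling: hard thresholds on unconverted count and ratio
## (both strict inequalities), knockout-control subtraction as positional
## exclusion, gradient threshold selection, mass-based ppm abundance, and
## WGBS-minus-5gmC deconvolution of 5mC.

#' Calling thresholds
#'
#' Both bounds are strict: a site is retained when the unconverted count is
#' > `min_unconverted` AND the unconverted ratio is > `min_ratio`. Defaults
#' are the selected cut-offs (count > 10, ratio > 17%).
#'
#' @param min_unconverted Exclusive lower bound on the unconverted count.
#' @param min_ratio Exclusive lower bound on unconverted/(depth).
#' @param min_depth Minimum depth for a record to be evaluated.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(min_unconverted = 10L, min_ratio = 0.17,
                            min_depth = 1L) {
  if (min_unconverted < 0 || min_unconverted != round(min_unconverted))
    stop("min_unconverted must be a non-negative integer")
  if (min_ratio < 0 || min_ratio > 1) stop("min_ratio must be in [0,1]")
  structure(list(min_unconverted = as.integer(min_unconverted),
                 min_ratio = min_ratio, min_depth = as.integer(min_depth)),
            class = "call_thresholds")
}

#' Call confident 5gmC sites
#'
#' Applies the strict double threshold to per-cytosine records from a DEA
#' (or TET-BS) sample. Zero-depth (or below `min_depth`) records are skipped
#' and counted, not errors.
#'
#' @param records Cytosine records.
#' @param thresholds A [call_thresholds()].
#' @param sample_id Optional sample label attached to the output.
#' @return data.table of called sites: chrom, pos, strand, context,
#'   n_unconverted, depth, ratio, sample_id, removed_by_ko (FALSE).
#'   Attribute `n_skipped` counts records below `min_depth`.
#' @export
call_gmc_sites <- function(records, thresholds = call_thresholds(),
                           sample_id = NA_character_) {
  rec <- as.data.table(records)
  rec[, depth := n_unconverted + n_converted]
  n_skip <- sum(rec$depth < max(thresholds$min_depth, 1L))
  ok <- rec[depth >= max(thresholds$min_depth, 1L)]
  ok[, ratio := n_unconverted / depth]
  called <- ok[n_unconverted > thresholds$min_unconverted &
                 ratio > thresholds$min_ratio]
  out <- called[, .(chrom, pos, strand,
                    context = if ("context" %in% names(called)) context else NA_character_,
                    n_unconverted, depth, ratio,
                    sample_id = sample_id, removed_by_ko = FALSE)]
  setorder(out, chrom, pos, strand)
  setattr(out, "n_skipped", n_skip)
  out[]
}

#' Subtract knockout-control background
#'
#' Calls the KO sample with the same thresholds and flags every candidate
#' whose (chrom, pos, strand) is also called in the KO as `removed_by_ko`.
#' Flagged sites stay in the audit table; use [retained_sites()] to filter.
#'
#' @param candidates Called sites from [call_gmc_sites()].
#' @param ko_records Cytosine records of the knockout sample (same
#'   chemistry), or NULL for pass-through with a warning.
#' @param thresholds A [call_thresholds()] applied to the KO sample.
#' @return The candidate table with `removed_by_ko` updated.
#' @export
subtract_ko <- function(candidates, ko_records,
                        thresholds = call_thresholds()) {
  out <- copy(as.data.table(candidates))
  if (is.null(ko_records)) {
    warning("no knockout-control records supplied; background subtraction skipped")
    return(out[])
  }
  ko <- call_gmc_sites(ko_records, thresholds, sample_id = "KO")
  kk <- site_key(ko$chrom, ko$pos, ko$strand)
  out[, removed_by_ko := site_key(chrom, pos, strand) %in% kk]
  out[]
}

#' Retained (non-flagged) sites
#'
#' @param sites Site table with a `removed_by_ko` flag.
#' @return Subset with `removed_by_ko == FALSE`.
#' @export
retained_sites <- function(sites) {
  as.data.table(sites)[removed_by_ko == FALSE]
}

#' Abundance of called modification in parts per million
#'
#' Mass-based: 1e6 x (sum of unconverted counts over called sites) /
#' (sum of depth over all cytosine records), paralleling a mole-fraction
#' per total cytosines.
#'
#' @param called_sites Called site table.
#' @param all_records All cytosine records of the sample.
#' @return ppm (numeric scalar).
#' @export
abundance_ppm <- function(called_sites, all_records) {
  total <- sum(as.numeric(all_records$n_unconverted) +
                 as.numeric(all_records$n_converted))
  if (total == 0) stop("undefined abundance: total cytosine depth is zero")
  1e6 * sum(as.numeric(called_sites$n_unconverted)) / total
}

#' Gradient threshold selection
#'
#' Evaluates a grid of (count, ratio) thresholds on two samples of the same
#' specimen profiled by different methods. Each grid point records the
#' called-site count per method, the abundance (ppm, from sample A), the
#' cross-method overlap (exact position identity) and Jaccard. The selected
#' point maximizes Jaccard among points whose ppm lies within
#' `ppm_window` x `expected_ppm`; if no point is in the window, the best
#' overall Jaccard is returned with a warning.
#'
#' @param records_a,records_b Cytosine records of the two methods.
#' @param count_grid Integer vector of candidate count bounds.
#' @param ratio_grid Numeric vector of candidate ratio bounds.
#' @param expected_ppm Expected abundance (ppm).
#' @param ppm_window Multiplicative window, default c(0.5, 2).
#' @param ko_records_a,ko_records_b Optional KO records for background
#'   subtraction at every grid point.
#' @return list of class `gradient_grid`: `grid` (one row per point) and
#'   `selected` (the chosen row).
#' @export
gradient_select <- function(records_a, records_b, count_grid = c(5L, 10L, 15L, 20L),
                            ratio_grid = c(0.1, 0.17, 0.25),
                            expected_ppm = 10, ppm_window = c(0.5, 2),
                            ko_records_a = NULL, ko_records_b = NULL) {
  grid <- CJ(min_count = as.integer(count_grid), min_ratio = ratio_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    th <- call_thresholds(grid$min_count[i], grid$min_ratio[i])
    a <- call_gmc_sites(records_a, th, "A")
    b <- call_gmc_sites(records_b, th, "B")
    if (!is.null(ko_records_a)) a <- retained_sites(subtract_ko(a, ko_records_a, th))
    if (!is.null(ko_records_b)) b <- retained_sites(subtract_ko(b, ko_records_b, th))
    ka <- site_key(a$chrom, a$pos, a$strand)
    kb <- site_key(b$chrom, b$pos, b$strand)
    n_ov <- length(intersect(ka, kb))
    un <- length(union(ka, kb))
    data.table(min_count = grid$min_count[i], min_ratio = grid$min_ratio[i],
               n_a = length(ka), n_b = length(kb), n_overlap = n_ov,
               jaccard = if (un > 0) n_ov / un else 0,
               ppm = abundance_ppm(a, records_a))
  })
  res <- rbindlist(rows)
  res[, in_window := ppm >= ppm_window[1] * expected_ppm &
        ppm <= ppm_window[2] * expected_ppm]
  cand <- res[in_window == TRUE]
  if (nrow(cand) == 0L) {
    warning("no grid point within the ppm window; returning best overall overlap")
    cand <- res
  }
  sel <- cand[order(-jaccard, min_count, min_ratio)][1]
  structure(list(grid = res[], selected = sel), class = "gradient_grid")
}

#' @export
print.gradient_grid <- function(x, ...) {
  cat("gradient_grid:", nrow(x$grid), "points; selected (count >",
      x$selected$min_count, ", ratio >", x$selected$min_ratio, ") jaccard",
      round(x$selected$jaccard, 3), "ppm", round(x$selected$ppm, 2), "\n")
  invisible(x)
}

#' Deconvolve 5mC from WGBS signal
#'
#' WGBS reads both 5mC and 5gmC as C, so the 5mC ratio at a position is the
#' WGBS unconverted ratio minus the confident 5gmC ratio at that position
#' (0 where no confident 5gmC), clamped to [0, 1]. Negative mass before
#' clamping is tallied as a residual-noise QC figure (attribute
#' `negative_mass`). Confident 5gmC sites without WGBS coverage are emitted
#' with `wgbs_ratio` missing.
#'
#' @param wgbs_records WGBS cytosine records.
#' @param gmc_sites Confident 5gmC site table (ratio column used).
#' @param min_depth Minimum WGBS depth for a position to be evaluated.
#' @return data.table: chrom, pos, strand, context, depth, wgbs_ratio,
#'   gmc_ratio, mc_ratio, wgbs_missing; sorted by (chrom, pos, strand).
#' @export
deconvolve_mc <- function(wgbs_records, gmc_sites, min_depth = 1L) {
  w <- as.data.table(wgbs_records)
  w[, depth := n_unconverted + n_converted]
  w <- w[depth >= min_depth]
  w[, wgbs_ratio := n_unconverted / depth]
  g <- as.data.table(gmc_sites)[, .(chrom, pos, strand, gmc_ratio = ratio)]
  out <- merge(w[, .(chrom, pos, strand,
                     context = if ("context" %in% names(w)) context else NA_character_,
                     depth, wgbs_ratio)],
               g, by = c("chrom", "pos", "strand"), all = TRUE)
  out[is.na(gmc_ratio), gmc_ratio := 0]
  out[, wgbs_missing := is.na(wgbs_ratio)]
  neg_mass <- out[!is.na(wgbs_ratio), sum(pmax(gmc_ratio - wgbs_ratio, 0))]
  out[, mc_ratio := pmin(pmax(wgbs_ratio - gmc_ratio, 0), 1)]
  setorder(out, chrom, pos, strand)
  setattr(out, "negative_mass", neg_mass)
  out[]
}

#' Call confident 5mC sites from deconvolved ratios
#'
#' Applies the same double threshold to the deconvolved 5mC signal, using
#' round(mc_ratio x depth) as the effective unconverted count.
#'
#' @param deconvolved Output of [deconvolve_mc()].
#' @param thresholds A [call_thresholds()].
#' @return Site table (chrom, pos, strand, context, n_unconverted, depth,
#'   ratio, sample_id, removed_by_ko).
#' @export
call_mc_sites <- function(deconvolved, thresholds = call_thresholds()) {
  d <- as.data.table(deconvolved)[wgbs_missing == FALSE]
  d[, n_eff := as.integer(round(mc_ratio * depth))]
  called <- d[n_eff > thresholds$min_unconverted & mc_ratio > thresholds$min_ratio]
  out <- called[, .(chrom, pos, strand, context, n_unconverted = n_eff, depth,
                    ratio = mc_ratio, sample_id = "mC", removed_by_ko = FALSE)]
  setorder(out, chrom, pos, strand)
  out[]
}
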