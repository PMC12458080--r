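## Conversion-chemistry model.
##
## A chemistry profile gives, per true base state (C, 5mC, 5gmC) and cytosine
## context (CG, CHG, CHH), the probability that the base is read as T after
## treatment and PCR. The three chemistries:
##   DEA    - deaminase converts C and 5mC with a small uniform residual
##            (non-conversion ~0.2%); 5gmC blocks deamination.
##   WGBS   - bisulfite converts C; both 5mC and 5gmC are protected.
##   TET-BS - TET oxidation then bisulfite; C converts, 5mC mostly converts
##            but with a context-dependent escape (~3% mean) that varies from
##            site to site; 5gmC resists both steps.

chem_states <- c("C", "5mC", "5gmC")
chem_contexts <- c("CG", "CHG", "CHH")

#' Conversion chemistry profile
#'
#' @param name One of "DEA", "WGBS", "TET-BS".
#' @param nonconversion Residual non-conversion of unmodified C (probability
#'   of reading C where T is expected). Default 0.002 for DEA and WGBS,
#'   0.004 for TET-BS.
#' @param mc_escape For TET-BS: named per-context probability that a 5mC
#'   escapes oxidation+conversion and reads as C. Default
#'   c(CG=0.045, CHG=0.03, CHH=0.015) (mean 0.03). For DEA the 5mC residual
#'   equals `nonconversion` (deaminase treats C and 5mC alike); for WGBS 5mC
#'   is fully protected (escape 1 by definition of bisulfite).
#' @param gmc_loss Probability that a true 5gmC is nevertheless converted
#'   (over-conversion). Default 0: full protection.
#' @param site_phi Beta precision of the per-site 5mC escape rate for
#'   TET-BS (site-to-site variability of oxidation efficiency); `Inf` means
#'   a constant escape. Default 5 for TET-BS, Inf otherwise.
#' @return Object of class `chemistry_profile` with a 3x3 matrix `p_T` of
#'   P(read T | state, context).
#' @export
chemistry_profile <- function(name = c("DEA", "WGBS", "TET-BS"),
                              nonconversion = NULL, mc_escape = NULL,
                              gmc_loss = 0, site_phi = NULL) {
  name <- match.arg(name)
  if (is.null(nonconversion))
    nonconversion <- if (name == "TET-BS") 0.004 else 0.002
  p_T <- matrix(0, 3, 3, dimnames = list(chem_states, chem_contexts))
  p_T["C", ] <- 1 - nonconversion
  if (name == "DEA") {
    p_T["5mC", ] <- 1 - nonconversion
    if (is.null(site_phi)) site_phi <- Inf
  } else if (name == "WGBS") {
    p_T["5mC", ] <- 0
    if (is.null(site_phi)) site_phi <- Inf
  } else {
    if (is.null(mc_escape)) mc_escape <- c(CG = 0.045, CHG = 0.03, CHH = 0.015)
    p_T["5mC", ] <- 1 - mc_escape[chem_contexts]
    if (is.null(site_phi)) site_phi <- 5
  }
  p_T["5gmC", ] <- gmc_loss
  if (any(p_T < 0 | p_T > 1)) stop("profile error: probability outside [0,1]")
  structure(list(name = name, p_T = p_T, site_phi = site_phi),
            class = "chemistry_profile")
}

#' @export
print.chemistry_profile <- function(x, ...) {
  cat("chemistry_profile:", x$name, "\nP(read T | state, context):\n")
  print(round(x$p_T, 4))
  if (is.finite(x$site_phi))
    cat("per-site 5mC escape: Beta, precision phi =", x$site_phi, "\n")
  invisible(x)
}

## P(read T) per record for a given state label, honouring AMBIG contexts by
## averaging over contexts.
profile_p_T <- function(profile, state, context) {
  m <- profile$p_T
  out <- numeric(length(context))
  known <- context %in% chem_contexts
  out[known] <- m[state, context[known]]
  out[!known] <- mean(m[state, ])
  out
}

#' Estimate conversion rates from spike-in records
#'
#' Pools converted/unconverted counts per spike-in class (unmodified vs
#' fully-5mC) and per context, and reports conversion rate
#' converted/(converted+unconverted) with Clopper-Pearson exact confidence
#' intervals (alpha = 0.05). Spike-in records are matched to classes by
#' chromosome name. Strata with zero total depth are flagged "no data"
#' rather than reported as 0.
#'
#' @param records Cytosine records aligned to spike-in sequences.
#' @param spikein_classes Named character vector mapping spike-in chromosome
#'   name to class ("unmodified" or "fully-5mC").
#' @return data.table with columns class, context ("all" = pooled),
#'   n_converted, n_unconverted, rate, nonconversion, ci_low, ci_high, note.
#' @export
estimate_conversion <- function(records, spikein_classes) {
  rec <- as.data.table(records)
  unknown <- setdiff(unique(rec$chrom), names(spikein_classes))
  if (length(unknown) > 0L)
    stop("records on chromosomes without a spike-in class: ",
         paste(unknown, collapse = ", "))
  rec[, class := spikein_classes[chrom]]
  strata <- CJ(class = unique(unname(spikein_classes)),
               context = c("all", chem_contexts))
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    cl <- strata$class[i]; ctx <- strata$context[i]
    sub <- if (ctx == "all") rec[class == cl] else rec[class == cl & context == ctx]
    nc <- sum(sub$n_converted); nu <- sum(sub$n_unconverted)
    if (nc + nu == 0L)
      return(data.table(class = cl, context = ctx, n_converted = 0L,
                        n_unconverted = 0L, rate = NA_real_,
                        nonconversion = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, note = "no data"))
    bt <- binom.test(nc, nc + nu)
    data.table(class = cl, context = ctx, n_converted = nc, n_unconverted = nu,
               rate = nc / (nc + nu), nonconversion = nu / (nc + nu),
               ci_low = bt$conf.int[1], ci_high = bt$conf.int[2], note = "")
  })
  rbindlist(rows)
}

#' Compare conversion reports of two chemistries
#'
#' Per (class, context) stratum, tests the two conversion rates against each
#' other with Fisher's exact test on the 2x2 conversion table and flags
#' strata where one chemistry converts significantly less.
#'
#' @param report_a,report_b Reports from [estimate_conversion()].
#' @param labels Character(2) naming the chemistries.
#' @param alpha Significance level for flagging (default 0.05).
#' @return data.table with per-stratum rates, difference, p-value and a flag
#'   in {"a_higher", "b_higher", "none", "incomparable"}.
#' @export
compare_profiles <- function(report_a, report_b, labels = c("A", "B"),
                             alpha = 0.05) {
  a <- as.data.table(report_a); b <- as.data.table(report_b)
  m <- merge(a, b, by = c("class", "context"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) stop("alignment error: no shared (class, context) strata")
  m[, `:=`(diff = rate_a - rate_b, p_value = NA_real_, flag = "none")]
  for (i in seq_len(nrow(m))) {
    if (m$note_a[i] == "no data" || m$note_b[i] == "no data") {
      set(m, i, "flag", "incomparable")
      next
    }
    tab <- matrix(c(m$n_converted_a[i], m$n_unconverted_a[i],
                    m$n_converted_b[i], m$n_unconverted_b[i]), nrow = 2,
                  byrow = TRUE)
    p <- fisher.test(tab)$p.value
    set(m, i, "p_value", p)
    if (p < alpha)
      set(m, i, "flag", if (m$rate_a[i] > m$rate_b[i]) "a_higher" else "b_higher")
  }
  out <- m[, .(class, context, rate_a, rate_b, diff, p_value, flag)]
  setnames(out, c("rate_a", "rate_b"),
           paste0("rate_", make.names(labels)))
  attr(out, "labels") <- labels
  out[]
}
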