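#' Classify a region from its three contrast significance flags
#'
#' Category logic per tier:
#' * `PAE_specific`: significant in PAEvCON and PAEvPF but not PFvCON —
#'   altered by alcohol exposure itself, not by the feeding paradigm;
#' * `PF_specific`: significant in PFvCON and PAEvPF but not PAEvCON;
#' * `shared`: significant in both PAEvCON and PFvCON — both prenatal
#'   treatments differ from control in this region;
#' * `none` otherwise.
#'
#' The three rules are mutually exclusive: `shared` requires both
#' group-vs-control flags, which each specific rule forbids.
#'
#' @param sig_paevcon,sig_paevpf,sig_pfvcon logical vectors of equal length.
#' @return character vector of categories.
#' @export
classify_region <- function(sig_paevcon, sig_paevpf, sig_pfvcon) {
  stopifnot(
    is.logical(sig_paevcon), is.logical(sig_paevpf), is.logical(sig_pfvcon)
  )
  out <- rep("none", length(sig_paevcon))
  out[sig_paevcon & sig_paevpf & !sig_pfvcon] <- "PAE_specific"
  out[sig_pfvcon & sig_paevpf & !sig_paevcon] <- "PF_specific"
  out[sig_paevcon & sig_pfvcon] <- "shared"
  out
}

#' Call DMRs for one tier from its contrast table
#'
#' Applies the FDR threshold per contrast, classifies every region, and
#' attaches direction and the 1.5-fold robustness flag from the category's
#' defining contrasts.
#'
#' @param ct a `contrast_table` for one tier (three contrasts per region).
#' @param regions optional `consensus_regions` table; provides `size_bp`.
#' @param alpha FDR threshold (default 0.05).
#' @return a `dmr_calls` data frame (regions with category != "none"):
#'   `region_id`, `tier`, `category`, `direction`, `robust_1p5fold`,
#'   `size_bp`.
#' @export
call_dmrs <- function(ct, regions = NULL, alpha = 0.05) {
  wide <- reshape_contrasts(ct)
  cat <- classify_region(
    wide$q_PAEvCON < alpha, wide$q_PAEvPF < alpha, wide$q_PFvCON < alpha
  )
  keep <- cat != "none"
  calls <- data.frame(
    region_id = wide$region_id[keep],
    tier = wide$tier[keep],
    category = cat[keep],
    stringsAsFactors = FALSE
  )
  dr <- direction_and_robustness(calls, ct)
  calls$direction <- dr$direction
  calls$robust_1p5fold <- dr$robust_1p5fold
  calls$size_bp <- if (!is.null(regions)) {
    sz <- stats::setNames(regions$end - regions$start, regions$region_id)
    as.integer(sz[calls$region_id])
  } else NA_integer_
  rownames(calls) <- NULL
  class(calls) <- c("dmr_calls", "data.frame")
  calls
}

reshape_contrasts <- function(ct) {
  need <- c("PAEvCON", "PAEvPF", "PFvCON")
  sp <- split(ct, ct$contrast)
  if (!all(need %in% names(sp))) abort("contrast table must contain ", paste(need, collapse = ", "))
  base <- sp[[need[1]]][, c("region_id", "tier")]
  for (cn in need) {
    s <- sp[[cn]]
    if (!identical(s$region_id, base$region_id)) {
      s <- s[match(base$region_id, s$region_id), ]
    }
    base[[paste0("logFC_", cn)]] <- s$logFC
    base[[paste0("q_", cn)]] <- s$q
  }
  base
}

#' Direction and 1.5-fold robustness of called DMRs
#'
#' Each category has two defining contrasts: `PAE_specific` uses PAEvCON and
#' PAEvPF; `PF_specific` uses PFvCON and the sign-flipped PAEvPF (so the
#' direction reads as PF versus the other two groups); `shared` uses PAEvCON
#' and PFvCON. Direction is `up`/`down` when both defining log fold changes
#' agree in sign, `inconsistent` otherwise. The robustness flag requires
#' `|logFC| >= log2(1.5)` in both defining contrasts.
#'
#' @param calls data frame with `region_id` and `category`.
#' @param ct the tier's `contrast_table` (provides the logFC values).
#' @return data frame with `direction` and `robust_1p5fold` aligned to
#'   `calls`.
#' @export
direction_and_robustness <- function(calls, ct) {
  wide <- reshape_contrasts(ct)
  i <- match(calls$region_id, wide$region_id)
  lfc1 <- lfc2 <- rep(NA_real_, nrow(calls))
  pae <- calls$category == "PAE_specific"
  pfs <- calls$category == "PF_specific"
  sh <- calls$category == "shared"
  lfc1[pae] <- wide$logFC_PAEvCON[i][pae]
  lfc2[pae] <- wide$logFC_PAEvPF[i][pae]
  lfc1[pfs] <- wide$logFC_PFvCON[i][pfs]
  lfc2[pfs] <- -wide$logFC_PAEvPF[i][pfs]
  lfc1[sh] <- wide$logFC_PAEvCON[i][sh]
  lfc2[sh] <- wide$logFC_PFvCON[i][sh]
  direction <- ifelse(lfc1 > 0 & lfc2 > 0, "up",
    ifelse(lfc1 < 0 & lfc2 < 0, "down", "inconsistent")
  )
  thr <- log2(1.5)
  data.frame(
    direction = direction,
    robust_1p5fold = abs(lfc1) >= thr & abs(lfc2) >= thr
  )
}

#' Reassign DMRs overlapping between sex-concordant and sex-specific tiers
#'
#' A region called with the same category in the concordant tier and in a
#' sex-specific tier is taken to be driven primarily by that sex, and is
#' removed from the concordant tier; sex tiers are never changed. "Overlap"
#' means identical `region_id` (all tiers are fit on the same consensus
#' regions). A region present in both the female and male tier is kept in
#' both, with a warning.
#'
#' @param concordant,female,male `dmr_calls` tables for the three tiers.
#' @return list with elements `concordant`, `female`, `male` and an
#'   `overlaps` attribute counting removed calls per category and sex.
#' @export
reassign_sex_tiers <- function(concordant, female, male) {
  key <- function(df) paste(df$region_id, df$category)
  in_f <- key(concordant) %in% key(female)
  in_m <- key(concordant) %in% key(male)
  both <- intersect(key(female), key(male))
  if (length(both)) {
    warning(length(both), " DMR(s) present in both sex tiers; kept in both")
  }
  overlaps <- if (nrow(concordant)) {
    stats::aggregate(cbind(female = in_f, male = in_m),
                     by = list(category = concordant$category), FUN = sum)
  } else {
    data.frame(category = character(), female = integer(), male = integer())
  }
  out <- list(
    concordant = concordant[!(in_f | in_m), , drop = FALSE],
    female = female,
    male = male
  )
  rownames(out$concordant) <- NULL
  attr(out, "overlaps") <- overlaps
  out
}

#' Monte-Carlo chi-squared test of direction bias
#'
#' Tests whether the up/down split of DMR directions departs from the
#' expected 50/50 proportion. The observed statistic is the usual
#' goodness-of-fit chi-square with expectation `n/2` per side; the null
#' distribution is simulated by drawing `B` binomial(n, 1/2) splits, and
#' `p_sim = (1 + #\{replicate chi2 >= observed\}) / (B + 1)` (add-one rule, so
#' the smallest attainable p is `1/(B+1)`).
#'
#' @param n_up,n_down non-negative counts, `n_up + n_down >= 1`.
#' @param B number of Monte-Carlo replicates (default 2000).
#' @param seed optional integer seed.
#' @return list: `n_up`, `n_down`, `chi2`, `p_sim`, `B`.
#' @export
direction_chisq_mc <- function(n_up, n_down, B = 2000, seed = NULL) {
  n <- n_up + n_down
  if (n < 1 || B < 1) abort("need n_up + n_down >= 1 and B >= 1")
  if (!is.null(seed)) set.seed(seed)
  e <- n / 2
  chi2 <- (n_up - e)^2 / e + (n_down - e)^2 / e
  ups <- stats::rbinom(B, n, 0.5)
  rep_chi2 <- (ups - e)^2 / e + ((n - ups) - e)^2 / e
  p_sim <- (1 + sum(rep_chi2 >= chi2 - 1e-12)) / (B + 1)
  list(n_up = n_up, n_down = n_down, chi2 = chi2, p_sim = p_sim, B = B)
}

#' Summarize DMR calls
#'
#' @param calls a `dmr_calls` table (or several rbind-ed tiers).
#' @return list with `size_range` (min, max bp), `size_median` (midpoint
#'   rule for even counts) and `counts`, a tier x category x direction table.
#' @export
summarize_dmrs <- function(calls) {
  sizes <- calls$size_bp[!is.na(calls$size_bp)]
  list(
    size_range = if (length(sizes)) range(sizes) else c(NA, NA),
    size_median = if (length(sizes)) stats::median(sizes) else NA,
    counts = table(tier = calls$tier, category = calls$category,
                   direction = calls$direction)
  )
}
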