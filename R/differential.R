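#' Fit per-region linear models for one analysis tier
#'
#' Three tiers are supported, mirroring the study design:
#' `"concordant"` fits `~ group + sex` on all samples; `"female"` and
#' `"male"` fit `~ group` on the samples of that sex only. Group uses
#' treatment coding with `CON` as the reference level, so the fitted
#' coefficients are directly the `PAE - CON` and `PF - CON` log2 differences.
#'
#' @param x regions x samples matrix of normalized log2 values.
#' @param design data frame with `sample_id`, `group` (levels
#'   `CON`, `PF`, `PAE`), `sex` (`F`/`M`); rows in column order of `x`.
#' @param tier `"concordant"`, `"female"` or `"male"`.
#' @return a `region_fit` list: `coefficients` (regions x p), `sigma2`
#'   (residual variances), `df_residual`, `xtx_inv`, `tier`, `design_matrix`.
#' @export
fit_models <- function(x, design, tier = c("concordant", "female", "male")) {
  tier <- match.arg(tier)
  x <- as.matrix(x)
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("region_%05d", seq_len(nrow(x)))
  }
  if (ncol(x) != nrow(design)) abort("design rows must match matrix columns")
  keep <- switch(tier,
    concordant = rep(TRUE, nrow(design)),
    female = design$sex == "F",
    male = design$sex == "M"
  )
  if (!any(keep)) abort("no samples in tier '", tier, "'")
  d <- design[keep, , drop = FALSE]
  xs <- x[, keep, drop = FALSE]
  d$group <- factor(as.character(d$group), levels = c("CON", "PF", "PAE"))
  if (anyNA(d$group)) abort("group must be one of CON, PF, PAE")
  mm <- if (tier == "concordant") {
    d$sex <- factor(as.character(d$sex), levels = c("F", "M"))
    stats::model.matrix(~ group + sex, data = d)
  } else {
    stats::model.matrix(~ group, data = d)
  }
  if (qr(mm)$rank < ncol(mm)) {
    abort("rank-deficient design in tier '", tier, "': collinear terms among ",
          paste(colnames(mm), collapse = ", "))
  }
  fit <- stats::lm.fit(mm, t(xs))
  coefs <- t(fit$coefficients) # regions x p
  dfres <- nrow(mm) - ncol(mm)
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / dfres
  out <- list(
    coefficients = coefs,
    sigma2 = stats::setNames(as.numeric(sigma2), rownames(x)),
    df_residual = dfres,
    xtx_inv = solve(crossprod(mm)),
    tier = tier,
    design_matrix = mm,
    samples = d$sample_id
  )
  class(out) <- "region_fit"
  out
}

#' Estimate empirical-Bayes moderation parameters
#'
#' Models the per-region residual variances as draws from a scaled-F
#' (inverse-chi-square prior) distribution and estimates the prior degrees of
#' freedom `d0` and prior variance `s0sq` by matching the first two moments
#' of the log variances (trigamma-inverse method). When the observed spread
#' of log variances does not exceed the chi-square sampling spread, `d0` is
#' infinite and `s0sq` is the mean variance.
#'
#' @param sigma2 per-region residual variances.
#' @param df residual degrees of freedom (scalar or per-region).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0sq` (prior
#'   variance).
#' @export
estimate_moderation <- function(sigma2, df) {
  df <- rep_len(df, length(sigma2))
  ok <- df > 0 & sigma2 > 0
  if (sum(ok) < 2) {
    if (all(sigma2 == 0)) abort("all residual variances are zero")
    abort("need >= 2 regions with positive residual df and variance")
  }
  s2 <- sigma2[ok]
  d <- df[ok]
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(d / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0sq = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

# solve trigamma(x) = y by Newton iteration (monotone, convex)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated contrast tests
#'
#' Computes, for each region and contrast, the log2 effect, the moderated
#' t-statistic `estimate / (s_tilde * sqrt(v_c))` with posterior variance
#' `s_tilde^2 = (d0 * s0sq + df * s2) / (d0 + df)`, and a two-sided p-value
#' from the t distribution on `d0 + df` degrees of freedom. Setting `d0 = 0`
#' recovers the classical per-region t-test. Benjamini-Hochberg q-values are
#' computed within each contrast.
#'
#' @param fit a `region_fit` from [fit_models()].
#' @param moderation list with `d0`, `s0sq` from [estimate_moderation()], or
#'   `NULL` to estimate it from `fit`.
#' @param contrasts character subset of `c("PAEvCON", "PAEvPF", "PFvCON")`.
#'   Under CON-reference coding these are `b_PAE`, `b_PAE - b_PF`, `b_PF`.
#' @return a `contrast_table` data frame: `region_id`, `tier`, `contrast`,
#'   `logFC`, `t`, `p`, `q` (3 rows per region by default).
#' @export
contrast_tests <- function(fit, moderation = NULL,
                           contrasts = c("PAEvCON", "PAEvPF", "PFvCON")) {
  if (is.null(moderation)) {
    moderation <- estimate_moderation(fit$sigma2, fit$df_residual)
  }
  d0 <- moderation$d0
  s0 <- moderation$s0sq
  d <- fit$df_residual
  s2_tilde <- if (is.infinite(d0)) {
    rep(s0, length(fit$sigma2))
  } else {
    (d0 * s0 + d * fit$sigma2) / (d0 + d)
  }
  df_total <- d0 + d
  cmat <- contrast_vectors(colnames(fit$coefficients))
  out <- lapply(contrasts, function(cn) {
    if (!cn %in% colnames(cmat)) abort("unknown contrast: ", cn)
    cv <- cmat[, cn]
    est <- as.numeric(fit$coefficients %*% cv)
    vc <- as.numeric(t(cv) %*% fit$xtx_inv %*% cv)
    tstat <- est / sqrt(s2_tilde * vc)
    tstat[is.na(tstat)] <- 0
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    data.frame(
      region_id = rownames(fit$coefficients), tier = fit$tier, contrast = cn,
      logFC = est, t = tstat, p = p, q = bh_fdr(p),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_table", "data.frame")
  attr(res, "moderation") <- moderation
  res
}

contrast_vectors <- function(coef_names) {
  p <- length(coef_names)
  base <- stats::setNames(numeric(p), coef_names)
  mk <- function(plus, minus = NULL) {
    v <- base
    v[plus] <- 1
    if (!is.null(minus)) v[minus] <- -1
    v
  }
  cbind(
    PAEvCON = mk("groupPAE"),
    PAEvPF = mk("groupPAE", "groupPF"),
    PFvCON = mk("groupPF")
  )
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values (monotone, order-preserving, capped at 1).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full differential analysis for one tier
#'
#' Convenience wrapper: fit, moderate, test the three contrasts.
#'
#' @inheritParams fit_models
#' @param moderate estimate and apply empirical-Bayes moderation
#'   (default `TRUE`); `FALSE` uses classical per-region t-tests (`d0 = 0`).
#' @return a `contrast_table`.
#' @export
run_differential <- function(x, design, tier, moderate = TRUE) {
  fit <- fit_models(x, design, tier)
  mod <- if (moderate) {
    estimate_moderation(fit$sigma2, fit$df_residual)
  } else {
    list(d0 = 0, s0sq = 1)
  }
  contrast_tests(fit, mod)
}
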