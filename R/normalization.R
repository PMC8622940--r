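#' Convert raw fragment counts to RPKM
#'
#' RPKM = count / (region length in kb) / (library size in millions): the
#' standard reads-per-kilobase-per-million scaling that makes regions of
#' different length and samples of different depth comparable.
#'
#' @param counts regions x samples count matrix. Region lengths and library
#'   sizes are taken from its `region_lengths` / `lib_sizes` attributes when
#'   not supplied.
#' @param lengths bp per region (same order as rows).
#' @param lib_sizes total fragments per sample (same order as columns).
#' @return numeric matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm <- function(counts, lengths = attr(counts, "region_lengths"),
                 lib_sizes = attr(counts, "lib_sizes")) {
  if (is.null(lengths) || is.null(lib_sizes)) {
    abort("region lengths and library sizes are required")
  }
  lengths <- as.numeric(lengths)
  lib_sizes <- as.numeric(lib_sizes)
  if (any(lengths <= 0)) abort("all region lengths must be > 0")
  zero <- which(lib_sizes <= 0)
  if (length(zero)) {
    abort("zero library size for sample: ",
          paste(colnames(counts)[zero], collapse = ", "))
  }
  out <- counts / (lengths / 1000)
  out <- sweep(out, 2, lib_sizes / 1e6, "/")
  out
}

#' Log2-transform an RPKM matrix with a pseudocount
#'
#' @param x RPKM matrix.
#' @param pseudocount positive constant added before taking log2 (default
#'   0.5); keeps zero counts finite without changing contrasts asymptotically.
#' @return `log2(x + pseudocount)`.
#' @export
log_transform <- function(x, pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  log2(x + pseudocount)
}

#' Empirical-Bayes batch adjustment protecting biological covariates
#'
#' Removes additive/multiplicative (location/scale) batch effects from a
#' matrix of log2 values while protecting the effects of the biological
#' design (treatment group and sex), following the parametric empirical-Bayes
#' scheme popularized for microarray batch correction:
#'
#' 1. fit a per-region linear model with batch indicators plus the protected
#'    covariates, and standardize the data by the batch-free fit;
#' 2. estimate per-batch, per-region location (`gamma_hat`) and scale
#'    (`delta_hat`) of the standardized deviations;
#' 3. pool them across regions into a normal location prior and an
#'    inverse-gamma scale prior (method of moments);
#' 4. iterate the posterior updates for `gamma_star`, `delta_star` to
#'    convergence;
#' 5. subtract `gamma_star`, rescale by `1/sqrt(delta_star)` and restore the
#'    protected fit.
#'
#' With a single batch the adjustment is the identity map.
#'
#' @param x regions x samples matrix of log2 values (finite).
#' @param batch per-sample batch labels (length = ncol(x)).
#' @param design per-sample data frame with columns `group` (factor with the
#'   control level first) and optionally `sex`; these effects are protected.
#'   May be `NULL` for a covariate-free adjustment.
#' @param tol relative convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return list with `adjusted` (matrix, same shape/order as `x`) and
#'   `model` (a `batch_model`: per-batch `gamma_star`/`delta_star` matrices,
#'   prior hyperparameters, iteration counts).
#' @export
combat_adjust <- function(x, batch, design = NULL, tol = 1e-4,
                          max_iter = 100) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("input matrix must be finite")
  batch <- factor(batch)
  n <- ncol(x)
  if (length(batch) != n) abort("batch labels must match samples")
  nb <- table(batch)
  if (nlevels(batch) == 1) {
    model <- list(
      gamma_star = matrix(0, nrow(x), 1), delta_star = matrix(1, nrow(x), 1),
      priors = NULL, iterations = 0L, batches = levels(batch)
    )
    class(model) <- "batch_model"
    return(list(adjusted = x, model = model))
  }
  if (any(nb < 2)) {
    abort("each batch needs >= 2 samples; offending batch: ",
          paste(names(nb)[nb < 2], collapse = ", "))
  }
  batchmod <- stats::model.matrix(~ 0 + batch)
  mod <- protected_model_matrix(design, n)
  full <- cbind(batchmod, mod)
  if (qr(full)$rank < ncol(full)) {
    abort("batch is confounded with a protected covariate; ",
          "cannot separate batch from biology")
  }

  # 1. standardize: batch-aware fit, batch-free grand mean
  beta <- solve(crossprod(full), crossprod(full, t(x))) # (nb + p) x G
  n_batches <- nlevels(batch)
  grand <- crossprod(as.numeric(nb) / n, beta[seq_len(n_batches), , drop = FALSE])
  var_pooled <- pmax(rowMeans((x - t(full %*% beta))^2), 1e-12)
  stand_mean <- matrix(grand, nrow(x), n) # G x n
  if (!is.null(mod)) {
    stand_mean <- stand_mean +
      t(mod %*% beta[-seq_len(n_batches), , drop = FALSE])
  }
  z <- (x - stand_mean) / sqrt(var_pooled)

  # 2-4. per-batch EB shrinkage of location and scale
  gamma_star <- delta_star <- matrix(NA_real_, nrow(x), n_batches,
                                     dimnames = list(rownames(x), levels(batch)))
  priors <- vector("list", n_batches)
  names(priors) <- levels(batch)
  iters <- integer(n_batches)
  for (b in seq_len(n_batches)) {
    cols <- which(batch == levels(batch)[b])
    zb <- z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1, stats::var)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    nb_b <- length(cols)
    g_new <- g_hat
    d_new <- d_hat
    it <- 0L
    change <- 1
    ssq_about <- function(g) rowSums((zb - g)^2)
    while (change > tol && it < max_iter) {
      g_old <- g_new
      d_old <- d_new
      g_new <- (nb_b * t2 * g_hat + d_old * g_bar) / (nb_b * t2 + d_old)
      d_new <- (b_prior + 0.5 * ssq_about(g_new)) / (nb_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-8),
                    abs(d_new - d_old) / d_old)
      it <- it + 1L
    }
    gamma_star[, b] <- g_new
    delta_star[, b] <- d_new
    priors[[b]] <- c(gamma_bar = g_bar, tau2 = t2,
                     a_prior = a_prior, b_prior = b_prior)
    iters[b] <- it
  }

  # 5. adjust and restore the protected fit
  adj <- z
  for (b in seq_len(n_batches)) {
    cols <- which(batch == levels(batch)[b])
    adj[, cols] <- (z[, cols, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  adjusted <- adj * sqrt(var_pooled) + stand_mean
  model <- list(gamma_star = gamma_star, delta_star = delta_star,
                priors = priors, iterations = iters,
                batches = levels(batch), tol = tol)
  class(model) <- "batch_model"
  list(adjusted = adjusted, model = model)
}

# treatment-coded protected design (group with control reference, plus sex),
# intercept dropped because the batch indicators span it
protected_model_matrix <- function(design, n) {
  if (is.null(design)) return(NULL)
  stopifnot(nrow(design) == n)
  terms <- c()
  if ("group" %in% names(design)) terms <- c(terms, "group")
  if ("sex" %in% names(design)) terms <- c(terms, "sex")
  if (length(terms) == 0) return(NULL)
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(f, data = design)
  mm[, -1, drop = FALSE]
}

#' @export
print.batch_model <- function(x, ...) {
  cat("batch_model:", length(x$batches), "batch(es);",
      "EB iterations:", paste(x$iterations, collapse = "/"), "\n")
  invisible(x)
}
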