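toy_design <- function(n_per_cell = 2) {
  g <- rep(c("CON", "PF", "PAE"), each = 2 * n_per_cell)
  data.frame(
    sample_id = sprintf("s%02d", seq_along(g)), group = g,
    sex = rep(c("F", "M"), length(g) / 2), stringsAsFactors = FALSE
  )
}

test_that("fit_models recovers closed-form OLS coefficients", {
  d <- toy_design(1)
  # noise-free group means: CON 1.0, PAE 3.0, PF 1.0
  x <- matrix(rep(c(1, 1, 1, 1, 3, 3), each = 1), 1)
  colnames(x) <- d$sample_id
  fit <- fit_models(x, d, "concordant")
  expect_equal(unname(fit$coefficients[1, "groupPAE"]), 2)

  # constant data: all coefficients except intercept zero, zero variance
  xc <- matrix(5, 2, 6, dimnames = list(NULL, d$sample_id))
  fit <- fit_models(xc, d, "concordant")
  expect_equal(unname(fit$coefficients[, "groupPAE"]), c(0, 0))
  expect_equal(unname(fit$sigma2), c(0, 0))

  # balanced design with a pure sex effect: group coefficients vanish
  d2 <- toy_design(2)
  xs <- matrix(rep(ifelse(d2$sex == "M", 1, 0), 3), 3, byrow = TRUE)
  colnames(xs) <- d2$sample_id
  fit <- fit_models(xs, d2, "concordant")
  expect_lt(max(abs(fit$coefficients[, c("groupPF", "groupPAE")])), 1e-10)

  # sex tiers subset the samples
  fitf <- fit_models(xs, d2, "female")
  expect_equal(fitf$df_residual, sum(d2$sex == "F") - 3)
})

test_that("moderation recovers known prior parameters and degenerate limits", {
  set.seed(11)
  d0 <- 4; s0 <- 2; df <- 6
  # scaled-F sampling model: s2 = s0 * chi2_df/df / (chi2_d0/d0)
  s2 <- s0 * (rchisq(10000, df) / df) / (rchisq(10000, d0) / d0)
  est <- estimate_moderation(s2, df)
  expect_lt(abs(est$d0 - d0) / d0, 0.1)
  expect_lt(abs(est$s0sq - s0) / s0, 0.1)

  # identical variances: infinite prior df, prior variance = common value
  est <- estimate_moderation(rep(3, 50), df = 6)
  expect_true(is.infinite(est$d0))
  expect_equal(est$s0sq, 3)

  expect_error(estimate_moderation(rep(0, 10), 5), "zero")
})

test_that("d0 = 0 reproduces the classical two-sided t-test exactly", {
  set.seed(21)
  d <- toy_design(2) # 4 per group
  x <- matrix(rnorm(50 * nrow(d)), 50, nrow(d),
              dimnames = list(NULL, d$sample_id))
  ct <- run_differential(x, d, "female", moderate = FALSE)
  sub <- ct[ct$contrast == "PAEvCON", ]
  xf <- x[, d$sex == "F"]
  gf <- d$group[d$sex == "F"]
  for (i in c(1, 17, 42)) {
    # pooled-variance t-test on the same two groups, CON vs PAE, with the
    # third group still contributing to the residual variance via OLS -> use
    # lm as the textbook oracle
    fit <- lm(xf[i, ] ~ factor(gf, levels = c("CON", "PF", "PAE")))
    want <- summary(fit)$coefficients[3, 4]
    expect_equal(sub$p[i], want, tolerance = 1e-12)
  }
})

test_that("moderated tests agree with the limma oracle", {
  library(limma)
  set.seed(31)
  d <- toy_design(3)
  x <- matrix(rnorm(300 * nrow(d), 8, 1), 300, nrow(d),
              dimnames = list(NULL, d$sample_id))
  ct <- run_differential(x, d, "concordant")
  dm <- stats::model.matrix(
    ~ factor(group, levels = c("CON", "PF", "PAE")) + sex, d
  )
  cm <- cbind(PAEvCON = c(0, 0, 1, 0), PAEvPF = c(0, -1, 1, 0),
              PFvCON = c(0, 1, 0, 0))
  ref <- limma::eBayes(limma::contrasts.fit(limma::lmFit(x, dm), cm))
  for (cn in colnames(cm)) {
    sub <- ct[ct$contrast == cn, ]
    expect_equal(sub$logFC, unname(ref$coefficients[, cn]), tolerance = 1e-10)
    expect_equal(sub$p, unname(ref$p.value[, cn]), tolerance = 1e-3)
  }
})

test_that("contrast tests satisfy the null center and q >= p", {
  set.seed(41)
  d <- toy_design(2)
  x <- matrix(rnorm(100 * nrow(d)), 100, nrow(d),
              dimnames = list(NULL, d$sample_id))
  x[1, ] <- 5 # constant row: zero estimate
  ct <- run_differential(x, d, "concordant")
  first <- ct[ct$region_id == ct$region_id[1], ]
  expect_lt(max(abs(first$t)), 1e-8)
  expect_gt(min(first$p), 1 - 1e-8)
  expect_true(all(ct$q >= ct$p - 1e-15))
})

test_that("bh_fdr matches the hand-computed and brute-force step-up", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(51)
  for (rep in 1:50) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

test_that("rank-deficient designs are rejected with a diagnostic", {
  d <- toy_design(1)
  d$sex <- "F" # sex collinear with intercept in the concordant model
  x <- matrix(rnorm(12), 2, 6, dimnames = list(NULL, d$sample_id))
  expect_error(fit_models(x, d, "concordant"), "rank-deficient")
})
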