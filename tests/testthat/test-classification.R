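test_that("classify_region matches the contrast-intersection rules on all 8 flag combos", {
  flags <- expand.grid(paevcon = c(FALSE, TRUE), paevpf = c(FALSE, TRUE),
                       pfvcon = c(FALSE, TRUE))
  got <- classify_region(flags$paevcon, flags$paevpf, flags$pfvcon)
  want <- with(flags, ifelse(
    paevcon & pfvcon, "shared",
    ifelse(paevcon & paevpf & !pfvcon, "PAE_specific",
           ifelse(pfvcon & paevpf & !paevcon, "PF_specific", "none"))
  ))
  expect_equal(got, want)
  # spot checks of the named rules
  expect_equal(classify_region(TRUE, TRUE, FALSE), "PAE_specific")
  expect_equal(classify_region(FALSE, TRUE, TRUE), "PF_specific")
  expect_equal(classify_region(TRUE, TRUE, TRUE), "shared")
  expect_equal(classify_region(FALSE, FALSE, FALSE), "none")
})

mk_calls <- function(ids, tier, category) {
  data.frame(region_id = ids, tier = tier, category = category,
             stringsAsFactors = FALSE)
}

test_that("sex-tier reassignment removes sex-driven calls from the concordant tier", {
  # candidate counts mirroring the three published analyses: 307 exposure-
  # specific concordant candidates with 5 female + 14 male overlaps -> 288;
  # 132 with 1 + 2 -> 129; 799 shared with 57 + 9 -> 733
  conc <- rbind(
    mk_calls(sprintf("pae_%03d", 1:307), "concordant", "PAE_specific"),
    mk_calls(sprintf("pf_%03d", 1:132), "concordant", "PF_specific"),
    mk_calls(sprintf("sh_%03d", 1:799), "concordant", "shared")
  )
  fem <- rbind(
    mk_calls(sprintf("pae_%03d", 1:5), "female", "PAE_specific"),
    mk_calls(sprintf("pae_f_%02d", 1:13), "female", "PAE_specific"),
    mk_calls(sprintf("pf_%03d", 1), "female", "PF_specific"),
    mk_calls(sprintf("sh_%03d", 1:57), "female", "shared")
  )
  mal <- rbind(
    mk_calls(sprintf("pae_%03d", 100:113), "male", "PAE_specific"),
    mk_calls(sprintf("pf_%03d", 10:11), "male", "PF_specific"),
    mk_calls(sprintf("sh_%03d", 700:708), "male", "shared")
  )
  out <- reassign_sex_tiers(conc, fem, mal)
  final <- table(out$concordant$category)
  expect_equal(unname(final[["PAE_specific"]]), 288)
  expect_equal(unname(final[["PF_specific"]]), 129)
  expect_equal(unname(final[["shared"]]), 733)
  # sex tiers are never modified
  expect_identical(out$female, fem)
  expect_identical(out$male, mal)

  # disjoint tiers leave the concordant tier untouched
  out2 <- reassign_sex_tiers(conc, mk_calls("zz_1", "female", "PAE_specific"),
                             mk_calls("zz_2", "male", "shared"))
  expect_equal(nrow(out2$concordant), nrow(conc))

  # a region in both sex tiers is kept in both, with a warning
  expect_warning(
    reassign_sex_tiers(conc, mk_calls("dup_1", "female", "shared"),
                       mk_calls("dup_1", "male", "shared")),
    "both sex tiers"
  )
})

test_that("direction and 1.5-fold robustness follow the defining contrasts", {
  ct <- data.frame(
    region_id = rep(c("r1", "r2", "r3", "r4"), 3),
    tier = "concordant",
    contrast = rep(c("PAEvCON", "PAEvPF", "PFvCON"), each = 4),
    logFC = c(-0.9, 0.3, 0.5, 0, # PAEvCON
              -1.1, -0.3, 0.5, 0.7, # PAEvPF (PF below PAE: positive)
              0, 0, 0, -0.8), # PFvCON
    t = 0, p = 1, q = 1, stringsAsFactors = FALSE
  )
  calls <- data.frame(
    region_id = c("r1", "r2", "r3", "r4"),
    category = c("PAE_specific", "PAE_specific", "PAE_specific",
                 "PF_specific"),
    stringsAsFactors = FALSE
  )
  dr <- direction_and_robustness(calls, ct)
  expect_equal(dr$direction, c("down", "inconsistent", "up", "down"))
  # |−0.9|, |−1.1| both >= log2(1.5) ~ 0.585 -> robust; 0.5 < 0.585 -> not
  expect_equal(dr$robust_1p5fold, c(TRUE, FALSE, FALSE, TRUE))
  # PF direction uses PFvCON and the sign-flipped PAEvPF: (-0.8, +0.7) -> down
})

test_that("the Monte-Carlo direction test honors its exact edge cases", {
  # perfect balance: chi2 = 0, every replicate ties or exceeds
  r <- direction_chisq_mc(10, 10, B = 500, seed = 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_sim, 1)

  # odd total: the minimum achievable replicate statistic equals the
  # observed one, so p is exactly 1 whatever the seed
  for (seed in c(1, 99, 2026)) {
    expect_equal(direction_chisq_mc(10, 9, B = 2000, seed = seed)$p_sim, 1)
  }

  # extreme split: no replicate reaches chi2 = 133.39, p sits at the floor
  r <- direction_chisq_mc(46, 242, B = 2000, seed = 7)
  expect_equal(r$chi2, 2 * 98^2 / 144)
  expect_equal(r$chi2, 133.3889, tolerance = 1e-4)
  expect_equal(r$p_sim, 1 / 2001)

  # the add-one floor is the smallest attainable value
  expect_gte(direction_chisq_mc(0, 50, B = 99, seed = 2)$p_sim, 1 / 100)
})

test_that("the Monte-Carlo p agrees with the standard simulated chi-squared test", {
  # same statistic and comparable simulated p as chisq.test with
  # simulate.p.value (binomial null, add-one estimator)
  obs <- c(30, 50)
  mine <- direction_chisq_mc(obs[1], obs[2], B = 4000, seed = 3)
  set.seed(3)
  ref <- stats::chisq.test(obs, p = c(0.5, 0.5), simulate.p.value = TRUE,
                           B = 4000)
  expect_equal(mine$chi2, unname(ref$statistic))
  expect_lt(abs(mine$p_sim - ref$p.value), 0.02)
})

test_that("summarize_dmrs computes order statistics with the midpoint rule", {
  mk <- function(sizes) {
    data.frame(region_id = paste0("r", seq_along(sizes)), tier = "concordant",
               category = "PAE_specific", direction = "down",
               robust_1p5fold = TRUE, size_bp = sizes)
  }
  expect_equal(summarize_dmrs(mk(300))$size_median, 300)
  expect_equal(summarize_dmrs(mk(300))$size_range, c(300, 300))
  expect_equal(summarize_dmrs(mk(c(100, 200, 400)))$size_median, 200)
  expect_equal(summarize_dmrs(mk(c(100, 200)))$size_median, 150)
})
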