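mk_ct <- function(ids, p, tier = "concordant", contrast = "PAEvCON") {
  data.frame(region_id = ids, tier = tier, contrast = contrast,
             logFC = 0, t = 0, p = p, q = p, stringsAsFactors = FALSE)
}

mk_ann <- function(ids, genes) {
  data.frame(region_id = ids, gene_ids = genes, stringsAsFactors = FALSE)
}

test_that("gene_scores takes -log10 of the best region p per gene", {
  ct <- mk_ct(c("r1", "r2", "r3"), c(0.01, 0.1, 1))
  ann <- mk_ann(c("r1", "r2", "r3"), c("GA", "GA", "GB"))
  gs <- gene_scores(ct, ann)
  expect_equal(gs$score[gs$gene_id == "GA"], 2) # min(0.01, 0.1)
  expect_equal(gs$n_regions[gs$gene_id == "GA"], 2)
  expect_equal(gs$score[gs$gene_id == "GB"], 0) # p = 1
  # regionless genes are simply absent
  expect_equal(nrow(gs), 2)
})

test_that("gsr_test matches exhaustive enumeration and degenerate cases", {
  scores <- data.frame(gene_id = paste0("g", 1:10), score = 1:10,
                       n_regions = 1, stringsAsFactors = FALSE)

  # the whole universe resamples to itself
  sets <- data.frame(set_id = "all", gene_id = scores$gene_id)
  r <- gsr_test(scores, sets, iterations = 200, seed = 1)
  expect_equal(r$p_emp, 1)

  # top-2 set: exact null P(mean >= 9.5) = 1/C(10,2) = 1/45
  sets <- data.frame(set_id = "top", gene_id = c("g9", "g10"))
  iters <- 9000
  r <- gsr_test(scores, sets, iterations = iters, seed = 2)
  exact <- (1 + iters / 45) / (iters + 1)
  mc_se <- sqrt((1 / 45) * (44 / 45) / iters)
  expect_lt(abs(r$p_emp - exact), 3 * mc_se)

  # exchangeable ties: every set is unremarkable
  tied <- data.frame(gene_id = paste0("g", 1:10), score = rep(2, 10),
                     n_regions = 1)
  sets <- data.frame(set_id = c("a", "a", "b", "b", "b"),
                     gene_id = c("g1", "g2", "g3", "g4", "g5"))
  r <- gsr_test(tied, sets, iterations = 100, seed = 3)
  expect_equal(r$p_emp, c(1, 1))
})

test_that("size-violating sets are excluded without disturbing the others", {
  scores <- data.frame(gene_id = paste0("g", 1:12), score = 1:12,
                       n_regions = 1)
  sets <- data.frame(
    set_id = c("ok", "ok", "ok", "tiny", "big", "big", "big", "big"),
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8")
  )
  a <- gsr_test(scores, sets, iterations = 500, max_size = 3, seed = 4)
  expect_equal(a$set_id, "ok")
  b <- gsr_test(scores, sets[sets$set_id == "ok", ], iterations = 500,
                max_size = 3, seed = 4)
  expect_equal(a$p_emp[a$set_id == "ok"], b$p_emp[b$set_id == "ok"])
})

test_that("multifunctionality re-run flags sets carried by promiscuous genes", {
  # one extreme driver gene in a 100-gene universe of graded ordinary scores
  scores <- data.frame(gene_id = paste0("g", 1:100),
                       score = c(10, seq(0.01, 0.99, length.out = 99)),
                       n_regions = 1)
  # driver g1 sits in every set; the other members score near the median,
  # so each set is significant only through the driver
  sets <- rbind(
    data.frame(set_id = "s1", gene_id = c("g1", "g48", "g53")),
    data.frame(set_id = "s2", gene_id = c("g1", "g49", "g54")),
    data.frame(set_id = "s3", gene_id = c("g1", "g50", "g55"))
  )
  r <- gsr_test(scores, sets, iterations = 2000, seed = 7)
  expect_true(all(r$p_emp < 0.05))
  rc <- multifunctionality_check(r, scores, sets, iterations = 2000,
                                 seed = 7, k_top = 1)
  expect_true(all(rc$multifunctionality_flagged))

  # k_top = 0 is a no-op given the same seed
  r0 <- multifunctionality_check(r, scores, sets, iterations = 2000,
                                 seed = 7, k_top = 0)
  expect_equal(r0$p_emp_rerun, r$p_emp)
  expect_false(any(r0$multifunctionality_flagged))

  expect_error(
    multifunctionality_check(r, scores, sets, k_top = nrow(scores)),
    "k_top"
  )
})

test_that("final pathway lists follow the contrast-intersection logic", {
  mk_res <- function(ids, q) {
    data.frame(set_id = ids, size = 5, observed_score = 1, p_emp = q, q = q)
  }
  res <- list(
    PAEvCON = mk_res(c("A", "B", "C"), c(0.01, 0.01, 0.5)),
    PAEvPF = mk_res(c("A", "B", "C"), c(0.01, 0.5, 0.5)),
    PFvCON = mk_res(c("A", "B", "C"), c(0.5, 0.01, 0.5))
  )
  out <- final_pathway_sets(res)
  expect_equal(out$category[out$set_id == "A"], "PAE_specific")
  expect_equal(out$category[out$set_id == "B"], "shared")
  expect_false("C" %in% out$set_id)
})

test_that("gene-list overlap is case-insensitive and deduplicated", {
  dmr_genes <- data.frame(
    gene_id = c("Negr1", "negr1", "Kcnq1", "Drd4"),
    tier = c("concordant", "concordant", "concordant", "female"),
    category = c("PAE_specific", "PAE_specific", "PAE_specific", "shared"),
    stringsAsFactors = FALSE
  )
  lists <- list(gwas = c("NEGR1", "MMS22L"), empty = character())
  ov <- gene_list_overlap(dmr_genes, lists)
  hit <- ov[ov$list_name == "gwas" & ov$tier == "concordant" &
              ov$category == "PAE_specific", ]
  expect_equal(hit$genes, "NEGR1")
  expect_equal(hit$n_overlap, 1)
  expect_true(all(ov$n_overlap[ov$list_name == "empty"] == 0))
})
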