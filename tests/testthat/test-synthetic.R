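small_cfg <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_regions = 300, n_genes = 40,
         chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chrX = 2e5)),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("generate_design crosses groups and sexes with litter and batch constraints", {
  d <- generate_design(n_per_cell = 5, n_batches = 2, seed = 1)
  expect_equal(nrow(d), 30)
  expect_equal(unname(table(d$group, d$sex)), matrix(5L, 3, 2))
  # no litter contributes two animals of the same sex
  expect_false(any(table(d$litter, d$sex) > 1))
  # batches unconfounded with group or sex (both present in every cell)
  expect_true(all(table(d$batch, d$group) >= 2))

  d1 <- generate_design(n_per_cell = 1, seed = 1)
  expect_equal(nrow(d1), 6)
  expect_error(generate_design(n_per_cell = 0), "n_per_cell")
})

test_that("genome annotation partitions gene bodies into exons and introns", {
  cfg <- small_cfg()
  g <- generate_genome_annotation(cfg)
  # exons and introns are disjoint and exactly tile each gene body
  for (gene in g$genes$name[1:5]) {
    body <- g$genes[g$genes$name == gene, ]
    ex <- g$exons[g$exons$name == gene, ]
    intr <- g$introns[g$introns$name == gene, ]
    segs <- rbind(ex[c("start", "end")], intr[c("start", "end")])
    segs <- segs[order(segs$start), ]
    expect_equal(segs$start[1], body$start)
    expect_equal(segs$end[nrow(segs)], body$end)
    # contiguous, non-overlapping tiling
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  }
  # promoters from the TSS definition, strand-aware
  plus <- g$genes[g$genes$strand == "+", ][1, ]
  p200 <- g$promoter200[g$promoter200$name == plus$name, ]
  expect_equal(c(p200$start, p200$end), c(plus$start - 200, plus$start))
  minus <- g$genes[g$genes$strand == "-", ][1, ]
  p1500 <- g$promoter1500[g$promoter1500$name == minus$name, ]
  expect_equal(c(p1500$start, p1500$end), c(minus$end, minus$end + 1500))
})

test_that("regions/counts generation is deterministic and honors the null", {
  cfg <- small_cfg()
  d <- generate_design(cfg$n_per_cell, cfg$n_batches, cfg$seed)
  rc1 <- generate_regions_counts(d, cfg)
  rc2 <- generate_regions_counts(d, cfg)
  expect_identical(rc1$counts, rc2$counts)
  expect_identical(rc1$truth, rc2$truth)

  # regions non-overlapping, some on the sex chromosome
  r <- rc1$regions
  same <- r$chrom[-1] == r$chrom[-nrow(r)]
  expect_true(all(r$start[-1][same] >= r$end[-nrow(r)][same]))
  expect_gt(sum(r$chrom == "chrX"), 0)
  # planted regions are autosomal and every truth row exists in the regions
  planted <- rc1$truth[rc1$truth$category != "none", ]
  expect_true(all(planted$region_id %in% r$region_id[r$chrom != "chrX"]))
  expect_true(all(abs(planted$effect) == cfg$effect_size))

  null_cfg <- small_cfg(effect_size = 0)
  rc0 <- generate_regions_counts(d, null_cfg)
  expect_true(all(rc0$truth$category == "none"))
  expect_true(all(rc0$truth$effect == 0))
})

test_that("planted effects have the stated magnitude at large n", {
  cfg <- sim_config(seed = 8, n_per_cell = 50, n_regions = 120, n_genes = 0,
                    chrom_lengths = c(chr1 = 1e6, chrX = 1e5))
  d <- generate_design(cfg$n_per_cell, cfg$n_batches, cfg$seed)
  rc <- generate_regions_counts(d, cfg)
  tr <- rc$truth
  ids <- tr$region_id[tr$tier == "concordant" & tr$category == "PAE_specific" &
                        tr$direction == "down"]
  expect_gt(length(ids), 0)
  pae <- d$group == "PAE"
  con <- d$group == "CON"
  for (id in ids) {
    obs <- log2(mean(rc$counts[id, pae])) - log2(mean(rc$counts[id, con]))
    expect_lt(abs(obs - (-1)), 0.2)
  }
})

test_that("peaksets and fragments reproduce the count matrix and dropout contract", {
  cfg <- small_cfg(seed = 4, n_regions = 80, dropout_prob = 0)
  d <- generate_design(2, 2, cfg$seed)
  rc <- generate_regions_counts(d, cfg)
  pf <- generate_peaksets_fragments(rc$regions, d, rc$counts, cfg)
  # no dropout: every sample's peakset has one peak per true region
  expect_true(all(vapply(pf$peaks, nrow, 0L) == nrow(rc$regions)))
  # fragment starts land inside their region: counting reproduces counts
  cm <- count_fragments(pf$fragments, rc$regions)
  expect_equal(unname(cm), unname(rc$counts), ignore_attr = TRUE)

  cfg1 <- small_cfg(seed = 4, n_regions = 80, dropout_prob = 1)
  pf1 <- generate_peaksets_fragments(rc$regions, d, rc$counts, cfg1)
  expect_true(all(vapply(pf1$peaks, nrow, 0L) == 0))
})

test_that("gene sets respect size bounds and the planted set is enriched", {
  genes <- sprintf("gene_%03d", 1:50)
  gs <- generate_gene_sets(genes, planted_genes = genes[1:15], n_sets = 10,
                           seed = 2)
  sizes <- table(gs$set_id)
  expect_true(all(sizes >= 2 & sizes <= 2000))
  planted <- attr(gs, "planted_set")
  expect_equal(planted, "set_planted")
  members <- gs$gene_id[gs$set_id == planted]
  expect_gte(mean(members %in% genes[1:15]), 0.8)
  gs2 <- generate_gene_sets(genes, planted_genes = genes[1:15], n_sets = 10,
                            seed = 2)
  expect_identical(gs, gs2)
  expect_error(generate_gene_sets(genes[1:5]), ">= 10")
})

test_that("simulate_study is end-to-end deterministic under one master seed", {
  cfg <- small_cfg(seed = 12, n_regions = 150)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$gene_sets, s2$gene_sets)
  expect_identical(as.data.frame(s1$genome$exons),
                   as.data.frame(s2$genome$exons))
})
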