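#' Annotate consensus regions with genomic feature classes
#'
#' A region receives every feature class it overlaps by at least one base
#' (a region may span multiple features). Two derived classes are added:
#' `intron_exon_boundary` when an exon and an intron of the same gene both
#' overlap the region, and `intergenic` when no gene-derived feature
#' (exon, intron, promoter, UTR) overlaps at all. CpG islands are independent
#' of gene structure and may co-occur with `intergenic`. `gene_ids` collects
#' the genes whose body or promoter overlaps the region.
#'
#' @param regions a `consensus_regions` table.
#' @param features named list of `interval_set`s; recognized names:
#'   `genes`, `exons`, `introns`, `promoter200`, `promoter1500`, `utr5`,
#'   `utr3`, `cpg_islands`. `exons`/`introns`/`genes`/promoters/UTRs should
#'   carry the gene id in their `name` column.
#' @return a `region_annotation` data frame: `region_id`, one logical column
#'   per feature class, and `gene_ids` (semicolon-joined, possibly empty).
#' @export
annotate_regions <- function(regions, features) {
  gene_classes <- c("exons", "introns", "promoter200", "promoter1500",
                    "utr5", "utr3")
  class_col <- c(
    exons = "exon", introns = "intron", promoter200 = "promoter200",
    promoter1500 = "promoter1500", utr5 = "utr5", utr3 = "utr3",
    cpg_islands = "cpg_island"
  )
  rgr <- as_granges(regions)
  n <- nrow(regions)
  ann <- data.frame(region_id = regions$region_id, stringsAsFactors = FALSE)
  overlaps <- list() # per class: hits data frame (region index, gene)
  for (cl in names(class_col)) {
    ann[[class_col[[cl]]]] <- rep(FALSE, n)
    fs <- features[[cl]]
    if (is.null(fs) || nrow(fs) == 0) next
    hits <- GenomicRanges::findOverlaps(rgr, as_granges(fs),
                                        minoverlap = 1L, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    ann[[class_col[[cl]]]][unique(qi)] <- TRUE
    overlaps[[cl]] <- data.frame(
      region = qi,
      gene = if ("name" %in% names(fs)) {
        fs$name[S4Vectors::subjectHits(hits)]
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  # intron/exon boundary: exon and intron of the same gene both overlap
  ann$intron_exon_boundary <- rep(FALSE, n)
  if (!is.null(overlaps$exons) && !is.null(overlaps$introns)) {
    ek <- paste(overlaps$exons$region, overlaps$exons$gene)
    ik <- paste(overlaps$introns$region, overlaps$introns$gene)
    hit <- overlaps$exons$region[ek %in% ik]
    ann$intron_exon_boundary[unique(hit)] <- TRUE
  }
  gene_derived <- class_col[gene_classes]
  ann$intergenic <- !Reduce(`|`, ann[gene_derived])
  # gene ids: gene body or promoter overlap
  gid <- rep("", n)
  src <- c("genes", "exons", "introns", "promoter200", "promoter1500",
           "utr5", "utr3")
  pieces <- overlaps[intersect(src, names(overlaps))]
  if (!is.null(features$genes) && nrow(features$genes) > 0) {
    hits <- GenomicRanges::findOverlaps(rgr, as_granges(features$genes),
                                        minoverlap = 1L, ignore.strand = TRUE)
    pieces$genes <- data.frame(
      region = S4Vectors::queryHits(hits),
      gene = features$genes$name[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
  }
  if (length(pieces)) {
    allhits <- do.call(rbind, pieces)
    allhits <- allhits[!is.na(allhits$gene), , drop = FALSE]
    if (nrow(allhits)) {
      by_region <- split(allhits$gene, allhits$region)
      for (r in names(by_region)) {
        gid[as.integer(r)] <- paste(sort(unique(by_region[[r]])),
                                    collapse = ";")
      }
    }
  }
  ann$gene_ids <- gid
  class(ann) <- c("region_annotation", "data.frame")
  ann
}

#' Feature enrichment of a DMR set against a permutation null
#'
#' For each feature class, compares the number of DMRs carrying the feature
#' with the distribution obtained from `n_perm` random subsets of the tested
#' region universe of the same size as the DMR set (sampling without
#' replacement). The empirical p-value uses the add-one rule and is
#' one-sided in the direction of the observed deviation: `enriched` when the
#' observed count is at or above the null mean (p = proportion of
#' permutation counts >= observed), `depleted` otherwise (<=).
#'
#' @param dmr_ids region ids of the DMR set (subset of `background_ids`).
#' @param background_ids all consensus region ids that entered testing.
#' @param annotation a `region_annotation` covering the background.
#' @param n_perm number of random subsets (default 10000).
#' @param seed optional seed.
#' @return data frame: `feature`, `observed_count`, `observed_prop`,
#'   `null_mean`, `direction`, `p_emp`, `n_perm`.
#' @export
permutation_enrichment <- function(dmr_ids, background_ids, annotation,
                                   n_perm = 10000, seed = NULL) {
  if (!all(dmr_ids %in% background_ids)) {
    abort("dmr_ids must be a subset of background_ids")
  }
  k <- length(dmr_ids)
  if (k < 1) abort("empty DMR set")
  if (k > length(background_ids)) abort("DMR set larger than background")
  if (!is.null(seed)) set.seed(seed)
  feat_cols <- setdiff(names(annotation), c("region_id", "gene_ids"))
  fm <- as.matrix(annotation[match(background_ids, annotation$region_id),
                             feat_cols, drop = FALSE])
  storage.mode(fm) <- "integer"
  obs <- colSums(fm[match(dmr_ids, background_ids), , drop = FALSE])
  nbg <- length(background_ids)
  null_counts <- matrix(0L, n_perm, length(feat_cols),
                        dimnames = list(NULL, feat_cols))
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nbg, k)
    null_counts[i, ] <- colSums(fm[idx, , drop = FALSE])
  }
  null_mean <- colMeans(null_counts)
  enriched <- obs >= null_mean
  p_emp <- vapply(seq_along(feat_cols), function(j) {
    if (enriched[j]) {
      (1 + sum(null_counts[, j] >= obs[j])) / (n_perm + 1)
    } else {
      (1 + sum(null_counts[, j] <= obs[j])) / (n_perm + 1)
    }
  }, numeric(1))
  data.frame(
    feature = feat_cols,
    observed_count = as.integer(obs),
    observed_prop = as.numeric(obs) / k,
    null_mean = null_mean,
    direction = ifelse(enriched, "enriched", "depleted"),
    p_emp = p_emp,
    n_perm = n_perm,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
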