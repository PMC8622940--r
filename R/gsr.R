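#' Per-gene scores from region-level p-values
#'
#' Each gene's score is `-log10` of the best (smallest) p-value among the
#' regions annotated to it for the chosen contrast — the standard input for
#' gene-score resampling when the underlying tests are region-level.
#'
#' @param ct a `contrast_table` for one tier.
#' @param annotation a `region_annotation` (provides `gene_ids`).
#' @param contrast which contrast's p-values to use.
#' @return data frame: `gene_id`, `score`, `n_regions`.
#' @export
gene_scores <- function(ct, annotation, contrast = "PAEvCON") {
  sub <- ct[ct$contrast == contrast, c("region_id", "p")]
  ann <- annotation[match(sub$region_id, annotation$region_id), ]
  has <- nzchar(ann$gene_ids) & !is.na(ann$gene_ids)
  if (!any(has)) {
    return(data.frame(gene_id = character(), score = numeric(),
                      n_regions = integer(), stringsAsFactors = FALSE))
  }
  genes <- strsplit(ann$gene_ids[has], ";", fixed = TRUE)
  long <- data.frame(
    gene_id = unlist(genes),
    p = rep(sub$p[has], lengths(genes)),
    stringsAsFactors = FALSE
  )
  best <- tapply(long$p, long$gene_id, min)
  nreg <- tapply(long$p, long$gene_id, length)
  data.frame(
    gene_id = names(best),
    score = -log10(pmax(as.numeric(best), 1e-300)),
    n_regions = as.integer(nreg),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Gene-score resampling (GSR) over gene sets
#'
#' For each retained gene set (size within `[min_size, max_size]` counting
#' only scored members, and at least 2 scored members), the observed
#' statistic is the mean member score. The null resamples that many scores
#' from the whole scored-gene universe without replacement, `iterations`
#' times; `p_emp` uses the add-one rule, and Benjamini-Hochberg q-values are
#' computed across retained sets.
#'
#' @param scores data frame from [gene_scores()].
#' @param sets data frame with columns `set_id`, `gene_id` (flattened GMT).
#' @param iterations resampling iterations (default 10000).
#' @param min_size,max_size set-size bounds (defaults 2 and 2000).
#' @param seed optional seed.
#' @return data frame: `set_id`, `size`, `observed_score`, `p_emp`, `q`.
#' @export
gsr_test <- function(scores, sets, iterations = 10000, min_size = 2,
                     max_size = 2000, seed = NULL) {
  if (nrow(scores) < max(2, min_size)) abort("too few scored genes")
  if (!is.null(seed)) set.seed(seed)
  sc <- stats::setNames(scores$score, scores$gene_id)
  members <- split(sets$gene_id, sets$set_id)
  members <- lapply(members, function(g) unique(g[g %in% names(sc)]))
  sizes <- lengths(members)
  keep <- sizes >= max(2, min_size) & sizes <= max_size
  members <- members[keep]
  sizes <- sizes[keep]
  if (length(members) == 0) {
    return(data.frame(set_id = character(), size = integer(),
                      observed_score = numeric(), p_emp = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  nall <- length(sc)
  # one shared null per distinct set size
  null_by_size <- lapply(
    stats::setNames(nm = sort(unique(sizes))),
    function(s) {
      s <- as.integer(s)
      vapply(seq_len(iterations),
             function(i) mean(sc[sample.int(nall, s)]), numeric(1))
    }
  )
  obs <- vapply(members, function(g) mean(sc[g]), numeric(1))
  p_emp <- vapply(seq_along(members), function(j) {
    nulls <- null_by_size[[as.character(sizes[j])]]
    (1 + sum(nulls >= obs[j] - 1e-12)) / (iterations + 1)
  }, numeric(1))
  out <- data.frame(
    set_id = names(members), size = as.integer(sizes),
    observed_score = obs, p_emp = p_emp, q = bh_fdr(p_emp),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("gsr_result", "data.frame")
  out
}

#' Multifunctionality robustness check for GSR results
#'
#' A gene's multifunctionality is the number of retained sets it belongs to.
#' The GSR test is re-run with the `k_top` most multifunctional genes removed
#' from the score table; a set is flagged when it was significant in the
#' original run but loses significance in the re-run — i.e. its enrichment
#' was driven by promiscuously annotated genes.
#'
#' @param results a `gsr_result` from [gsr_test()].
#' @param scores,sets,iterations,min_size,max_size,seed as in [gsr_test()];
#'   pass the same seed for a comparable re-run.
#' @param k_top number of most-multifunctional genes to remove (default 1%
#'   of scored genes, at least 1).
#' @param alpha significance threshold on `p_emp` (default 0.05).
#' @return `results` with added columns `multifunctionality_flagged` and
#'   `p_emp_rerun`.
#' @export
multifunctionality_check <- function(results, scores, sets,
                                     iterations = 10000, min_size = 2,
                                     max_size = 2000, seed = NULL,
                                     k_top = NULL, alpha = 0.05) {
  if (is.null(k_top)) k_top <- max(1L, floor(0.01 * nrow(scores)))
  if (k_top >= nrow(scores)) {
    abort("k_top must be smaller than the number of scored genes")
  }
  if (k_top == 0) {
    results$p_emp_rerun <- results$p_emp
    results$multifunctionality_flagged <- FALSE
    return(results)
  }
  retained <- sets[sets$set_id %in% results$set_id, ]
  mf <- table(unique(retained[, c("set_id", "gene_id")])$gene_id)
  mf_ranked <- names(sort(mf, decreasing = TRUE))
  drop <- mf_ranked[seq_len(min(k_top, length(mf_ranked)))]
  scores2 <- scores[!scores$gene_id %in% drop, , drop = FALSE]
  rerun <- gsr_test(scores2, sets, iterations, min_size, max_size, seed)
  i <- match(results$set_id, rerun$set_id)
  results$p_emp_rerun <- rerun$p_emp[i]
  results$multifunctionality_flagged <-
    results$p_emp < alpha & (is.na(i) | rerun$p_emp[i] >= alpha)
  results
}

#' Category-specific pathway lists across the three contrasts
#'
#' Applies the same intersection logic as DMR classification to set-level
#' significance: a set is significant for a contrast when `q < alpha` and not
#' multifunctionality-flagged.
#'
#' @param results_by_contrast named list of `gsr_result` tables with names
#'   `PAEvCON`, `PAEvPF`, `PFvCON`.
#' @param alpha FDR threshold (default 0.05).
#' @return data frame: `set_id`, `category` (only non-"none" rows).
#' @export
final_pathway_sets <- function(results_by_contrast, alpha = 0.05) {
  need <- c("PAEvCON", "PAEvPF", "PFvCON")
  if (!all(need %in% names(results_by_contrast))) {
    abort("results for all three contrasts are required")
  }
  sig <- lapply(results_by_contrast[need], function(r) {
    flagged <- if ("multifunctionality_flagged" %in% names(r)) {
      r$multifunctionality_flagged
    } else FALSE
    r$set_id[r$q < alpha & !flagged]
  })
  all_sets <- unique(unlist(lapply(results_by_contrast[need], `[[`, "set_id")))
  cat <- classify_region(
    all_sets %in% sig$PAEvCON, all_sets %in% sig$PAEvPF,
    all_sets %in% sig$PFvCON
  )
  data.frame(set_id = all_sets, category = cat,
             stringsAsFactors = FALSE)[cat != "none", , drop = FALSE]
}

#' Overlap of DMR-linked genes with external gene lists
#'
#' Case-insensitive symbol matching (both sides uppercased), deduplicated.
#'
#' @param dmr_genes data frame with columns `gene_id`, `tier`, `category`
#'   (one row per DMR-linked gene occurrence).
#' @param external_lists named list of character vectors of gene symbols.
#' @return data frame: `list_name`, `tier`, `category`, `genes`
#'   (semicolon-joined, uppercase; empty string when no overlap).
#' @export
gene_list_overlap <- function(dmr_genes, external_lists) {
  combos <- unique(dmr_genes[, c("tier", "category")])
  out <- do.call(rbind, lapply(names(external_lists), function(ln) {
    ext <- unique(toupper(external_lists[[ln]]))
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      g <- dmr_genes$gene_id[
        dmr_genes$tier == combos$tier[i] &
          dmr_genes$category == combos$category[i]
      ]
      ov <- sort(intersect(unique(toupper(g)), ext))
      data.frame(
        list_name = ln, tier = combos$tier[i], category = combos$category[i],
        genes = paste(ov, collapse = ";"), n_overlap = length(ov),
        stringsAsFactors = FALSE
      )
    }))
  }))
  if (is.null(out)) {
    out <- data.frame(list_name = character(), tier = character(),
                      category = character(), genes = character(),
                      n_overlap = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
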