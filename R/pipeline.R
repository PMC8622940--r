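#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, injects defaults (the study's
#' published parameters: minimum peak support 3, FDR 0.05, 10,000 enrichment
#' permutations, GSR iterations 10,000 with set sizes in [2, 2000]),
#' type/range-checks every parameter, rejects unknown keys, and checks that
#' required input paths exist unless synthetic mode is enabled. Errors are
#' aggregated, one line per violation.
#'
#' @param config YAML path or named list.
#' @return a validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    synthetic = FALSE,
    use_reads = FALSE,
    outdir = NULL,
    design = NULL, peaks_manifest = NULL, fragments_manifest = NULL,
    counts = NULL, regions = NULL, features_dir = NULL, gene_sets = NULL,
    external_lists = NULL,
    min_samples = 3, alpha = 0.05, pseudocount = 0.5,
    n_perm = 10000, gsr_iterations = 10000,
    gsr_min_size = 2, gsr_max_size = 2000,
    B = 2000, seed = 1, moderate = TRUE,
    sex_chroms = c("chrX", "chrY"),
    sim = list()
  )
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config key: ", unknown))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$min_samples) && cfg$min_samples >= 1,
      "min_samples must be >= 1")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha <= 1,
      "alpha must be in (0, 1]")
  chk(is.numeric(cfg$pseudocount) && cfg$pseudocount > 0,
      "pseudocount must be > 0")
  chk(is.numeric(cfg$n_perm) && cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(is.numeric(cfg$gsr_iterations) && cfg$gsr_iterations >= 1,
      "gsr_iterations must be >= 1")
  chk(is.numeric(cfg$gsr_min_size) && cfg$gsr_min_size >= 2,
      "gsr_min_size must be >= 2")
  chk(is.numeric(cfg$gsr_max_size) && cfg$gsr_max_size >= cfg$gsr_min_size,
      "gsr_max_size must be >= gsr_min_size")
  chk(is.numeric(cfg$B) && cfg$B >= 1, "B must be >= 1")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  if (!isTRUE(cfg$synthetic)) {
    for (key in c("design", "peaks_manifest", "fragments_manifest")) {
      if (is.null(cfg[[key]]) && is.null(cfg$counts) && key != "design") next
      if (is.null(cfg[[key]])) {
        if (key == "design") errs <- c(errs, "missing required key: design")
        next
      }
      if (!file.exists(cfg[[key]])) {
        errs <- c(errs, paste0(key, " path does not exist: ", cfg[[key]]))
      }
    }
    if (is.null(cfg$counts) && is.null(cfg$peaks_manifest)) {
      errs <- c(errs,
                "either counts or peaks_manifest + fragments_manifest needed")
    }
  }
  if (length(errs)) abort("invalid config:\n  ", paste(errs, collapse = "\n  "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full differential-methylation pipeline
#'
#' Executes the stages in dependency order: simulate (synthetic mode) or load
#' inputs; consensus + sex-chromosome removal + counting; RPKM + log2 +
#' batch adjustment; moderated differential testing for the three tiers;
#' DMR classification with sex-tier reassignment and direction tests;
#' genomic-feature annotation and permutation enrichment; gene-score
#' resampling with multifunctionality check and category-specific pathway
#' lists; optional external gene-list overlap. All outputs are plain TSV.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return invisibly, a list of all stage results plus a `manifest` of output
#'   file hashes when `outdir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(unclass(config))
  res <- list(config = cfg)

  if (isTRUE(cfg$synthetic)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_study(scfg, with_reads = isTRUE(cfg$use_reads))
    res$truth <- sim$truth
    design <- sim$design
    genome <- sim$genome
    gene_sets <- sim$gene_sets
    if (isTRUE(cfg$use_reads)) {
      consensus <- build_consensus(sim$peaks, cfg$min_samples)
      consensus <- remove_sex_chromosomes(consensus, cfg$sex_chroms)
      counts <- count_fragments(sim$fragments, consensus)
    } else {
      consensus <- remove_sex_chromosomes(sim$regions, cfg$sex_chroms)
      counts <- sim$counts[consensus$region_id, , drop = FALSE]
      attr(counts, "lib_sizes") <- attr(sim$counts, "lib_sizes")
      attr(counts, "region_lengths") <-
        attr(sim$counts, "region_lengths")[consensus$region_id]
    }
  } else {
    design <- utils::read.delim(cfg$design, stringsAsFactors = FALSE)
    genome <- load_feature_beds(cfg$features_dir)
    gene_sets <- if (!is.null(cfg$gene_sets)) {
      utils::read.delim(cfg$gene_sets, stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(cfg$counts)) {
      if (is.null(cfg$regions)) {
        abort("counts input requires a regions BED (config key 'regions')")
      }
      ctab <- utils::read.delim(cfg$counts, check.names = FALSE)
      counts <- as.matrix(ctab[, -1])
      rownames(counts) <- ctab[[1]]
      if (!all(design$sample_id %in% colnames(counts))) {
        abort("counts columns must cover all design samples")
      }
      counts <- counts[, design$sample_id, drop = FALSE]
      rb <- read_bed(cfg$regions)
      consensus <- as_consensus_regions(data.frame(
        chrom = rb$chrom, start = rb$start, end = rb$end,
        region_id = if ("name" %in% names(rb)) rb$name else
          rownames(counts), stringsAsFactors = FALSE
      ))
      consensus <- remove_sex_chromosomes(consensus, cfg$sex_chroms)
      counts <- counts[consensus$region_id, , drop = FALSE]
      lib <- utils::read.delim(paste0(cfg$counts, ".libsizes"),
                               stringsAsFactors = FALSE)
      attr(counts, "lib_sizes") <- stats::setNames(lib$lib_size,
                                                   lib$sample_id)[colnames(counts)]
      attr(counts, "region_lengths") <- stats::setNames(
        consensus$end - consensus$start, consensus$region_id)
    } else {
      peaks <- read_manifest(cfg$peaks_manifest)
      frags <- read_manifest(cfg$fragments_manifest)
      consensus <- build_consensus(peaks, cfg$min_samples)
      consensus <- remove_sex_chromosomes(consensus, cfg$sex_chroms)
      counts <- count_fragments(frags[design$sample_id], consensus)
    }
  }
  res$design <- design
  res$consensus <- consensus

  # normalization
  norm <- log_transform(rpkm(counts), cfg$pseudocount)
  batches <- design$batch
  res$batch_model <- NULL
  if (length(unique(batches)) > 1) {
    cb <- combat_adjust(norm, batches, design)
    norm <- cb$adjusted
    res$batch_model <- cb$model
  }
  res$normalized <- norm

  # differential testing, three tiers
  tiers <- c("concordant", "female", "male")
  res$contrasts <- lapply(
    stats::setNames(nm = tiers),
    function(tier) run_differential(norm, design, tier, cfg$moderate)
  )

  # classification
  calls <- lapply(res$contrasts, call_dmrs, regions = consensus,
                  alpha = cfg$alpha)
  re <- reassign_sex_tiers(calls$concordant, calls$female, calls$male)
  res$dmrs <- re
  all_calls <- do.call(rbind, re[tiers])
  res$summary <- summarize_dmrs(all_calls)
  res$direction_tests <- direction_tests_by_cell(
    all_calls, cfg$B, spawn_seed(cfg$seed, "classify")
  )

  # annotation + enrichment
  res$annotation <- annotate_regions(consensus, genome)
  res$enrichment <- enrichment_by_cell(
    all_calls, consensus$region_id, res$annotation,
    cfg$n_perm, spawn_seed(cfg$seed, "enrich")
  )

  # gene-score resampling on the sex-concordant tier
  if (!is.null(gene_sets) && nrow(gene_sets) > 0) {
    res$gsr <- lapply(
      stats::setNames(nm = c("PAEvCON", "PAEvPF", "PFvCON")),
      function(cn) {
        sc <- gene_scores(res$contrasts$concordant, res$annotation, cn)
        if (nrow(sc) < 2) return(NULL)
        r <- gsr_test(sc, gene_sets, cfg$gsr_iterations, cfg$gsr_min_size,
                      cfg$gsr_max_size, seed = spawn_seed(cfg$seed, "gsr"))
        multifunctionality_check(r, sc, gene_sets, cfg$gsr_iterations,
                                 cfg$gsr_min_size, cfg$gsr_max_size,
                                 seed = spawn_seed(cfg$seed, "gsr"),
                                 alpha = cfg$alpha)
      }
    )
    if (!any(vapply(res$gsr, is.null, TRUE))) {
      res$pathways <- final_pathway_sets(res$gsr, cfg$alpha)
    }
  }

  # external gene-list overlap
  if (!is.null(cfg$external_lists)) {
    lists <- read_gene_lists(cfg$external_lists)
    dmr_genes <- dmr_gene_table(all_calls, res$annotation)
    res$overlaps <- gene_list_overlap(dmr_genes, lists)
  }

  if (!is.null(cfg$outdir)) {
    res$manifest <- write_pipeline_outputs(res, cfg$outdir)
  }
  invisible(res)
}

direction_tests_by_cell <- function(calls, B, seed) {
  cells <- unique(calls[, c("tier", "category")])
  if (nrow(cells) == 0) return(NULL)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- calls[calls$tier == cells$tier[i] &
                   calls$category == cells$category[i], ]
    dt <- direction_chisq_mc(sum(sub$direction == "up"),
                             sum(sub$direction == "down"),
                             B = B, seed = seed + i)
    data.frame(tier = cells$tier[i], category = cells$category[i],
               n_up = dt$n_up, n_down = dt$n_down, chi2 = dt$chi2,
               p_sim = dt$p_sim, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

enrichment_by_cell <- function(calls, background, annotation, n_perm, seed) {
  cells <- unique(calls[, c("tier", "category")])
  if (nrow(cells) == 0) return(NULL)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- calls$region_id[calls$tier == cells$tier[i] &
                             calls$category == cells$category[i]]
    ids <- intersect(ids, background)
    if (length(ids) == 0) return(NULL)
    e <- permutation_enrichment(ids, background, annotation, n_perm,
                                seed = seed + i)
    cbind(tier = cells$tier[i], category = cells$category[i], e)
  })
  do.call(rbind, out)
}

dmr_gene_table <- function(calls, annotation) {
  i <- match(calls$region_id, annotation$region_id)
  gid <- annotation$gene_ids[i]
  has <- !is.na(gid) & nzchar(gid)
  if (!any(has)) {
    return(data.frame(gene_id = character(), tier = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  genes <- strsplit(gid[has], ";", fixed = TRUE)
  data.frame(
    gene_id = unlist(genes),
    tier = rep(calls$tier[has], lengths(genes)),
    category = rep(calls$category[has], lengths(genes)),
    stringsAsFactors = FALSE
  )
}

read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "path") %in% names(man)))
  sets <- lapply(man$path, read_bed)
  names(sets) <- man$sample_id
  sets
}

load_feature_beds <- function(dir) {
  classes <- c("genes", "exons", "introns", "promoter200", "promoter1500",
               "utr5", "utr3", "cpg_islands")
  out <- list()
  if (is.null(dir)) return(out)
  for (cl in classes) {
    p <- file.path(dir, paste0(cl, ".bed"))
    if (file.exists(p)) out[[cl]] <- read_bed(p, label = cl)
  }
  out
}

read_gene_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("list_name", "gene_id") %in% names(df)))
  split(df$gene_id, df$list_name)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character()
  paths <- c(paths, wt(res$design, "design.tsv"))
  paths <- c(paths, wt(res$consensus, "consensus_regions.tsv"))
  norm <- data.frame(region_id = rownames(res$normalized), res$normalized,
                     check.names = FALSE)
  paths <- c(paths, wt(norm, "normalized_log2rpkm.tsv"))
  for (tier in names(res$contrasts)) {
    paths <- c(paths, wt(res$contrasts[[tier]],
                         paste0("contrasts_", tier, ".tsv")))
    paths <- c(paths, wt(res$dmrs[[tier]], paste0("dmrs_", tier, ".tsv")))
  }
  if (!is.null(res$direction_tests)) {
    paths <- c(paths, wt(res$direction_tests, "direction_tests.tsv"))
  }
  ann <- res$annotation
  feat_cols <- setdiff(names(ann), c("region_id", "gene_ids"))
  flat <- data.frame(
    region_id = ann$region_id,
    features = apply(ann[feat_cols], 1, function(r) {
      paste(feat_cols[as.logical(r)], collapse = ";")
    }),
    gene_ids = ann$gene_ids, stringsAsFactors = FALSE
  )
  paths <- c(paths, wt(flat, "annotation.tsv"))
  if (!is.null(res$enrichment)) {
    paths <- c(paths, wt(res$enrichment, "enrichment.tsv"))
  }
  if (!is.null(res$gsr)) {
    for (cn in names(res$gsr)) {
      if (!is.null(res$gsr[[cn]])) {
        paths <- c(paths, wt(res$gsr[[cn]], paste0("gsr_", cn, ".tsv")))
      }
    }
  }
  if (!is.null(res$pathways)) paths <- c(paths, wt(res$pathways, "pathways.tsv"))
  if (!is.null(res$overlaps)) paths <- c(paths, wt(res$overlaps, "overlaps.tsv"))
  if (!is.null(res$truth)) paths <- c(paths, wt(res$truth, "truth.tsv"))
  manifest <- data.frame(
    file = basename(paths),
    md5 = as.character(tools::md5sum(paths)),
    seed = res$config$seed,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(outdir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
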