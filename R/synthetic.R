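#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults reproduce
#' the study's design: 3 prenatal treatment groups (CON, PF, PAE) crossed
#' with 2 sexes at 5 animals per cell, negative-binomial region counts with
#' common dispersion 0.1, a 0.5 log2 multiplicative batch shift, planted
#' differentially methylated regions of every tier x category x direction
#' combination at 1 log2 unit, and a sex chromosome whose regions carry a
#' sex-dependent baseline (so failing to remove them is detectable).
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param n_per_cell animals per group x sex cell (default 5; 30 samples).
#' @param n_batches number of batches (default 2).
#' @param n_regions number of consensus-sized regions (default 5000).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param batch_effect log2 shift added to every region of batch 2, 3, ...
#'   relative to batch 1 (default 0.5).
#' @param effect_size planted log2 shift of differential regions (default 1).
#' @param planted_frac fraction of regions planted as DMRs (default 0.10).
#' @param dropout_prob per-sample peak dropout probability (default 0.05).
#' @param libsize_sd sd of the log-normal library-size factors (default 0.2).
#' @param rate_meanlog,rate_sdlog log-normal parameters of the per-region
#'   baseline rate (fragments per kb at unit library factor); defaults give a
#'   median-length region a mean count near 60, typical of meDIP-seq peak
#'   depth.
#' @param region_len_meanlog,region_len_sdlog log-normal parameters of region
#'   lengths (defaults give a ~465 bp median, matching observed DMR sizes).
#' @param chrom_lengths named vector of chromosome lengths including one sex
#'   chromosome.
#' @param sex_chrom name of the sex chromosome.
#' @param sex_chrom_effect log2 female-vs-male baseline shift on the sex
#'   chromosome (default 1: two X copies in females).
#' @param n_genes number of autosomal genes in the synthetic annotation.
#' @param frag_len sequenced fragment length (default 300 bp).
#' @param jitter_bp peak boundary jitter (default 30 bp).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_per_cell = 5, n_batches = 2,
                       n_regions = 5000, nb_dispersion = 0.1,
                       batch_effect = 0.5, effect_size = 1,
                       planted_frac = 0.1, dropout_prob = 0.05,
                       libsize_sd = 0.2,
                       rate_meanlog = log(120), rate_sdlog = 0.5,
                       region_len_meanlog = log(465),
                       region_len_sdlog = 0.4,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6,
                                         chr4 = 5e6, chrX = 1e6),
                       sex_chrom = "chrX", sex_chrom_effect = 1,
                       n_genes = 300, frag_len = 300, jitter_bp = 30) {
  if (n_per_cell < 1) abort("n_per_cell must be >= 1")
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1) abort("dropout_prob in [0,1]")
  if (!sex_chrom %in% names(chrom_lengths)) {
    abort("sex_chrom must be one of the chromosomes")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the sample design table
#'
#' Fully crossed groups x sexes with `n_per_cell` animals each. Litters are
#' assigned so that no litter contributes more than one male and one female
#' (female i and male i of the same enumeration share litter i). Batches are
#' interleaved within each group x sex cell, keeping batch near-balanced and
#' unconfounded with the biology.
#'
#' @param n_per_cell animals per group x sex cell.
#' @param n_batches number of batches.
#' @param seed integer seed.
#' @return data frame: `sample_id`, `group`, `sex`, `batch`, `litter`.
#' @export
generate_design <- function(n_per_cell = 5, n_batches = 2, seed = 1) {
  if (n_per_cell < 1) abort("n_per_cell must be >= 1")
  set.seed(spawn_seed(seed, "design"))
  groups <- c("CON", "PF", "PAE")
  sexes <- c("F", "M")
  grid <- expand.grid(idx = seq_len(n_per_cell), group = groups, sex = sexes,
                      stringsAsFactors = FALSE)
  # litter i is shared by at most one female and one male (possibly of
  # different groups), never two animals of the same sex
  n_litters <- 3 * n_per_cell
  litter_of <- function(sex) sample(seq_len(n_litters))
  lit_f <- litter_of("F")
  lit_m <- litter_of("M")
  within_cell_rank <- stats::ave(seq_len(nrow(grid)),
                                 grid$group, grid$sex, FUN = seq_along)
  design <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(grid))),
    group = grid$group,
    sex = grid$sex,
    batch = paste0("B", (within_cell_rank - 1) %% n_batches + 1),
    litter = paste0("L", ifelse(
      grid$sex == "F",
      lit_f[(match(grid$group, groups) - 1) * n_per_cell + grid$idx],
      lit_m[(match(grid$group, groups) - 1) * n_per_cell + grid$idx]
    )),
    stringsAsFactors = FALSE
  )
  design
}

#' Generate a synthetic genome annotation
#'
#' Genes are laid out on non-overlapping autosomal slots; each gene body is
#' partitioned exactly into alternating exons and introns (no overlap, full
#' coverage). Promoters are `[TSS-200, TSS)` and `[TSS-1500, TSS)` on the
#' coding strand (mirrored for minus-strand genes), UTRs sit at the ends of
#' the terminal exons, and CpG islands are placed at half the promoters plus
#' at random autosomal positions.
#'
#' @param config a `sim_config`.
#' @return named list of `interval_set`s: `genes`, `exons`, `introns`,
#'   `promoter200`, `promoter1500`, `utr5`, `utr3`, `cpg_islands`.
#' @export
generate_genome_annotation <- function(config) {
  set.seed(spawn_seed(config$seed, "genome"))
  autos <- setdiff(names(config$chrom_lengths), config$sex_chrom)
  lens <- config$chrom_lengths[autos]
  n_genes <- config$n_genes
  if (n_genes == 0) {
    empty <- interval_set()
    return(list(genes = empty, exons = empty, introns = empty,
                promoter200 = empty, promoter1500 = empty, utr5 = empty,
                utr3 = empty,
                cpg_islands = random_islands(config, 50)))
  }
  per_chrom <- pmax(round(n_genes * lens / sum(lens)), 1L)
  # trim rounding overshoot
  while (sum(per_chrom) > n_genes) {
    per_chrom[which.max(per_chrom)] <- per_chrom[which.max(per_chrom)] - 1L
  }
  rows <- list()
  gi <- 0L
  for (ch in autos) {
    k <- per_chrom[[ch]]
    if (k == 0) next
    slot <- floor(lens[[ch]] / k)
    if (slot < 12000) abort("chromosome ", ch, " too short for ", k, " genes")
    for (j in seq_len(k)) {
      gi <- gi + 1L
      slot_start <- (j - 1) * slot
      glen <- sample(5000:min(20000, slot - 4000), 1)
      gstart <- slot_start + 2000 +
        sample.int(max(1, slot - glen - 4000), 1) - 1
      rows[[gi]] <- list(chrom = ch, start = gstart, end = gstart + glen,
                         gene = sprintf("gene_%03d", gi),
                         strand = sample(c("+", "-"), 1))
    }
  }
  genes <- do.call(rbind, lapply(rows, as.data.frame))
  ex <- list(); intr <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_ex <- sample(3:8, 1)
    k <- 2 * n_ex - 1
    w <- stats::rexp(k) + 0.2
    w <- pmax(50, floor(w / sum(w) * (g$end - g$start)))
    w[k] <- (g$end - g$start) - sum(w[-k]) # exact partition
    if (w[k] < 50) { w[1] <- w[1] + w[k] - 50; w[k] <- 50 }
    bounds <- g$start + cumsum(c(0, w))
    seg <- data.frame(chrom = g$chrom, start = bounds[-length(bounds)],
                      end = bounds[-1], gene = g$gene, strand = g$strand,
                      stringsAsFactors = FALSE)
    ex[[i]] <- seg[seq(1, k, by = 2), ]
    if (k > 1) intr[[i]] <- seg[seq(2, k, by = 2), ]
  }
  exons <- do.call(rbind, ex)
  introns <- do.call(rbind, intr)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  prom <- function(w) {
    data.frame(
      chrom = genes$chrom,
      start = ifelse(plus, tss - w, tss),
      end = ifelse(plus, tss, tss + w),
      gene = genes$gene, strand = genes$strand, stringsAsFactors = FALSE
    )
  }
  p200 <- prom(200)
  p1500 <- prom(1500)
  # UTRs: ends of the terminal exons, strand-aware
  first_ex <- exons[!duplicated(exons$gene), ]
  last_ex <- exons[rev(!duplicated(rev(exons$gene))), ]
  last_ex <- last_ex[match(first_ex$gene, last_ex$gene), ]
  fplus <- first_ex$strand == "+"
  u5 <- data.frame(
    chrom = first_ex$chrom,
    start = ifelse(fplus, first_ex$start, last_ex$end - 150),
    end = ifelse(fplus, first_ex$start + 150, last_ex$end),
    gene = first_ex$gene, stringsAsFactors = FALSE
  )
  u3 <- data.frame(
    chrom = first_ex$chrom,
    start = ifelse(fplus, last_ex$end - 150, first_ex$start),
    end = ifelse(fplus, last_ex$end, first_ex$start + 150),
    gene = first_ex$gene, stringsAsFactors = FALSE
  )
  mkset <- function(df, lab) {
    interval_set(df$chrom, df$start, df$end, name = df$gene,
                 strand = if ("strand" %in% names(df)) df$strand else NULL,
                 label = lab)
  }
  prom_islands <- which(stats::runif(nrow(genes)) < 0.5)
  cpg <- rbind(
    data.frame(chrom = genes$chrom[prom_islands],
               start = pmax(0, tss[prom_islands] - 500),
               end = tss[prom_islands] + 500, stringsAsFactors = FALSE),
    random_islands_df(config, 50)
  )
  list(
    genes = mkset(genes, "genes"),
    exons = mkset(exons, "exons"),
    introns = mkset(introns, "introns"),
    promoter200 = mkset(p200, "promoter200"),
    promoter1500 = mkset(p1500, "promoter1500"),
    utr5 = mkset(u5, "utr5"),
    utr3 = mkset(u3, "utr3"),
    cpg_islands = interval_set(cpg$chrom, cpg$start, cpg$end,
                               label = "cpg_islands")
  )
}

random_islands_df <- function(config, n) {
  autos <- setdiff(names(config$chrom_lengths), config$sex_chrom)
  ch <- sample(autos, n, replace = TRUE)
  len <- sample(500:2000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(config$chrom_lengths[[ch[i]]] - len[i], 1) - 1
  }, numeric(1))
  data.frame(chrom = ch, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

random_islands <- function(config, n) {
  df <- random_islands_df(config, n)
  interval_set(df$chrom, df$start, df$end, label = "cpg_islands")
}

#' Generate consensus-sized regions, their count matrix and the truth table
#'
#' Regions are placed on per-chromosome grids (guaranteeing non-overlap) with
#' log-normal lengths. Counts are negative-binomial with mean
#' `mu_rs = rate_r * length_r/1000 * libfactor_s * 2^(batch + planted
#' effects)` and common dispersion. Planted regions are autosomal, assigned
#' round-robin across every tier x category x direction cell; sex-chromosome
#' regions carry a female-vs-male baseline shift instead (a tripwire for the
#' sex-chromosome-removal step).
#'
#' @param design design table from [generate_design()].
#' @param config a `sim_config`.
#' @return list: `regions` (`consensus_regions`), `counts` (matrix with
#'   `lib_sizes` / `region_lengths` attributes), `truth` (data frame:
#'   `region_id`, `tier`, `category`, `direction`, `effect`).
#' @export
generate_regions_counts <- function(design, config) {
  set.seed(spawn_seed(config$seed, "regions"))
  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths
  n_per <- pmax(round(config$n_regions * lens / sum(lens)), 1L)
  while (sum(n_per) > config$n_regions) {
    n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
  }
  while (sum(n_per) < config$n_regions) {
    n_per[which.max(lens)] <- n_per[which.max(lens)] + 1L
  }
  reg <- list()
  for (ch in chroms) {
    k <- n_per[[ch]]
    bin <- floor(lens[[ch]] / k)
    rl <- pmin(pmax(round(stats::rlnorm(k, config$region_len_meanlog,
                                        config$region_len_sdlog)), 250),
               min(3000, bin - 10))
    offset <- vapply(seq_len(k), function(i) {
      sample.int(bin - rl[i], 1) - 1
    }, numeric(1))
    start <- (seq_len(k) - 1) * bin + offset
    reg[[ch]] <- data.frame(chrom = ch, start = start, end = start + rl,
                            stringsAsFactors = FALSE)
  }
  regdf <- do.call(rbind, reg)
  regdf <- regdf[order(regdf$chrom, regdf$start), ]
  regdf$region_id <- sprintf("region_%05d", seq_len(nrow(regdf)))
  regions <- as_consensus_regions(regdf)

  # truth: planted cells, autosomal regions only
  autosomal <- regions$region_id[regions$chrom != config$sex_chrom]
  n_plant <- round(config$planted_frac * config$n_regions)
  n_plant <- min(n_plant, length(autosomal))
  cells <- expand.grid(
    tier = c("concordant", "female", "male"),
    category = c("PAE_specific", "PF_specific", "shared"),
    direction = c("up", "down"),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    region_id = regions$region_id,
    tier = NA_character_, category = "none", direction = NA_character_,
    effect = 0, stringsAsFactors = FALSE
  )
  if (config$effect_size != 0 && n_plant > 0) {
    planted_ids <- sample(autosomal, n_plant)
    cell_idx <- rep(seq_len(nrow(cells)), length.out = n_plant)
    i <- match(planted_ids, truth$region_id)
    truth$tier[i] <- cells$tier[cell_idx]
    truth$category[i] <- cells$category[cell_idx]
    truth$direction[i] <- cells$direction[cell_idx]
    truth$effect[i] <- ifelse(cells$direction[cell_idx] == "up", 1, -1) *
      config$effect_size
  }

  set.seed(spawn_seed(config$seed, "counts"))
  g <- nrow(regions)
  n <- nrow(design)
  rate <- stats::rlnorm(g, config$rate_meanlog, config$rate_sdlog)
  libf <- stats::rlnorm(n, 0, config$libsize_sd)
  lenkb <- (regions$end - regions$start) / 1000
  log2mu <- matrix(log2(rate * lenkb), g, n) +
    matrix(log2(libf), g, n, byrow = TRUE)
  batch_idx <- as.integer(sub("^B", "", design$batch))
  log2mu <- log2mu + matrix(config$batch_effect * (batch_idx - 1),
                            g, n, byrow = TRUE)
  on_x <- regions$chrom == config$sex_chrom
  log2mu[on_x, design$sex == "F"] <-
    log2mu[on_x, design$sex == "F"] + config$sex_chrom_effect
  planted <- which(truth$category != "none")
  for (r in planted) {
    tgt_groups <- switch(truth$category[r],
      PAE_specific = "PAE", PF_specific = "PF", shared = c("PAE", "PF")
    )
    sel <- design$group %in% tgt_groups
    if (truth$tier[r] == "female") sel <- sel & design$sex == "F"
    if (truth$tier[r] == "male") sel <- sel & design$sex == "M"
    log2mu[r, sel] <- log2mu[r, sel] + truth$effect[r]
  }
  mu <- 2^log2mu
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(g * n, mu = mu, size = 1 / config$nb_dispersion),
           g, n)
  } else {
    matrix(stats::rpois(g * n, lambda = mu), g, n)
  }
  dimnames(counts) <- list(regions$region_id, design$sample_id)
  attr(counts, "lib_sizes") <- stats::setNames(
    pmax(colSums(counts), 1), design$sample_id
  )
  attr(counts, "region_lengths") <- stats::setNames(
    regions$end - regions$start, regions$region_id
  )
  list(regions = regions, counts = counts, truth = truth)
}

#' Generate per-sample peaksets and fragment sets
#'
#' Each sample's peakset is the true region set with independent boundary
#' jitter, with each peak dropped independently with probability
#' `dropout_prob`. Fragments are placed with their start base uniformly
#' inside the region, `counts[r, s]` fragments per region, so counting
#' fragments by their start base reproduces the count matrix exactly.
#'
#' @param regions `consensus_regions` table (non-overlapping).
#' @param design design table.
#' @param counts count matrix (regions x samples).
#' @param config a `sim_config`.
#' @return list with `peaks` and `fragments`: named lists of `interval_set`
#'   per sample.
#' @export
generate_peaksets_fragments <- function(regions, design, counts, config) {
  set.seed(spawn_seed(config$seed, "peaks"))
  peaks <- list()
  j <- config$jitter_bp
  gaps <- region_gaps(regions)
  for (s in design$sample_id) {
    keep <- stats::runif(nrow(regions)) >= config$dropout_prob
    if (!any(keep)) {
      peaks[[s]] <- interval_set(label = s)
      next
    }
    r <- regions[keep, , drop = FALSE]
    dj <- pmin(j, floor(pmin(gaps$left[keep], r$end - r$start) / 2 - 1))
    dj <- pmax(dj, 0)
    ej <- pmin(j, floor(pmin(gaps$right[keep], r$end - r$start) / 2 - 1))
    ej <- pmax(ej, 0)
    ns <- r$start - round(stats::runif(nrow(r), 0, dj))
    ne <- r$end + round(stats::runif(nrow(r), 0, ej))
    peaks[[s]] <- interval_set(r$chrom, pmax(0, ns), ne, label = s)
  }
  set.seed(spawn_seed(config$seed, "fragments"))
  fragments <- list()
  for (s in design$sample_id) {
    cts <- counts[, s]
    tot <- sum(cts)
    if (tot == 0) {
      fragments[[s]] <- interval_set(label = s)
      next
    }
    ridx <- rep(seq_len(nrow(regions)), cts)
    rl <- (regions$end - regions$start)[ridx]
    starts <- regions$start[ridx] + floor(stats::runif(tot) * rl)
    fragments[[s]] <- interval_set(
      regions$chrom[ridx], starts, starts + config$frag_len, label = s
    )
  }
  list(peaks = peaks, fragments = fragments)
}

# distance to the previous/next region on the same chromosome (jitter must
# not make neighboring peaks overlap, which would merge true regions)
region_gaps <- function(regions) {
  n <- nrow(regions)
  left <- rep(Inf, n)
  right <- rep(Inf, n)
  same_prev <- c(FALSE, regions$chrom[-1] == regions$chrom[-n])
  gaps <- c(NA, regions$start[-1] - regions$end[-n])
  left[same_prev] <- gaps[same_prev]
  right[c(same_prev[-1], FALSE)] <- gaps[same_prev]
  list(left = left, right = right)
}

#' Generate gene sets with one planted high-scoring set
#'
#' Random sets drawn from the gene universe with sizes within the GSR
#' bounds, plus one designated set (`set_planted`) in which at least 80% of
#' members are genes hosting planted DMRs.
#'
#' @param gene_ids universe of gene ids (>= 10).
#' @param planted_genes genes hosting planted DMRs (may be empty; the
#'   planted set is then omitted).
#' @param n_sets number of random sets (default 20).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds (defaults 2 and 2000).
#' @return data frame `set_id`, `gene_id`; attribute `planted_set` names the
#'   planted set (or `NA`).
#' @export
generate_gene_sets <- function(gene_ids, planted_genes = character(),
                               n_sets = 20, seed = 1, min_size = 2,
                               max_size = 2000) {
  if (length(gene_ids) < 10) abort("need >= 10 genes")
  set.seed(spawn_seed(seed, "genesets"))
  sizes <- sample(min_size:min(max_size, max(min_size, 40),
                               length(gene_ids)), n_sets, replace = TRUE)
  out <- do.call(rbind, lapply(seq_len(n_sets), function(i) {
    data.frame(set_id = sprintf("set_%02d", i),
               gene_id = sample(gene_ids, sizes[i]),
               stringsAsFactors = FALSE)
  }))
  planted_id <- NA_character_
  planted_genes <- intersect(planted_genes, gene_ids)
  if (length(planted_genes) >= 2) {
    sz <- min(20, length(planted_genes))
    n_pl <- ceiling(0.9 * sz)
    members <- sample(planted_genes, n_pl)
    filler <- setdiff(gene_ids, members)
    if (sz > n_pl && length(filler)) {
      members <- c(members, sample(filler, min(sz - n_pl, length(filler))))
    }
    planted_id <- "set_planted"
    out <- rbind(out, data.frame(set_id = planted_id, gene_id = members,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "planted_set") <- planted_id
  out
}

#' Simulate a complete synthetic study
#'
#' One call generating everything downstream stages need: design, genome
#' annotation, regions, counts, truth table, and gene sets (with the planted
#' set built from genes hosting planted DMRs). Identical seeds and configs
#' give byte-identical results.
#'
#' @param config a `sim_config`.
#' @param with_reads also generate per-sample peaksets and fragment sets
#'   (memory-heavy at full size; default `FALSE`).
#' @return list: `config`, `design`, `genome`, `regions`, `counts`, `truth`,
#'   `gene_sets`, and optionally `peaks` / `fragments`.
#' @export
simulate_study <- function(config = sim_config(), with_reads = FALSE) {
  design <- generate_design(config$n_per_cell, config$n_batches, config$seed)
  genome <- generate_genome_annotation(config)
  rc <- generate_regions_counts(design, config)
  planted <- rc$truth$region_id[rc$truth$category != "none"]
  planted_genes <- character()
  if (length(planted) && nrow(genome$genes) > 0) {
    pr <- rc$regions[rc$regions$region_id %in% planted, ]
    hits <- intersect_intervals(
      interval_set(pr$chrom, pr$start, pr$end), genome$genes
    )
    if (nrow(hits)) planted_genes <- unique(hits$name_b)
  }
  gene_sets <- if (nrow(genome$genes) >= 10) {
    generate_gene_sets(genome$genes$name, planted_genes, seed = config$seed)
  } else NULL
  out <- list(config = config, design = design, genome = genome,
              regions = rc$regions, counts = rc$counts, truth = rc$truth,
              gene_sets = gene_sets)
  if (with_reads) {
    pf <- generate_peaksets_fragments(rc$regions, design, rc$counts, config)
    out$peaks <- pf$peaks
    out$fragments <- pf$fragments
  }
  out
}
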