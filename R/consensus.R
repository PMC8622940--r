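#' Build consensus regions from per-sample peaksets
#'
#' Pools the peaks of all samples, merges them by single-linkage union
#' (any two peaks sharing >= 1 base are combined, DiffBind-style), computes
#' each merged region's support as the number of distinct samples
#' contributing at least one overlapping peak, and drops regions supported by
#' fewer than `min_samples` samples.
#'
#' @param peaksets named list of `interval_set`, one per sample.
#' @param min_samples minimum number of supporting samples (default 3).
#' @return a data frame of class `consensus_regions` with columns
#'   `region_id`, `chrom`, `start`, `end`, `support`, sorted and
#'   non-overlapping.
#' @export
build_consensus <- function(peaksets, min_samples = 3) {
  if (length(peaksets) < 1) abort("at least one peakset is required")
  if (min_samples < 1) abort("min_samples must be >= 1")
  if (is.null(names(peaksets))) {
    names(peaksets) <- paste0("sample", seq_along(peaksets))
  }
  nonempty <- vapply(peaksets, nrow, 0L) > 0
  if (!any(nonempty)) {
    return(new_consensus(interval_set(), integer()))
  }
  pooled <- do.call(rbind, lapply(which(nonempty), function(i) {
    data.frame(chrom = peaksets[[i]]$chrom, start = peaksets[[i]]$start,
               end = peaksets[[i]]$end, sample = names(peaksets)[i],
               stringsAsFactors = FALSE)
  }))
  pooled_set <- interval_set(pooled$chrom, pooled$start, pooled$end)
  merged <- merge_overlapping(pooled_set)
  hits <- GenomicRanges::findOverlaps(
    as_granges(interval_set(pooled$chrom, pooled$start, pooled$end)),
    as_granges(merged), minoverlap = 1L, ignore.strand = TRUE
  )
  # pooled rows were re-sorted inside interval_set(); rebuild sample labels
  ord <- order(pooled$chrom, pooled$start, pooled$end)
  samp_sorted <- pooled$sample[ord]
  support <- tapply(
    samp_sorted[S4Vectors::queryHits(hits)],
    S4Vectors::subjectHits(hits),
    function(s) length(unique(s))
  )
  supp <- integer(nrow(merged))
  supp[as.integer(names(support))] <- as.integer(support)
  keep <- supp >= min_samples
  new_consensus(merged[keep, , drop = FALSE], supp[keep])
}

new_consensus <- function(set, support) {
  df <- data.frame(
    region_id = if (nrow(set)) sprintf("region_%05d", seq_len(nrow(set))) else character(),
    chrom = set$chrom, start = set$start, end = set$end,
    support = support, stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("consensus_regions", "data.frame")
  df
}

#' Coerce a region table to consensus_regions
#'
#' Accepts any data frame with `chrom`, `start`, `end` (non-overlapping) and
#' optional `region_id` / `support` columns; used when regions come from a
#' simulator or an external file rather than [build_consensus()].
#'
#' @param df region table.
#' @return a `consensus_regions` data frame.
#' @export
as_consensus_regions <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  out <- data.frame(
    region_id = if ("region_id" %in% names(df)) df$region_id else
      sprintf("region_%05d", seq_len(nrow(df))),
    chrom = as.character(df$chrom), start = df$start, end = df$end,
    support = if ("support" %in% names(df)) df$support else NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  if (anyDuplicated(out$region_id)) abort("region_ids must be unique")
  rownames(out) <- NULL
  class(out) <- c("consensus_regions", "data.frame")
  out
}

#' Remove sex-chromosome regions
#'
#' @param regions a `consensus_regions` table.
#' @param sex_chroms chromosome names to drop (default `c("chrX", "chrY")`).
#' @return the filtered table; other regions untouched.
#' @export
remove_sex_chromosomes <- function(regions, sex_chroms = c("chrX", "chrY")) {
  out <- regions[!regions$chrom %in% sex_chroms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count fragments per consensus region
#'
#' A fragment is assigned to the region containing its start base, so each
#' fragment is counted at most once even when it spans a region boundary.
#' Library size of a sample is its total fragment count (all fragments, not
#' only in-region ones), matching the per-million convention of RPKM.
#'
#' @param fragments named list of `interval_set`, one per sample, in the
#'   design's sample order.
#' @param regions a `consensus_regions` table (non-overlapping).
#' @return an integer matrix (regions x samples) with `region_id` rownames,
#'   carrying a `lib_sizes` attribute (named numeric) and a `region_lengths`
#'   attribute (bp per region).
#' @export
count_fragments <- function(fragments, regions) {
  if (is.null(names(fragments))) abort("fragments list must be named by sample")
  rgr <- as_granges(regions)
  mat <- matrix(0L, nrow = nrow(regions), ncol = length(fragments),
                dimnames = list(regions$region_id, names(fragments)))
  lib <- numeric(length(fragments))
  names(lib) <- names(fragments)
  for (s in names(fragments)) {
    fr <- fragments[[s]]
    lib[s] <- nrow(fr)
    if (nrow(fr) == 0) next
    starts <- GenomicRanges::GRanges(
      seqnames = fr$chrom,
      ranges = IRanges::IRanges(start = fr$start + 1, width = 1)
    )
    hits <- GenomicRanges::findOverlaps(starts, rgr, ignore.strand = TRUE)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(regions))
    mat[, s] <- as.integer(tab)
  }
  attr(mat, "lib_sizes") <- lib
  attr(mat, "region_lengths") <- stats::setNames(
    regions$end - regions$start, regions$region_id
  )
  mat
}

#' Write a count matrix (and its library sizes) to TSV
#'
#' @param counts matrix from [count_fragments()].
#' @param path counts TSV path; library sizes go to `paste0(path, ".libsizes")`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(region_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- attr(counts, "lib_sizes")
  if (!is.null(lib)) {
    utils::write.table(
      data.frame(sample_id = names(lib), lib_size = lib),
      paste0(path, ".libsizes"), sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
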