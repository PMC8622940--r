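#' Genomic interval sets
#'
#' An `interval_set` is a data frame with columns `chrom`, `start`, `end`
#' (0-based half-open, the BED convention) and optional `name` and `strand`
#' columns, normalized so rows are sorted by `(chrom, start, end)`. It is the
#' atom shared by peaks, consensus regions, sequenced fragments and genomic
#' feature annotations.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` per interval.
#' @param name optional character vector (e.g. gene ids).
#' @param strand optional character vector in `{"+", "-", "."}`.
#' @param label free-text source tag kept as an attribute.
#' @return a data frame of class `interval_set`, sorted.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NULL, strand = NULL,
                         label = NA_character_) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    abort("chrom, start and end must have equal length")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) abort("non-integer coordinates")
  if (any(start < 0)) abort("negative start coordinate")
  if (any(start >= end)) abort("start must be < end for every interval")
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) abort("strand must be +, - or .")
    df$strand <- as.character(strand)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  attr(df, "label") <- label
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "interval_set '%s': %d intervals on %d chromosome(s)\n",
    attr(x, "label") %||% NA, nrow(x), length(unique(x$chrom))
  ))
  NextMethod()
}

#' @rdname interval_set
#' @param x object to test or coerce.
#' @export
is_interval_set <- function(x) inherits(x, "interval_set")

#' Convert an interval set to GRanges (1-based closed) and back
#'
#' Internal bridge to the GenomicRanges machinery used for merge, intersect
#' and overlap counting. BED `[start, end)` maps to `[start + 1, end]`.
#'
#' @keywords internal
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand == ".", "*", x$strand)
    } else "*"
  )
}

#' @keywords internal
granges_to_set <- function(gr, label = NA_character_) {
  interval_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    label = label
  )
}

#' Read a BED file into an interval_set
#'
#' Parses BED3/BED6 with the standard 0-based half-open convention. Lines
#' starting with `track`, `browser` or `#` are skipped. Malformed coordinates
#' (non-integer, or start >= end) raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param strip_chr_prefix if `TRUE`, a leading `"chr"` is removed from
#'   chromosome names at the boundary. Chromosome names are otherwise matched
#'   exactly downstream; no silent renaming is attempted.
#' @param label source tag; defaults to the file name.
#' @return an `interval_set`, sorted by `(chrom, start, end)`.
#' @export
read_bed <- function(path, strip_chr_prefix = FALSE, label = basename(path)) {
  if (!file.exists(path)) abort("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(interval_set(label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  # tolerate space-delimited files
  one <- lengths(fields) < 3
  fields[one] <- strsplit(lines[idx][one], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort("BED line ", idx[which(nf < 3)[1]], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) abort("BED line ", idx[bad[1]], ": non-integer coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    abort("BED line ", idx[bad[1]], ": requires 0 <= start < end")
  }
  if (strip_chr_prefix) chrom <- sub("^chr", "", chrom)
  name <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4) else NULL
  strand <- if (all(nf >= 6)) {
    s <- vapply(fields, `[[`, "", 6)
    ifelse(s %in% c("+", "-"), s, ".")
  } else NULL
  interval_set(chrom, start, end, name = name, strand = strand, label = label)
}

#' Write an interval_set as BED
#'
#' Emits BED3 (or BED6 when `name`/`strand` columns or extra score data are
#' present), tab-separated, no header.
#'
#' @param x an `interval_set` or compatible data frame.
#' @param path output path.
#' @param extra optional named list of extra columns appended after the BED6
#'   fields (e.g. consensus support).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = NULL) {
  out <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  if ("name" %in% names(x) || !is.null(extra) || "strand" %in% names(x)) {
    out$name <- if ("name" %in% names(x)) x$name else "."
    out$score <- 0
    out$strand <- if ("strand" %in% names(x)) x$strand else "."
  }
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals (single-linkage union)
#'
#' Intervals sharing at least one base are combined into their union.
#' Touching-but-not-overlapping intervals (`end == start` under the half-open
#' convention share no base) are deliberately not merged.
#'
#' @param x an `interval_set`.
#' @return an `interval_set` with non-overlapping intervals.
#' @export
merge_overlapping <- function(x) {
  if (nrow(x) == 0) return(x)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = 0L,
                              ignore.strand = TRUE)
  granges_to_set(gr, label = attr(x, "label"))
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals (one from each set) overlapping by at
#' least one base, with the overlap length `min(ends) - max(starts)`.
#'
#' @param a,b interval sets.
#' @return a data frame with one row per overlapping pair: `chrom`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `overlap_bp`, plus `name_a` /
#'   `name_b` when the inputs carry names.
#' @export
intersect_intervals <- function(a, b) {
  empty <- data.frame(
    chrom = character(), start_a = numeric(), end_a = numeric(),
    start_b = numeric(), end_b = numeric(), overlap_bp = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = 1L, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    chrom = a$chrom[i],
    start_a = a$start[i], end_a = a$end[i],
    start_b = b$start[j], end_b = b$end[j],
    overlap_bp = pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]),
    stringsAsFactors = FALSE
  )
  if ("name" %in% names(a)) out$name_a <- a$name[i]
  if ("name" %in% names(b)) out$name_b <- b$name[j]
  out
}

#' Serialize an intersect table to TSV
#'
#' @param tab output of [intersect_intervals()].
#' @param path output path.
#' @export
write_intersections <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
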