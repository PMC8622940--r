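# Independent brute-force oracles used to validate the interval, FDR and
# resampling machinery. Deliberately naive: per-base bitmaps, O(n^2) pair
# scans and literal step-up formulas, sharing no code with the package.

# single-linkage merge oracle: union-find over per-base coverage, so two
# intervals join a component iff they share at least one base (touching
# half-open intervals share none and stay separate)
bitmap_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    cover <- vector("list", max(sub$end)) # interval ids covering each base
    for (i in seq_len(n)) {
      for (b in (sub$start[i] + 1):sub$end[i]) {
        for (j in cover[[b]]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
        cover[[b]] <- c(cover[[b]], i)
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      out[[paste(ch, cc)]] <- data.frame(
        chrom = ch, start = min(sub$start[idx]), end = max(sub$end[idx]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all overlapping pairs with overlap length, by per-base intersection
bitmap_pairs <- function(a, b) {
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- length(intersect(seq(a$start[i], a$end[i] - 1),
                             seq(b$start[j], b$end[j] - 1)))
      if (ov > 0) {
        k <- k + 1
        rows[[k]] <- data.frame(
          chrom = a$chrom[i], start_a = a$start[i], end_a = a$end[i],
          start_b = b$start[j], end_b = b$end[j], overlap_bp = ov,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0) return(NULL)
  do.call(rbind, rows)
}

# literal BH step-up: q_i = min over j with p_(j) >= p_i of p_(j) * m / j
bh_bruteforce <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- vapply(seq_len(m), function(j) {
      if (ps[j] >= pi) ps[j] * m / j else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# random non-degenerate interval data frame on a tiny genome
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 500) {
  start <- sample.int(max_pos - 1, n, replace = TRUE) - 1
  len <- sample.int(60, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# canonical row order for comparing interval tables
sort_df <- function(df) {
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}
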