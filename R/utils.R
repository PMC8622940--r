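#' @keywords internal
"_PACKAGE"

#' Derive a per-stage random seed from a master seed
#'
#' Uses a counter-based linear-congruential step so that each named stage gets
#' an independent, reproducible seed and skipping one stage never shifts the
#' randomness consumed by another.
#'
#' @param master integer master seed.
#' @param stage stage name (one of the pipeline stage labels) or a
#'   non-negative integer counter.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
spawn_seed <- function(master, stage) {
  stages <- c(
    design = 1L, genome = 2L, regions = 3L, counts = 4L, peaks = 5L,
    fragments = 6L, genesets = 7L, consensus = 8L, normalize = 9L,
    differential = 10L, classify = 11L, enrich = 12L, gsr = 13L,
    overlap = 14L
  )
  k <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else {
    as.integer(stage)
  }
  m <- 2147483647 # 2^31 - 1, prime modulus
  as.integer((as.numeric(master) %% m * 48271 + 104729 * (k + 1)) %% m)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix; keeps call noise out of user errors
abort <- function(...) stop(..., call. = FALSE)
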