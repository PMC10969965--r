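# shared helpers (not exported)

.msg <- function(fmt, ...) message(sprintf(fmt, ...))

#' Round half away from zero
#'
#' Base `round()` rounds half to even; per-chromosome percentages are reported
#' in the conventional half-up style (81.25 -> 81.3), so modal percentages use
#' this helper. A tiny epsilon guards against binary representation of values
#' such as 83.35 stored fractionally below the half boundary.
#'
#' @param x numeric vector (assumed non-negative).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Natural (numeric-aware) ordering for chromosome identifiers: "chr2" before
# "chr10"; purely non-numeric ids fall back to lexicographic order.
.chromOrder <- function(ids) {
  if (!length(ids)) return(integer(0))
  num <- suppressWarnings(as.numeric(gsub("\\D", "", ids)))
  order(is.na(num), num, ids)
}

.reverseComplement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Empty alignment-hit table; the common currency of the mapper, the BLAST
# tabular reader, and the assignment operations.
.emptyHits <- function() {
  S4Vectors::DataFrame(
    query_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    identity = numeric(0), aln_length = integer(0)
  )
}

.checkFraction <- function(x, name, min_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x <= 1 && (if (min_open) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be a single value in %s1] (got %s)",
                 name, if (min_open) "(0, " else "[0, ",
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}
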