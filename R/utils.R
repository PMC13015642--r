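# Shared internal helpers: interval arithmetic on 0-based half-open
# coordinates, and small validation utilities. All in-memory coordinates in
# this package are 0-based half-open; conversion to 1-based happens only at
# the VCF boundary (io_formats).

# Overlap length between one interval and a set of intervals on one chrom.
# Vectorised over the first interval set; `bl` is a data frame with
# chrom/start/end. Returns logical: does row i of `x` overlap any bl row?
overlaps_any <- function(x_chrom, x_start, x_end, bl) {
  if (is.null(bl) || nrow(bl) == 0) {
    return(rep(FALSE, length(x_start)))
  }
  hit <- rep(FALSE, length(x_start))
  for (i in seq_len(nrow(bl))) {
    same <- x_chrom == bl$chrom[i]
    hit <- hit | (same & x_start < bl$end[i] & x_end > bl$start[i])
  }
  hit
}

# Pairwise overlap in bp between interval a and each row of `tbl` (same
# chrom assumed filtered already).
overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain columns: %s (missing: %s)",
      what, paste(cols, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

# Deterministic child seed derived from a parent seed and a stream label;
# keeps derived seeds positive and below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(
    coverage = 11L, snv = 23L, methyl = 37L, sv = 53L, hla = 71L,
    mix = 89L, events = 101L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}
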