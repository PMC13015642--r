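# Shared fixture builders: everything is generated in code at test time.

# A flat coverage track: one tibble row per bin.
make_coverage <- function(chroms = "chr1", n_bins = 100, depth = 30,
                          bin_bp = 1000) {
  purrr::map_dfr(chroms, function(ch) {
    s <- seq(0L, (n_bins - 1L) * bin_bp, by = bin_bp)
    tibble::tibble(
      chrom = ch, start = s, end = s + as.integer(bin_bp),
      depth = rep_len(depth, n_bins)
    )
  })
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal single-sample SNV VCF.
write_snv_vcf <- function(rows, format = "GT:DP:AF") {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"a\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"),
    rows
  ), ext = ".vcf")
}

# A bedMethyl line in the modkit-style 18-column dialect.
bedmethyl_line <- function(chrom, pos, n_mod, n_valid, haplotype = NULL) {
  pct <- if (n_valid > 0) 100 * n_mod / n_valid else 0
  base <- sprintf(
    "%s\t%d\t%d\tm\t%d\t+\t%d\t%d\t255,0,0\t%d\t%.2f\t%d\t%d\t0\t0\t0\t0\t0",
    chrom, pos, pos + 1L, n_valid, pos, pos + 1L, n_valid, pct, n_mod,
    n_valid - n_mod
  )
  if (!is.null(haplotype)) base <- paste0(base, "\t", haplotype)
  base
}

# Methylation window track on a fixed grid from a vector of fractions.
make_windows <- function(fractions, chrom = "chr1", window_bp = 10000,
                         n_valid = 100) {
  n <- length(fractions)
  tibble::tibble(
    chrom = chrom,
    start = seq(0L, (n - 1L) * window_bp, by = window_bp),
    end = seq(window_bp, n * window_bp, by = window_bp),
    n_valid = n_valid,
    n_modified = round(fractions * n_valid),
    fraction = fractions
  )
}

# Exhaustive minimum-SSE segmentation oracle: best placement of exactly k
# breakpoints (0 <= k <= 2) of a numeric series, by full enumeration.
exhaustive_breakpoints <- function(x, k) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 0) return(integer())
  if (k == 1) {
    best <- Inf; best_b <- NA
    for (b in 1:(n - 1)) {
      s <- sse(x[1:b]) + sse(x[(b + 1):n])
      if (s < best) { best <- s; best_b <- b }
    }
    return(best_b)
  }
  best <- Inf; best_b <- c(NA, NA)
  for (b1 in 1:(n - 2)) {
    left <- sse(x[1:b1])
    for (b2 in (b1 + 1):(n - 1)) {
      s <- left + sse(x[(b1 + 1):b2]) + sse(x[(b2 + 1):n])
      if (s < best) { best <- s; best_b <- c(b1, b2) }
    }
  }
  best_b
}

# Piecewise-constant series with steps at given bins (1-based breakpoint
# index: level changes after x[b]).
step_series <- function(n, breaks, levels, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bounds <- c(0, breaks, n)
  x <- unlist(purrr::map2(
    diff(bounds), levels,
    function(len, lv) rep(lv, len)
  ))
  x + stats::rnorm(n, 0, noise_sd)
}

# Breakpoints (bin indices) recovered by segment_ratio on a plain series.
binseg_breakpoints <- function(x, penalty, chrom = "chr1", bin_bp = 1000) {
  ratio <- tibble::tibble(
    chrom = chrom,
    start = seq(0L, (length(x) - 1L) * bin_bp, by = bin_bp),
    end = seq(bin_bp, length(x) * bin_bp, by = bin_bp),
    ratio = 2^x, log2_ratio = x
  )
  segs <- tidy(segment_ratio(ratio, min_segment_bp = 0, penalty = penalty))
  if (nrow(segs) < 2) return(integer())
  head(segs$end, -1) / bin_bp
}
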