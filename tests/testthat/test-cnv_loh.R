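test_that("ratio normalization centers a flat diploid genome at 1", {
  cov <- make_coverage(paste0("chr", 1:3), n_bins = 50, depth = 30)
  ratio <- normalize_ratio(cov, cov)
  expect_true(all(ratio$ratio == 1))
  expect_true(all(ratio$log2_ratio == 0))
})

test_that("a doubled chromosome yields ratio 2 there and 1 elsewhere", {
  chroms <- paste0("chr", 1:10)
  normal <- make_coverage(chroms, n_bins = 100, depth = 30)
  tumor <- normal
  tumor$depth[tumor$chrom == "chr5"] <- 60
  ratio <- normalize_ratio(tumor, normal)
  # medians: normal 30, tumor 30 (event covers < 50% of bins)
  expect_equal(unique(ratio$ratio[ratio$chrom == "chr5"]), 2)
  expect_equal(unique(ratio$ratio[ratio$chrom == "chr1"]), 1)
})

test_that("blacklisted and zero-normal-depth bins are removed", {
  cov <- make_coverage("chr1", n_bins = 10, depth = 30)
  normal <- cov
  normal$depth[3] <- 0
  bl <- tibble::tibble(chrom = "chr1", start = 5000L, end = 6000L)
  ratio <- normalize_ratio(cov, normal, blacklist = bl)
  expect_false(2000 %in% ratio$start) # zero normal depth
  expect_false(5000 %in% ratio$start) # blacklisted
  expect_equal(nrow(ratio), 8)
})

test_that("disjoint bin grids are rejected", {
  a <- make_coverage("chr1", n_bins = 10)
  b <- make_coverage("chr2", n_bins = 10)
  expect_error(normalize_ratio(a, b), "bin grid")
})

test_that("a noiseless step is segmented at the exact breakpoint", {
  x <- step_series(600, breaks = 300, levels = c(log2(1), log2(1.5)))
  bps <- binseg_breakpoints(x, penalty = 0.01)
  expect_equal(bps, 300)
  expect_equal(bps, unname(exhaustive_breakpoints(x, 1)))
})

test_that("a noisy step localizes within 3 bins across seeds", {
  for (seed in 1:5) {
    x <- step_series(600, breaks = 300, levels = c(0, log2(1.5)),
                     noise_sd = 0.1, seed = seed)
    bps <- binseg_breakpoints(x, penalty = 2)
    expect_equal(length(bps), 1)
    expect_lte(abs(bps - 300), 3)
    expect_equal(bps, unname(exhaustive_breakpoints(x, 1)))
  }
})

test_that("a constant track yields one segment per chromosome", {
  cov <- make_coverage(c("chr1", "chr2"), n_bins = 200, depth = 30)
  segs <- tidy(segment_ratio(normalize_ratio(cov, cov), min_segment_bp = 0))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_bins, c(200L, 200L))
  empty <- segment_ratio(normalize_ratio(cov[0, ], NULL))
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("binary segmentation matches the exhaustive-SSE oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(60:200, 1)
    k <- sample(0:2, 1)
    if (k == 0) {
      x <- step_series(n, breaks = integer(), levels = 0.2,
                       noise_sd = 0.08, seed = rep)
      expect_equal(binseg_breakpoints(x, penalty = 1.5), integer())
    } else {
      breaks <- sort(sample(seq(15, n - 15, by = 5), k))
      if (k == 2 && diff(breaks) < 12) breaks <- c(breaks[1], breaks[1] + 14)
      levels <- cumsum(c(0, sample(c(-1, 1), k, replace = TRUE) *
                           runif(k, 0.8, 1.5)))
      x <- step_series(n, breaks = breaks, levels = levels,
                       noise_sd = 0.08, seed = 100 + rep)
      bps <- binseg_breakpoints(x, penalty = 1.5)
      expect_equal(bps, unname(exhaustive_breakpoints(x, k)))
    }
  }
})

test_that("CNV calls apply the size floor, neutral suppression and calibration", {
  m <- purity_model(0.5)
  segs <- tibble::tibble(
    chrom = c("chr1", "chr2", "chr3"),
    start = 0L,
    end = c(50000L, 2000000L, 2000000L),
    n_bins = c(50L, 2000L, 2000L),
    mean_ratio = c(1.5, 1.0, 1.5),
    mean_log2 = log2(c(1.5, 1.0, 1.5))
  )
  calls <- call_cnv(segs, m)
  # 50 kb segment below the floor; neutral segment silent
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "chr3")
  expect_equal(calls$observed_cn, 3.0)
  expect_equal(calls$calibrated_cn, 4L)
  expect_equal(calls$cnv_type, "DUP")
})

test_that("every reported call is the argmin-residual copy state", {
  m <- purity_model(0.7)
  segs <- tibble::tibble(
    chrom = paste0("chr", 1:4), start = 0L, end = 2000000L, n_bins = 2000L,
    mean_ratio = c(0.65, 1.35, 1.7, 2.1),
    mean_log2 = log2(c(0.65, 1.35, 1.7, 2.1))
  )
  calls <- call_cnv(segs, m)
  for (i in seq_len(nrow(calls))) {
    resid <- abs(expected_observed_cn(m, 0:10) - calls$observed_cn[i])
    expect_equal(calls$calibrated_cn[i], which.min(resid) - 1L)
  }
})

test_that("LoH detection finds a planted block and respects purity limits", {
  m <- purity_model(0.7)
  set.seed(5)
  block_pos <- sort(sample(1000000:3000000, 200))
  flank_pos <- sort(sample(c(1:900000, 3100000:8000000), 400))
  mk_sites <- function(pos, af_fun) {
    d <- rep(30L, length(pos))
    tibble::tibble(
      chrom = "chr1", pos = pos, ref_allele = "A", alt_allele = "G",
      allele_fraction = af_fun(d), depth = d,
      genotype = "het", haplotype = "unphased", filter_pass = TRUE
    )
  }
  all_pos <- sort(c(block_pos, flank_pos))
  normal <- mk_sites(all_pos, function(d) rbinom(length(d), 30, 0.5) / 30)
  in_block <- all_pos %in% block_pos
  tumor_af <- ifelse(
    in_block,
    rbinom(length(all_pos), 30, expected_alt_fraction(m, 2, 2)) / 30,
    rbinom(length(all_pos), 30, 0.5) / 30
  )
  tumor <- mk_sites(all_pos, function(d) tumor_af)
  regions <- detect_loh(tumor, normal, m, min_sites = 25)
  expect_equal(nrow(regions), 1)
  expect_lte(abs(regions$start - min(block_pos)), 30000)
  expect_lte(abs(regions$end - max(block_pos)), 30000)
  expect_gte(regions$n_adjusted_hom_sites, 100)

  # the same evidence at 10% purity is inseparable from het noise
  m_low <- purity_model(0.1)
  tumor_low <- tumor
  tumor_low$allele_fraction <- ifelse(
    in_block,
    rbinom(length(all_pos), 30, expected_alt_fraction(m_low, 2, 2)) / 30,
    rbinom(length(all_pos), 30, 0.5) / 30
  )
  expect_equal(nrow(detect_loh(tumor_low, normal, m_low)), 0)
})

test_that("all-het samples and empty site sets give no LoH regions", {
  m <- purity_model(0.9)
  sites <- tibble::tibble(
    chrom = "chr1", pos = seq(1000L, 100000L, by = 1000L),
    ref_allele = "A", alt_allele = "G",
    allele_fraction = 0.5, depth = 30L, genotype = "het",
    haplotype = "unphased", filter_pass = TRUE
  )
  expect_equal(nrow(detect_loh(sites, sites, m)), 0)
  expect_warning(
    out <- detect_loh(sites[0, ], sites, m),
    "no shared"
  )
  expect_equal(nrow(out), 0)
})

test_that("truth matching uses an inclusive 70% truth-side overlap", {
  truth <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000000L)
  exact <- match_calls(truth, tibble::tibble(
    chrom = "chr1", start = 300000L, end = 1000000L
  ))
  expect_true(exact$matches$matched)
  expect_equal(exact$recall, 1.0)
  under <- match_calls(truth, tibble::tibble(
    chrom = "chr1", start = 400000L, end = 1000000L
  ))
  expect_false(under$matches$matched)
  expect_equal(under$recall, 0)
  ident <- match_calls(truth, truth)
  expect_equal(ident$recall, 1.0)
})

test_that("no CNV or LoH call crosses a chromosome boundary", {
  g <- genome_spec(4, 3e6)
  tr <- plant_events(g, n_cnv = 2, n_loh = 1, n_dmr = 0, n_sv = 0,
                     n_hla_loh = 0, cnv_bp = 1e6, loh_bp = 1e6, seed = 8)
  pair <- simulate_pair(tr, purity_model(0.8), g, seed = 8)
  segs <- segment_ratio(normalize_ratio(pair$tumor$coverage, pair$normal$coverage))
  calls <- call_cnv(segs, purity_model(0.8))
  lohs <- detect_loh(pair$tumor$snvs, pair$normal$snvs, purity_model(0.8))
  lens <- tibble::deframe(g)
  for (tbl in list(calls, lohs)) {
    if (nrow(tbl) == 0) next
    expect_true(all(tbl$end <= lens[tbl$chrom]))
    expect_true(all(tbl$start >= 0))
  }
})
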