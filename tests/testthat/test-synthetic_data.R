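small_genome <- function() genome_spec(4, 2e6)

test_that("simulation is reproducible under a seed and varies across seeds", {
  g <- small_genome()
  tr <- plant_events(g, n_cnv = 1, n_loh = 1, n_dmr = 2, n_sv = 3,
                     n_hla_loh = 1, cnv_bp = 5e5, loh_bp = 5e5, seed = 4)
  a <- simulate_pair(tr, purity_model(0.7), g, seed = 9)
  b <- simulate_pair(tr, purity_model(0.7), g, seed = 9)
  expect_identical(a$tumor$coverage, b$tumor$coverage)
  expect_identical(a$tumor$snvs, b$tumor$snvs)
  expect_identical(a$tumor$methyl, b$tumor$methyl)
  expect_identical(a$normal$hla, b$normal$hla)
  c <- simulate_pair(tr, purity_model(0.7), g, seed = 10)
  expect_false(identical(a$tumor$coverage$depth, c$tumor$coverage$depth))
})

test_that("an event-free pair is flat in coverage ratio and het VAF", {
  g <- genome_spec(2, 5e6) # 10 Mb
  pair <- simulate_pair(NULL, purity_model(0.8), g, seed = 21)
  ratio <- normalize_ratio(pair$tumor$coverage, pair$normal$coverage)
  seg_mean <- sum(ratio$tumor_norm) / sum(ratio$normal_norm)
  expect_lt(abs(seg_mean - 1), 0.05)
  expect_lt(abs(mean(pair$tumor$snvs$allele_fraction) - 0.5), 0.02)
  expect_lt(abs(mean(pair$normal$snvs$allele_fraction) - 0.5), 0.02)
})

test_that("a planted CN=4 event at half purity reads as a duplication ratio of 1.5", {
  g <- genome_spec(10, 2e6)
  tr <- tibble::tibble(
    kind = "cnv", chrom = "chr3", start = 500000L, end = 1500000L, cn = 4
  )
  pair <- simulate_pair(tr, purity_model(0.5), g, seed = 13)
  ratio <- normalize_ratio(pair$tumor$coverage, pair$normal$coverage)
  inside <- ratio$chrom == "chr3" & ratio$start >= 5e5 & ratio$end <= 15e5
  est <- sum(ratio$tumor_norm[inside]) / sum(ratio$normal_norm[inside])
  expect_lt(abs(est - 1.5), 0.05)
})

test_that("overlapping same-kind truth events are rejected", {
  tr <- tibble::tibble(
    kind = "cnv", chrom = "chr1",
    start = c(0L, 100000L), end = c(200000L, 400000L), cn = c(3, 4)
  )
  expect_error(
    simulate_pair(tr, purity_model(0.9), small_genome(), seed = 1),
    "overlapping"
  )
})

test_that("titration mixing is exact at the endpoints", {
  g <- small_genome()
  pair <- simulate_pair(NULL, purity_model(1.0), g, seed = 2)
  expect_identical(mix_titration(pair$tumor, pair$normal, 1), pair$tumor)
  expect_identical(mix_titration(pair$tumor, pair$normal, 0), pair$normal)
  expect_error(mix_titration(pair$tumor, pair$normal, 1.5), "alpha")
})

test_that("a half mixture over a CN=4 event implies an observed CN near 3", {
  g <- genome_spec(10, 2e6)
  tr <- tibble::tibble(
    kind = "cnv", chrom = "chr2", start = 500000L, end = 1500000L, cn = 4
  )
  pair <- simulate_pair(tr, purity_model(1.0), g, seed = 17)
  mix <- mix_titration(pair$tumor, pair$normal, 0.5, seed = 17)
  ratio <- normalize_ratio(mix$coverage, pair$normal$coverage)
  inside <- ratio$chrom == "chr2" & ratio$start >= 5e5 & ratio$end <= 15e5
  est_cn <- 2 * sum(ratio$tumor_norm[inside]) / sum(ratio$normal_norm[inside])
  expect_lt(abs(est_cn - 3.0), 0.1)
})

test_that("mixing preserves count-level consistency of SNVs and methylation", {
  g <- small_genome()
  pair <- simulate_pair(NULL, purity_model(1.0), g, seed = 6)
  mix <- mix_titration(pair$tumor, pair$normal, 0.6, seed = 6)
  expect_true(all(mix$snvs$alt_count <= mix$snvs$depth))
  expect_true(all(mix$methyl$n_modified <= mix$methyl$n_valid))
  expect_equal(mix$purity, 0.6)
})

test_that("exported fixtures round-trip through the readers", {
  g <- small_genome()
  tr <- plant_events(g, n_cnv = 1, n_loh = 1, n_dmr = 2, n_sv = 3,
                     n_hla_loh = 1, cnv_bp = 5e5, loh_bp = 5e5, seed = 4)
  pair <- simulate_pair(tr, purity_model(0.7), g, seed = 4)
  out <- tempfile()
  paths <- export_fixture(pair$tumor, out, "t")

  cov <- read_coverage(paths[["coverage"]])
  expect_equal(cov$depth, pair$tumor$coverage$depth)
  expect_equal(cov$start, pair$tumor$coverage$start)

  snvs <- read_snvs(paths[["snv"]], min_allele_fraction = 0.1)
  kept <- pair$tumor$snvs[pair$tumor$snvs$allele_fraction > 0.1, ]
  expect_equal(snvs$pos, kept$pos)
  expect_equal(snvs$allele_fraction, kept$allele_fraction)

  methyl <- read_methyl_pileup(paths[["methyl"]])
  expect_equal(methyl$n_modified, pair$tumor$methyl$n_modified)
  expect_equal(methyl$n_valid, pair$tumor$methyl$n_valid)

  svs <- read_svs(paths[["sv"]])
  expect_equal(nrow(svs), nrow(pair$tumor$svs))
  expect_equal(sort(svs$length), sort(pair$tumor$svs$length))

  hla <- read_hla_counts(paths[["hla"]])
  expect_equal(hla$tumor_c1, pair$tumor$hla$tumor_c1)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$purity, 0.7)
  expect_equal(nrow(truth$events), nrow(tr))
  expect_setequal(
    truth$events$start[truth$events$kind == "cnv"],
    tr$start[tr$kind == "cnv"]
  )

  # empty truth still produces readable minimal files
  empty <- simulate_pair(NULL, purity_model(0.9), genome_spec(1, 2e5),
                         n_germline_sv = 0, seed = 5)
  p2 <- export_fixture(empty$tumor, tempfile(), "e")
  expect_equal(nrow(read_svs(p2[["sv"]])), 0)
  expect_gt(nrow(read_coverage(p2[["coverage"]])), 0)
})

test_that("expected mixture coverage is the convex combination of compartments", {
  g <- small_genome()
  tr <- tibble::tibble(
    kind = "cnv", chrom = "chr1", start = 500000L, end = 1500000L, cn = 4
  )
  pair <- simulate_pair(tr, purity_model(1.0), g, seed = 30)
  for (a in c(0.25, 0.5, 0.75)) {
    mix <- mix_titration(pair$tumor, pair$normal, a, seed = 30)
    expect_equal(
      mix$coverage$depth,
      a * pair$tumor$coverage$depth + (1 - a) * pair$normal$coverage$depth
    )
  }
})
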