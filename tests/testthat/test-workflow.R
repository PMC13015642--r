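# End-to-end workflow fixtures are simulated once per test file run.

paired_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- genome_spec(4, 5e6)
    tr <- plant_events(
      g, n_cnv = 2, n_loh = 1, n_dmr = 4, n_sv = 4, n_hla_loh = 1,
      cnv_bp = 1e6, loh_bp = 1e6, seed = 42
    )
    pair <- simulate_pair(tr, purity_model(0.9), g, seed = 42)
    dir <- tempfile("fixture_")
    t_paths <- export_fixture(pair$tumor, dir, "tumor")
    n_paths <- export_fixture(pair$normal, dir, "normal")
    cache <<- list(truth = tr, tumor = t_paths, normal = n_paths, pair = pair)
    cache
  }
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(run_config("paired", purity = 1.5, paths = list()), "purity")
  expect_error(run_config("paired", purity = 0, paths = list()), "purity")
  expect_error(run_config("paired", purity = 0.5, paths = list()), "requires paths")
  expect_error(
    run_config("tumor_only", purity = 0.5,
               paths = list(tumor_cov = tempfile(), normal_cov = tempfile())),
    "forbids"
  )
  expect_error(
    run_config("paired", purity = 0.5, paths = list(
      tumor_cov = "/nonexistent/a.bed", normal_cov = "/nonexistent/b.bed",
      tumor_snv = "/nonexistent/c.vcf", normal_snv = "/nonexistent/d.vcf"
    )),
    "not found"
  )
})

test_that("the paired workflow recovers planted events end to end", {
  fx <- paired_fixture()
  cfg <- run_config(
    "paired", purity = 0.9,
    paths = list(
      tumor_cov = fx$tumor[["coverage"]], normal_cov = fx$normal[["coverage"]],
      tumor_snv = fx$tumor[["snv"]], normal_snv = fx$normal[["snv"]],
      tumor_methyl = fx$tumor[["methyl"]], normal_methyl = fx$normal[["methyl"]],
      tumor_sv = fx$tumor[["sv"]], normal_sv = fx$normal[["sv"]],
      hla_counts = fx$tumor[["hla"]]
    ),
    out_dir = tempfile()
  )
  run <- run_paired(cfg)
  truth <- fx$truth
  cnv_truth <- truth[truth$kind == "cnv", ]
  expect_equal(match_calls(cnv_truth, run$results$cnvs)$recall, 1.0)
  loh_truth <- truth[truth$kind == "loh", ]
  expect_equal(match_calls(loh_truth, run$results$lohs)$recall, 1.0)
  expect_equal(nrow(run$results$somatic_svs), sum(truth$kind == "sv"))
  # planted DMR events are recovered (attenuated by purity 0.9): at least
  # one called window inside each clearly-supra-threshold event
  dmr_truth <- truth[truth$kind == "dmr" & abs(truth$delta_pp) * 0.9 >= 35, ]
  for (i in seq_len(nrow(dmr_truth))) {
    n_hit <- sum(
      run$results$dmrs$chrom == dmr_truth$chrom[i] &
        run$results$dmrs$start >= dmr_truth$start[i] &
        run$results$dmrs$end <= dmr_truth$end[i]
    )
    expect_gte(n_hit, 1)
  }
  # HLA-LoH called for the planted gene
  hla_truth <- truth$gene[truth$kind == "hla_loh"]
  hla_calls <- run$results$hla
  expect_true(all(
    hla_calls$classification[hla_calls$gene %in% hla_truth] %in%
      c("loh_allele1_lost", "loh_allele2_lost")
  ))
  expect_true(file.exists(run$files[["vcf"]]))
  # tidy/glance summaries agree with the bundle
  expect_equal(
    tidy(run)$n[tidy(run)$category == "cnvs"], nrow(run$results$cnvs)
  )
  expect_equal(glance(run)$n_loh, nrow(run$results$lohs))
})

test_that("identical tumor and normal inputs yield zero somatic calls", {
  fx <- paired_fixture()
  cfg <- run_config(
    "paired", purity = 0.9,
    paths = list(
      tumor_cov = fx$normal[["coverage"]], normal_cov = fx$normal[["coverage"]],
      tumor_snv = fx$normal[["snv"]], normal_snv = fx$normal[["snv"]],
      tumor_methyl = fx$normal[["methyl"]], normal_methyl = fx$normal[["methyl"]],
      tumor_sv = fx$normal[["sv"]], normal_sv = fx$normal[["sv"]]
    ),
    out_dir = tempfile()
  )
  run <- run_paired(cfg)
  expect_equal(nrow(run$results$cnvs), 0)
  expect_equal(nrow(run$results$lohs), 0)
  expect_equal(nrow(run$results$dmrs), 0)
  expect_equal(nrow(run$results$somatic_svs), 0)
})

test_that("the tumor-only workflow prioritizes large events and extremes", {
  g <- genome_spec(4, 5e6)
  tr <- dplyr::bind_rows(
    tibble::tibble(kind = "cnv", chrom = "chr1", start = 1000000L,
                   end = 3000000L, cn = 4),
    tibble::tibble(kind = "loh", chrom = "chr3", start = 1000000L,
                   end = 3000000L, retained_hap = "H1"),
    tibble::tibble(kind = "sv", chrom = "chr4", start = 2000000L,
                   end = 2005000L, sv_type = "DEL", sv_length = 5000L)
  )
  pair <- simulate_pair(tr, purity_model(0.9), g, seed = 77)
  dir <- tempfile()
  paths <- export_fixture(pair$tumor, dir, "t")
  cfg <- run_config(
    "tumor_only", purity = 0.9,
    paths = list(
      tumor_cov = paths[["coverage"]], tumor_snv = paths[["snv"]],
      tumor_methyl = paths[["methyl"]], tumor_sv = paths[["sv"]],
      population = paths[["population"]]
    ),
    out_dir = tempfile()
  )
  run <- run_tumor_only(cfg)
  # the 2 Mb planted events clear the 1 Mb tumor-only floor
  expect_gte(nrow(run$results$cnvs), 1)
  expect_true(any(run$results$cnvs$chrom == "chr1"))
  expect_false(any(run$results$cnvs$somatic)) # candidates, not somatic calls
  expect_gte(nrow(run$results$lohs), 1)
  expect_true(any(run$results$lohs$chrom == "chr3"))
  # only the population-absent SV is pseudo-somatic
  expect_equal(run$results$pseudo_somatic$pos, 2000000L)
  expect_true(all(c("high", "low", "intermediate") %in%
                    stats::na.omit(run$results$extreme$methyl_class)))
})

test_that("reports render deterministically with conserved tallies", {
  fx <- paired_fixture()
  cfg <- run_config(
    "paired", purity = 0.9,
    paths = list(
      tumor_cov = fx$tumor[["coverage"]], normal_cov = fx$normal[["coverage"]],
      tumor_snv = fx$tumor[["snv"]], normal_snv = fx$normal[["snv"]]
    ),
    out_dir = tempfile()
  )
  run <- run_paired(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  render_report(run, d1)
  render_report(run, d2)
  for (f in c("summary_counts.tsv", "per_chromosome.tsv", "report.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  per_chrom <- readr::read_tsv(file.path(d1, "per_chromosome.tsv"),
                               col_types = readr::cols())
  cnv_tally <- per_chrom[per_chrom$category == "cnvs", ]
  expect_equal(sum(cnv_tally$n), nrow(run$results$cnvs))
  idx <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(idx$counts$cnvs, nrow(run$results$cnvs))
  expect_equal(idx$mode, "paired")
})
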