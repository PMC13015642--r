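test_that("window summarization pools counts and applies the validity floor", {
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 5000L, 9000L, 12000L, 25000L),
    n_modified = c(3L, 0L, 7L, 10L, 0L),
    n_valid = c(10L, 5L, 7L, 10L, 0L)
  )
  win <- summarize_windows(sites, window_bp = 10000, min_valid = 5)
  # window 0: (3+0+7)/(10+5+7) pooled, not the mean of per-site fractions
  expect_equal(win$fraction[win$start == 0], 10 / 22)
  expect_equal(win$fraction[win$start == 10000], 1.0)
  expect_true(is.na(win$fraction[win$start == 20000]))
  # pure pooled arithmetic: (3 of 10) + (0 of 5) -> 3/15
  two <- summarize_windows(tibble::tibble(
    chrom = "chr1", pos = c(0L, 100L), n_modified = c(3L, 0L),
    n_valid = c(10L, 5L)
  ), min_valid = 5)
  expect_equal(two$fraction, 0.2)
})

test_that("cDMR calling is inclusive at the threshold and directional", {
  tumor <- make_windows(c(0.70, 0.50, 0.63, 0.10))
  control <- make_windows(c(0.30, 0.50, 0.30, 0.60))
  calls <- call_cdmr(tumor, control, threshold_pp = 33)
  expect_equal(nrow(calls), 3)
  hyper <- calls[calls$start == 0, ]
  expect_equal(hyper$direction, "hyper_in_tumor")
  expect_equal(hyper$difference_pp, 40)
  # exactly 33 pp is called ("at least" is inclusive)
  at_33 <- calls[calls$start == 20000, ]
  expect_equal(nrow(at_33), 1)
  expect_equal(at_33$difference_pp, 33)
  expect_equal(calls$direction[calls$start == 30000], "hypo_in_tumor")
})

test_that("cDMR calling of a track against itself is empty", {
  x <- make_windows(runif(50))
  expect_equal(nrow(call_cdmr(x, x)), 0)
})

test_that("swapping tumor and control flips direction and negates differences", {
  set.seed(31)
  tumor <- make_windows(runif(80))
  control <- make_windows(runif(80))
  ab <- call_cdmr(tumor, control)
  ba <- call_cdmr(control, tumor)
  expect_equal(nrow(ab), nrow(ba))
  j <- dplyr::inner_join(
    ab, ba,
    by = c("chrom", "start", "end"), suffix = c("_ab", "_ba")
  )
  expect_equal(j$difference_pp_ab, -j$difference_pp_ba)
  expect_true(all(
    (j$direction_ab == "hyper_in_tumor") == (j$direction_ba == "hypo_in_tumor")
  ))
})

test_that("threshold calibration finds the constructed crossing point", {
  n <- 10000
  base <- rep(0.4, n)
  other <- base
  # 45 windows at 33.5 pp and 15 windows at 32.5 pp: counts are 60 at
  # t = 32 and 45 at t = 33, so the mean per-pair count first drops to
  # <= 50 at t = 33
  other[1:45] <- base[1:45] + 0.335
  other[46:60] <- base[46:60] + 0.325
  cohort <- dplyr::bind_rows(
    dplyr::mutate(make_windows(base), sample = "n1"),
    dplyr::mutate(make_windows(other), sample = "n2")
  )
  expect_equal(calibrate_threshold(cohort, target_count = 50), 33L)
})

test_that("threshold calibration degenerate cohorts behave as specified", {
  x <- make_windows(runif(200, 0.3, 0.7))
  cohort <- dplyr::bind_rows(
    dplyr::mutate(x, sample = "a"),
    dplyr::mutate(x, sample = "b"),
    dplyr::mutate(x, sample = "c")
  )
  # identical samples: t = 0 counts every window, t = 1 counts none
  expect_equal(calibrate_threshold(cohort, target_count = 50), 1L)
  # target at least the window count: even t = 0 suffices
  expect_equal(calibrate_threshold(cohort, target_count = 200), 0L)
  expect_error(
    calibrate_threshold(dplyr::mutate(x, sample = "a")),
    "at least 2"
  )
})

test_that("threshold calibration is monotone in the target count", {
  set.seed(12)
  cohort <- purrr::map_dfr(1:4, function(i) {
    dplyr::mutate(make_windows(runif(500)), sample = paste0("n", i))
  })
  targets <- c(5, 20, 80, 200, 500)
  ths <- vapply(targets, function(t) calibrate_threshold(cohort, t), integer(1))
  expect_true(all(diff(ths) <= 0))
})

test_that("extreme-state classification uses inclusive cuts", {
  win <- make_windows(c(0.95, 0.90, 0.10, 0.104, 0.50, NA))
  cls <- classify_extreme(win)$methyl_class
  expect_equal(cls[1:5], c("high", "high", "low", "intermediate", "intermediate"))
  expect_true(is.na(cls[6]))
})

test_that("panel reference takes per-window medians with a sample floor", {
  mk <- function(fr, nm) dplyr::mutate(make_windows(fr), sample = nm)
  panel <- dplyr::bind_rows(
    mk(c(0.1, 0.2, NA), "a"), mk(c(0.2, 0.4, NA), "b"),
    mk(c(0.9, 0.6, NA), "c"), mk(c(NA, 0.8, 0.5), "d")
  )
  ref <- panel_reference(panel, min_samples = 3)
  expect_equal(ref$fraction[ref$start == 0], 0.2)  # odd count median
  expect_equal(ref$fraction[ref$start == 10000], 0.5) # even: mean of 0.4, 0.6
  expect_true(is.na(ref$fraction[ref$start == 20000])) # only 1 sample defined
  # identical samples reproduce any member
  same <- dplyr::bind_rows(mk(c(0.3, 0.6), "a"), mk(c(0.3, 0.6), "b"),
                           mk(c(0.3, 0.6), "c"))
  expect_equal(panel_reference(same)$fraction, c(0.3, 0.6))
})

test_that("constitutive regions are the all-sample intersection by direction", {
  call_of <- function(fr_t, fr_c) call_cdmr(make_windows(fr_t), make_windows(fr_c))
  s1 <- call_of(c(0.9, 0.9, 0.9), c(0.2, 0.2, 0.2))
  s2 <- call_of(c(0.9, 0.9, 0.2), c(0.2, 0.2, 0.2))
  s3 <- call_of(c(0.9, 0.9, 0.9), c(0.2, 0.65, 0.2))
  # window 0 hyper in all three; window 1 in two; window 2 in two
  out <- constitutive_regions(list(s1, s2, s3), "hyper_in_tumor")
  expect_equal(out$start, 0L)
  expect_equal(
    nrow(constitutive_regions(list(s1, s1[0, ]), "hyper_in_tumor")), 0
  )
  expect_error(constitutive_regions(list(), "hyper_in_tumor"), "empty")
})
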