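# Somatic CNV and LoH calling from binned coverage and SNV allele
# fractions. Coverage ratios are segmented by binary segmentation on the
# log2 scale; segments are converted to copy-number states through the
# purity mixture model; LoH regions are runs of germline-het sites whose
# tumor VAF has shifted into a purity-adjusted homozygous band.

#' Normalized tumor/normal coverage ratio per bin
#'
#' Each bin's ratio is (tumor depth / tumor genome-wide median) /
#' (normal depth / normal genome-wide median), so a flat diploid genome
#' sits at ratio 1. Blacklisted bins and bins with zero normal depth are
#' removed. In tumor-only mode (`normal = NULL`) the ratio is the tumor
#' depth over its own genome-wide median.
#'
#' @param tumor Coverage tibble from [read_coverage()].
#' @param normal Matching coverage tibble on the same bin grid, or NULL.
#' @param blacklist Optional tibble of intervals (`chrom`,`start`,`end`) to
#'   exclude.
#' @return Tibble `chrom`, `start`, `end`, `ratio`, `log2_ratio`.
#' @export
normalize_ratio <- function(tumor, normal = NULL, blacklist = NULL) {
  assert_columns(tumor, c("chrom", "start", "end", "depth"), "`tumor`")
  n_in <- nrow(tumor)
  if (n_in == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      tumor_norm = double(), normal_norm = double(),
      ratio = double(), log2_ratio = double()
    ))
  }
  if (!is.null(normal)) {
    assert_columns(normal, c("chrom", "start", "end", "depth"), "`normal`")
    if (nrow(tumor) != nrow(normal) ||
        !all(tumor$chrom == normal$chrom & tumor$start == normal$start &
               tumor$end == normal$end)) {
      abort("tumor and normal coverage tracks are not on the same bin grid")
    }
    t_med <- median(tumor$depth)
    n_med <- median(normal$depth)
    if (t_med <= 0 || n_med <= 0) abort("zero median depth; track unusable")
    keep <- normal$depth > 0
    out <- tibble(
      chrom = tumor$chrom[keep], start = tumor$start[keep], end = tumor$end[keep],
      tumor_norm = tumor$depth[keep] / t_med,
      normal_norm = normal$depth[keep] / n_med,
      ratio = (tumor$depth[keep] / t_med) / (normal$depth[keep] / n_med)
    )
  } else {
    t_med <- median(tumor$depth)
    if (t_med <= 0) abort("zero median depth; track unusable")
    keep <- tumor$depth > 0
    out <- tibble(
      chrom = tumor$chrom[keep], start = tumor$start[keep], end = tumor$end[keep],
      tumor_norm = tumor$depth[keep] / t_med,
      normal_norm = 1,
      ratio = tumor$depth[keep] / t_med
    )
  }
  bl_hit <- overlaps_any(out$chrom, out$start, out$end, blacklist)
  out <- out[!bl_hit, , drop = FALSE]
  if (nrow(out) < 0.5 * n_in) {
    warn("more than 50% of coverage bins removed during normalization")
  }
  mutate(out, log2_ratio = log2(.data$ratio))
}

# Best single split of x[lo..hi] (global indices): maximal SSE reduction.
# Vectorised via cumulative sums; returns list(k = split index so the left
# part is lo..k, gain = SSE reduction) or NULL when no split possible.
best_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  cs <- cumsum(x)
  tot <- cs[n]
  k <- seq_len(n - 1)
  n1 <- k
  n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (tot - cs[k]) / n2
  gain <- n1 * n2 / n * (m1 - m2)^2
  best <- which.max(gain)
  list(k = best, gain = gain[best])
}

segment_one <- function(x, penalty) {
  # returns sorted vector of breakpoints (index k means split after x[k])
  n <- length(x)
  if (n < 2) return(integer())
  stack <- list(c(1L, n))
  bps <- integer()
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1]; hi <- seg[2]
    sp <- best_split(x[lo:hi])
    if (is.null(sp) || sp$gain <= penalty) next
    k <- lo + sp$k - 1L
    bps <- c(bps, k)
    stack[[length(stack) + 1L]] <- c(lo, k)
    stack[[length(stack) + 1L]] <- c(k + 1L, hi)
  }
  sort(bps)
}

#' Segment a coverage-ratio track
#'
#' Recursive binary segmentation of log2(ratio) per chromosome: a split is
#' accepted only when the reduction in within-segment sum of squared
#' deviations exceeds `penalty`. Segments shorter than `min_segment_bp`
#' are merged into the neighboring segment with the nearest mean.
#'
#' @param ratio Tibble from [normalize_ratio()].
#' @param min_segment_bp Minimum reported segment span (default 100 kb).
#' @param penalty SSE-reduction acceptance penalty; default
#'   `10 * sigma^2` where `sigma` is the MAD estimate of the per-bin log2
#'   noise from bin-to-bin differences.
#' @return A `ratio_segments` tibble: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_ratio`, `mean_log2`.
#' @export
segment_ratio <- function(ratio, min_segment_bp = 100000, penalty = NULL) {
  if (nrow(ratio) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      n_bins = integer(), mean_ratio = double(), mean_log2 = double()
    )
    return(new_ratio_segments(out, penalty = NA_real_, sigma = NA_real_))
  }
  assert_columns(ratio, c("chrom", "start", "end", "log2_ratio"), "`ratio`")
  d <- diff(ratio$log2_ratio)
  sigma <- mad(d) / sqrt(2)
  if (is.null(penalty)) {
    penalty <- 10 * max(sigma, 1e-6)^2
  }
  segs <- ratio %>%
    group_by(.data$chrom) %>%
    dplyr::group_map(function(g, key) {
      x <- g$log2_ratio
      bps <- segment_one(x, penalty)
      bounds <- c(0L, bps, length(x))
      idx <- purrr::map2(
        bounds[-length(bounds)] + 1L, bounds[-1],
        function(a, b) a:b
      )
      has_norm <- all(c("tumor_norm", "normal_norm") %in% names(g))
      purrr::map_dfr(idx, function(ii) {
        tibble(
          chrom = key$chrom[[1]],
          start = g$start[ii[1]],
          end = g$end[ii[length(ii)]],
          n_bins = length(ii),
          # ratio of segment means: unbiased, unlike the mean of per-bin
          # ratios whose reciprocal-denominator skew inflates it
          mean_ratio = if (has_norm) {
            mean(g$tumor_norm[ii]) / mean(g$normal_norm[ii])
          } else {
            mean(g$ratio[ii])
          },
          sum_t = if (has_norm) sum(g$tumor_norm[ii]) else sum(g$ratio[ii]),
          sum_n = if (has_norm) sum(g$normal_norm[ii]) else length(ii),
          mean_log2 = mean(x[ii])
        )
      })
    }) %>%
    bind_rows()
  segs <- merge_short_segments(segs, min_segment_bp)
  segs <- segs[order(factor(segs$chrom, levels = unique(ratio$chrom)), segs$start), ]
  segs <- select(segs, -"sum_t", -"sum_n")
  new_ratio_segments(segs, penalty = penalty, sigma = sigma)
}

# Merge segments shorter than min_bp into the adjacent same-chromosome
# segment with the nearest mean, iterating shortest-first.
merge_short_segments <- function(segs, min_bp) {
  segs <- as.data.frame(segs)
  repeat {
    len <- segs$end - segs$start
    chroms <- segs$chrom
    short <- which(len < min_bp)
    # only mergeable if a same-chrom neighbor exists
    short <- short[vapply(short, function(i) {
      (i > 1 && chroms[i - 1] == chroms[i]) ||
        (i < nrow(segs) && chroms[i + 1] == chroms[i])
    }, TRUE)]
    if (length(short) == 0) break
    i <- short[which.min(len[short])]
    left_ok <- i > 1 && chroms[i - 1] == chroms[i]
    right_ok <- i < nrow(segs) && chroms[i + 1] == chroms[i]
    j <- if (left_ok && right_ok) {
      if (abs(segs$mean_log2[i - 1] - segs$mean_log2[i]) <=
            abs(segs$mean_log2[i + 1] - segs$mean_log2[i])) i - 1L else i + 1L
    } else if (left_ok) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    w_a <- segs$n_bins[a]; w_b <- segs$n_bins[b]
    segs$start[a] <- min(segs$start[a], segs$start[b])
    segs$end[a] <- max(segs$end[a], segs$end[b])
    segs$sum_t[a] <- segs$sum_t[a] + segs$sum_t[b]
    segs$sum_n[a] <- segs$sum_n[a] + segs$sum_n[b]
    segs$mean_ratio[a] <- segs$sum_t[a] / segs$sum_n[a]
    segs$mean_log2[a] <- (w_a * segs$mean_log2[a] + w_b * segs$mean_log2[b]) / (w_a + w_b)
    segs$n_bins[a] <- w_a + w_b
    segs <- segs[-b, , drop = FALSE]
  }
  as_tibble(segs)
}

new_ratio_segments <- function(tbl, penalty, sigma) {
  structure(
    tbl,
    class = c("ratio_segments", class(as_tibble(tbl))),
    penalty = penalty,
    sigma = sigma
  )
}

#' @export
tidy.ratio_segments <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @export
glance.ratio_segments <- function(x, ...) {
  tibble(
    n_segments = nrow(x),
    n_chromosomes = length(unique(x$chrom)),
    n_bins = sum(x$n_bins),
    penalty = attr(x, "penalty"),
    sigma = attr(x, "sigma")
  )
}

#' Call copy-number variants from ratio segments
#'
#' Converts each segment's mean ratio to an observed copy number
#' (`mean_ratio * normal_ploidy`), calibrates it through the purity model,
#' and reports DEL/DUP calls. Segments whose calibrated copy number equals
#' the normal ploidy, whose |log2 ratio| lies within `neutral_band`, or
#' whose span falls below `min_size_bp` are suppressed.
#'
#' @param segments A `ratio_segments` tibble from [segment_ratio()].
#' @param model A [purity_model()].
#' @param neutral_band Half-width of the copy-neutral |log2 ratio| band
#'   (default 0.1).
#' @param min_size_bp Minimum reported call span; 100 kb in paired mode,
#'   1 Mb for tumor-only prioritization.
#' @param somatic Flag recorded on emitted calls (default TRUE: calls from
#'   a tumor/normal ratio are somatic by construction).
#' @return Tibble `chrom`, `start`, `end`, `n_bins`, `observed_cn`,
#'   `calibrated_cn`, `cnv_type`, `somatic`.
#' @export
call_cnv <- function(segments, model, neutral_band = 0.1,
                     min_size_bp = 100000, somatic = TRUE) {
  stopifnot(inherits(model, "purity_model"))
  segs <- if (inherits(segments, "ratio_segments")) tidy(segments) else as_tibble(segments)
  if (nrow(segs) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_bins = integer(), observed_cn = double(), calibrated_cn = integer(),
      cnv_type = character(), somatic = logical()
    ))
  }
  segs <- segs %>%
    mutate(
      observed_cn = .data$mean_ratio * model$normal_ploidy,
      calibrated_cn = calibrate_tumor_cn(model, .data$observed_cn)
    )
  # adjacent segments calibrating to the same state are one event split by
  # a spurious breakpoint; merge them before applying the size floor
  run <- cumsum(
    c(TRUE, segs$chrom[-1] != segs$chrom[-nrow(segs)] |
        segs$calibrated_cn[-1] != segs$calibrated_cn[-nrow(segs)])
  )
  segs <- segs %>%
    mutate(.run = run) %>%
    group_by(.data$.run) %>%
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      observed_cn = sum(.data$observed_cn * .data$n_bins) / sum(.data$n_bins),
      mean_log2 = sum(.data$mean_log2 * .data$n_bins) / sum(.data$n_bins),
      calibrated_cn = .data$calibrated_cn[1],
      n_bins = sum(.data$n_bins),
      .groups = "drop"
    ) %>%
    select(-".run")
  segs %>%
    filter(
      .data$calibrated_cn != model$normal_ploidy,
      abs(.data$mean_log2) > neutral_band,
      .data$end - .data$start >= min_size_bp
    ) %>%
    mutate(
      cnv_type = dplyr::if_else(.data$calibrated_cn < model$normal_ploidy, "DEL", "DUP"),
      somatic = somatic
    ) %>%
    select(
      "chrom", "start", "end", "n_bins", "observed_cn", "calibrated_cn",
      "cnv_type", "somatic"
    )
}

#' Detect loss-of-heterozygosity regions from VAF shifts
#'
#' Germline-heterozygous sites (genotype het with normal allele fraction
#' in \[0.30, 0.70\]) are classified in the tumor against the
#' purity-adjusted VAF bands ([classify_site()]). Maximal per-chromosome
#' runs containing at least `min_sites` adjusted-homozygous sites with a
#' persistent-het fraction at most `max_het_frac` become LoH regions
#' spanning the first to last supporting site. Without a normal
#' (`normal_snvs = NULL`), tumor-only mode classifies all tumor sites and
#' applies a 1 Mb minimum span. Sex chromosomes are excluded by default.
#'
#' @param tumor_snvs SNV tibble for the tumor ([read_snvs()]).
#' @param normal_snvs Matched normal SNV tibble, or NULL for tumor-only.
#' @param model A [purity_model()].
#' @param min_sites Minimum adjusted-hom sites per region (default 25).
#' @param max_het_frac Maximum persistent-het fraction among counted sites
#'   (default 0.15).
#' @param min_size_bp Minimum region span; default 100 kb paired, forced
#'   to at least 1 Mb in tumor-only mode.
#' @param tolerance VAF band half-width for [classify_site()].
#' @param exclude_chroms Chromosomes never assessed (default chrX/chrY/X/Y).
#' @param cnv_calls Optional [call_cnv()] output used to populate each
#'   region's `concurrent_cn`.
#' @return Tibble `chrom`, `start`, `end`, `n_adjusted_hom_sites`,
#'   `n_persistent_het_sites`, `concurrent_cn`.
#' @export
detect_loh <- function(tumor_snvs, normal_snvs = NULL, model,
                       min_sites = 25, max_het_frac = 0.15,
                       min_size_bp = 100000, tolerance = 0.10,
                       exclude_chroms = c("chrX", "chrY", "X", "Y"),
                       cnv_calls = NULL) {
  stopifnot(inherits(model, "purity_model"))
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_adjusted_hom_sites = integer(), n_persistent_het_sites = integer(),
    concurrent_cn = integer()
  )
  if (is.null(normal_snvs)) {
    min_size_bp <- max(min_size_bp, 1000000)
    sites <- filter(tumor_snvs, !(.data$chrom %in% exclude_chroms))
  } else {
    normal_het <- filter(
      normal_snvs,
      .data$genotype == "het",
      .data$allele_fraction >= 0.30, .data$allele_fraction <= 0.70,
      !(.data$chrom %in% exclude_chroms)
    )
    sites <- semi_join(
      filter(tumor_snvs, !(.data$chrom %in% exclude_chroms)),
      normal_het,
      by = c("chrom", "pos")
    )
  }
  if (nrow(sites) == 0) {
    warn("no shared informative SNV sites; returning no LoH regions")
    return(empty)
  }
  sites <- classify_site(model, sites, tolerance = tolerance) %>%
    arrange(factor(.data$chrom, levels = unique(.data$chrom)), .data$pos)

  regions <- sites %>%
    group_by(.data$chrom) %>%
    dplyr::group_map(~ scan_loh_runs(.x, .y$chrom[[1]], min_sites, max_het_frac)) %>%
    bind_rows()
  if (nrow(regions) == 0) return(empty)
  regions <- filter(regions, .data$end - .data$start >= min_size_bp)
  if (nrow(regions) == 0) return(empty)
  regions$concurrent_cn <- NA_integer_
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    for (i in seq_len(nrow(regions))) {
      cand <- filter(cnv_calls, .data$chrom == regions$chrom[i])
      if (nrow(cand) == 0) next
      ov <- overlap_bp(regions$start[i], regions$end[i], cand$start, cand$end)
      if (max(ov) > 0) {
        regions$concurrent_cn[i] <- cand$calibrated_cn[which.max(ov)]
      }
    }
  }
  regions
}

# Scan one chromosome's classified sites for LoH runs. Greedy: a candidate
# region opens at an adjusted-hom site and accumulates hom and persistent
# het sites (ambiguous sites are neither support nor interruption); it
# closes when the cumulative het fraction would exceed the cap or when a
# short consecutive run of hets appears (the signature of leaving the LoH
# block for normal het background), emitting the span of its first..last
# hom site if support suffices. Trailing hets never extend a region: the
# span always ends at the last supporting hom site.
scan_loh_runs <- function(sites, chrom, min_sites, max_het_frac,
                          max_consecutive_het = 8L) {
  cls <- sites$site_class
  pos <- sites$pos
  out <- list()
  n_hom <- 0L; n_het <- 0L; consec_het <- 0L
  first_hom <- NA_integer_; last_hom <- NA_integer_
  flush <- function() {
    if (n_hom >= min_sites) {
      out[[length(out) + 1L]] <<- tibble(
        chrom = chrom,
        start = first_hom - 1L, # site position (1-based) -> 0-based start
        end = last_hom,
        n_adjusted_hom_sites = n_hom,
        n_persistent_het_sites = n_het
      )
    }
    n_hom <<- 0L; n_het <<- 0L; consec_het <<- 0L
    first_hom <<- NA_integer_; last_hom <<- NA_integer_
  }
  for (i in seq_along(cls)) {
    c_i <- cls[i]
    if (c_i %in% c("hom_alt_adjusted", "hom_ref_adjusted")) {
      n_hom <- n_hom + 1L
      consec_het <- 0L
      if (is.na(first_hom)) first_hom <- pos[i]
      last_hom <- pos[i]
    } else if (c_i == "het") {
      if (is.na(first_hom)) next # regions open on hom support
      if ((n_het + 1L) / (n_hom + n_het + 1L) > max_het_frac ||
            consec_het + 1L > max_consecutive_het) {
        flush()
      } else {
        n_het <- n_het + 1L
        consec_het <- consec_het + 1L
      }
    }
    # ambiguous: ignored
  }
  flush()
  bind_rows(out)
}

#' Match called intervals against a truth set
#'
#' A truth interval is matched when some call overlaps at least
#' `min_overlap_frac` of the truth interval's own length (fraction
#' measured on the truth side, inclusive at the boundary), mirroring a
#' `bedtools intersect -f 0.7` comparison.
#'
#' @param truth Tibble of truth intervals (`chrom`, `start`, `end`).
#' @param calls Tibble of called intervals (`chrom`, `start`, `end`).
#' @param min_overlap_frac Minimum truth-side overlap fraction (default 0.7).
#' @return A list with `matches` (truth tibble plus `matched`,
#'   `best_overlap_frac`) and `recall`.
#' @export
match_calls <- function(truth, calls, min_overlap_frac = 0.7) {
  assert_columns(truth, c("chrom", "start", "end"), "`truth`")
  assert_columns(calls, c("chrom", "start", "end"), "`calls`")
  truth <- as_tibble(truth)
  frac <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- calls[calls$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(0)
    ov <- overlap_bp(truth$start[i], truth$end[i], cand$start, cand$end)
    max(ov) / (truth$end[i] - truth$start[i])
  }, numeric(1))
  truth$best_overlap_frac <- frac
  truth$matched <- frac >= min_overlap_frac
  list(
    matches = truth,
    recall = if (nrow(truth) == 0) NA_real_ else mean(truth$matched)
  )
}

#' @rdname segment_ratio
#' @param object,x A `ratio_segments` object.
#' @param ... Unused.
#' @export
autoplot.ratio_segments <- function(object, ...) {
  segs <- tidy(object)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end,
      y = .data$mean_log2, yend = .data$mean_log2
    ), linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "position (bp)", y = expression(log[2] ~ "coverage ratio"),
      title = "Segmented tumor/normal coverage ratio"
    ) +
    ggplot2::theme_minimal()
}
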