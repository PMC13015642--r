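# Windowed methylation summarization and tumor-vs-control differential
# calling. The window statistic is the pooled proportion of modified calls
# (sum of modified / sum of valid per window), and the calling rule is a
# difference of at least `threshold_pp` percentage points between tumor
# and control fractions over a shared non-overlapping window grid.

#' Summarize per-CpG methylation into fixed windows
#'
#' Pools modified and valid call counts over non-overlapping windows of
#' `window_bp` anchored at coordinate 0 per chromosome. The methylated
#' fraction is defined only when a window accumulates at least `min_valid`
#' valid calls; otherwise the window is unassessed (fraction NA).
#'
#' @param sites Tibble from [read_methyl_pileup()] (`chrom`, `pos`,
#'   `n_modified`, `n_valid`).
#' @param window_bp Window width in bp (default 10,000).
#' @param min_valid Minimum pooled valid calls per window (default 5).
#' @return Tibble `chrom`, `start`, `end`, `n_valid`, `n_modified`,
#'   `fraction`.
#' @export
summarize_windows <- function(sites, window_bp = 10000, min_valid = 5) {
  assert_columns(sites, c("chrom", "pos", "n_modified", "n_valid"), "`sites`")
  if (nrow(sites) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      n_valid = integer(), n_modified = integer(), fraction = double()
    ))
  }
  sites %>%
    mutate(start = (.data$pos %/% window_bp) * window_bp) %>%
    group_by(.data$chrom, .data$start) %>%
    summarise(
      n_valid = sum(.data$n_valid),
      n_modified = sum(.data$n_modified),
      .groups = "drop"
    ) %>%
    mutate(
      end = .data$start + as.integer(window_bp),
      fraction = dplyr::if_else(
        .data$n_valid >= min_valid,
        .data$n_modified / .data$n_valid,
        NA_real_
      )
    ) %>%
    arrange(factor(.data$chrom, levels = unique(sites$chrom)), .data$start) %>%
    select("chrom", "start", "end", "n_valid", "n_modified", "fraction")
}

#' Call cancer differentially methylated regions (cDMRs)
#'
#' Windows where tumor and control fractions are both defined and differ
#' by at least `threshold_pp` percentage points (inclusive) are emitted
#' with their direction.
#'
#' @param tumor,control Window tibbles from [summarize_windows()] on the
#'   same grid.
#' @param threshold_pp Calling threshold in percentage points (default 33,
#'   the cohort-calibrated value; see [calibrate_threshold()]).
#' @return Tibble `chrom`, `start`, `end`, `tumor_fraction`,
#'   `control_fraction`, `difference_pp`, `direction`
#'   (hyper_in_tumor/hypo_in_tumor).
#' @export
call_cdmr <- function(tumor, control, threshold_pp = 33) {
  assert_columns(tumor, c("chrom", "start", "end", "fraction"), "`tumor`")
  assert_columns(control, c("chrom", "start", "end", "fraction"), "`control`")
  joined <- inner_join(
    select(tumor, "chrom", "start", "end", tumor_fraction = "fraction"),
    select(control, "chrom", "start", "end", control_fraction = "fraction"),
    by = c("chrom", "start", "end")
  )
  shared_assessed <- sum(!is.na(joined$tumor_fraction) & !is.na(joined$control_fraction))
  n_assessed_t <- sum(!is.na(tumor$fraction))
  n_assessed_c <- sum(!is.na(control$fraction))
  if (nrow(joined) == 0 && (n_assessed_t > 0 || n_assessed_c > 0)) {
    abort("tumor and control window tracks share no windows; grids differ")
  }
  joined %>%
    filter(!is.na(.data$tumor_fraction), !is.na(.data$control_fraction)) %>%
    mutate(difference_pp = (.data$tumor_fraction - .data$control_fraction) * 100) %>%
    filter(abs(.data$difference_pp) >= threshold_pp) %>%
    mutate(direction = dplyr::if_else(
      .data$difference_pp > 0, "hyper_in_tumor", "hypo_in_tumor"
    )) %>%
    select(
      "chrom", "start", "end", "tumor_fraction", "control_fraction",
      "difference_pp", "direction"
    )
}

#' Calibrate the cDMR threshold from a cohort of normals
#'
#' For every unordered pair of normal samples, counts windows whose
#' methylated fractions differ by at least t percentage points, for each
#' integer t in 0..100, and returns the smallest t at which the mean
#' per-pair count drops to at most `target_count` candidate regions. With
#' the lung-normal cohort this procedure yields the 33-pp threshold.
#'
#' @param cohort Long tibble of per-sample windows: columns `sample`,
#'   `chrom`, `start`, `end`, `fraction` (one [summarize_windows()] track
#'   per sample on a shared grid).
#' @param target_count Target mean candidate-region count per pair
#'   (default 50).
#' @return Integer threshold in percentage points.
#' @export
calibrate_threshold <- function(cohort, target_count = 50) {
  assert_columns(cohort, c("sample", "chrom", "start", "end", "fraction"), "`cohort`")
  samples <- unique(cohort$sample)
  if (length(samples) < 2) {
    abort("threshold calibration needs at least 2 normal samples")
  }
  wide <- tidyr::pivot_wider(
    cohort,
    id_cols = c("chrom", "start", "end"),
    names_from = "sample", values_from = "fraction"
  )
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  # per-pair counts of |difference| >= t for integer t via tabulation
  counts <- matrix(0, nrow = length(pairs), ncol = 101)
  for (k in seq_along(pairs)) {
    d <- abs(wide[[pairs[[k]][1]]] - wide[[pairs[[k]][2]]]) * 100
    d <- d[!is.na(d)]
    counts[k, ] <- vapply(0:100, function(t) sum(d >= t), numeric(1))
  }
  mean_counts <- colMeans(counts)
  ok <- which(mean_counts <= target_count)
  if (length(ok) == 0) {
    abort("no integer threshold in 0..100 reaches the target count")
  }
  as.integer(min(ok) - 1L)
}

#' Classify windows into extreme methylation states
#'
#' Per-sample extreme classification used when no matched normal exists:
#' windows at or above `high_cut` are `high` (hypermethylated), at or
#' below `low_cut` are `low` (hypomethylated), others `intermediate`.
#' Unassessed windows (NA fraction) keep an NA class.
#'
#' @param windows Window tibble from [summarize_windows()].
#' @param high_cut Hypermethylation cut, inclusive (default 0.90).
#' @param low_cut Hypomethylation cut, inclusive (default 0.10).
#' @return The input tibble with a `methyl_class` column.
#' @export
classify_extreme <- function(windows, high_cut = 0.90, low_cut = 0.10) {
  assert_columns(windows, "fraction", "`windows`")
  mutate(as_tibble(windows), methyl_class = case_when(
    is.na(.data$fraction) ~ NA_character_,
    .data$fraction >= high_cut ~ "high",
    .data$fraction <= low_cut ~ "low",
    TRUE ~ "intermediate"
  ))
}

#' Panel-of-normals methylation reference
#'
#' Builds a single reference track as the per-window median of the
#' defined fractions across the panel samples (even counts: mean of the
#' two central values). Windows defined in fewer than `min_samples`
#' samples are unassessed in the reference.
#'
#' @param panel Long tibble: `sample`, `chrom`, `start`, `end`, `fraction`.
#' @param min_samples Minimum samples defining a window (default 3).
#' @return Window tibble `chrom`, `start`, `end`, `fraction`, `n_samples`.
#' @export
panel_reference <- function(panel, min_samples = 3) {
  assert_columns(panel, c("sample", "chrom", "start", "end", "fraction"), "`panel`")
  if (length(unique(panel$sample)) < 1) abort("panel is empty")
  panel %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(
      n_samples = sum(!is.na(.data$fraction)),
      fraction = dplyr::if_else(
        sum(!is.na(.data$fraction)) >= min_samples,
        median(.data$fraction, na.rm = TRUE),
        NA_real_
      ),
      .groups = "drop"
    ) %>%
    arrange(factor(.data$chrom, levels = unique(panel$chrom)), .data$start) %>%
    select("chrom", "start", "end", "fraction", "n_samples")
}

#' Constitutive differentially methylated regions across a cohort
#'
#' Windows called with the stated direction in every sample's cDMR set —
#' the cross-sample "constitutive" signature.
#'
#' @param per_sample_calls Named list of [call_cdmr()] tibbles, one per
#'   sample.
#' @param direction `"hyper_in_tumor"` or `"hypo_in_tumor"`.
#' @return Tibble of windows (`chrom`, `start`, `end`) present with that
#'   direction in all samples.
#' @export
constitutive_regions <- function(per_sample_calls,
                                 direction = c("hyper_in_tumor", "hypo_in_tumor")) {
  direction <- match.arg(direction)
  if (length(per_sample_calls) == 0) abort("empty cohort")
  keyed <- purrr::map(per_sample_calls, function(calls) {
    calls %>%
      filter(.data$direction == !!direction) %>%
      select("chrom", "start", "end") %>%
      distinct()
  })
  out <- keyed[[1]]
  for (k in keyed[-1]) {
    out <- inner_join(out, k, by = c("chrom", "start", "end"))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Tumor-vs-control methylation comparison plot
#'
#' Scatter of per-window methylated fractions, tumor against control,
#' with windows beyond the percentage-point threshold highlighted by
#' direction — the genome-wide methylation de-regulation view.
#'
#' @param tumor,control Window tibbles on a shared grid.
#' @param threshold_pp Highlight threshold (default 33).
#' @return A ggplot object.
#' @export
plot_methylation_comparison <- function(tumor, control, threshold_pp = 33) {
  joined <- inner_join(
    select(tumor, "chrom", "start", "end", tumor_fraction = "fraction"),
    select(control, "chrom", "start", "end", control_fraction = "fraction"),
    by = c("chrom", "start", "end")
  ) %>%
    filter(!is.na(.data$tumor_fraction), !is.na(.data$control_fraction)) %>%
    mutate(
      diff_pp = (.data$tumor_fraction - .data$control_fraction) * 100,
      state = case_when(
        .data$diff_pp >= threshold_pp ~ "higher in tumor",
        .data$diff_pp <= -threshold_pp ~ "higher in control",
        TRUE ~ "no difference"
      )
    )
  ggplot2::ggplot(joined, ggplot2::aes(
    .data$tumor_fraction, .data$control_fraction, colour = .data$state
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "higher in tumor" = "firebrick",
      "higher in control" = "steelblue",
      "no difference" = "grey70"
    )) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "tumor methylated fraction", y = "control methylated fraction",
      colour = NULL, title = "Per-window methylation comparison"
    ) +
    ggplot2::theme_minimal()
}
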