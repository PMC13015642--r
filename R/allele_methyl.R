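# Allele-specific methylation (ASM) over a configured gene panel.
# Haplotype-split methylation pileups from tumor and normal yield up to
# four series per gene (tumor H1/H2, normal H1/H2); all unordered pairs
# are compared window-wise, flagging within-sample haplotype differences
# as ASM and reporting haplotype-resolved tumor-normal changes.

#' Build per-gene haplotype methylation series
#'
#' Restricts haplotype-tagged methylation sites to each panel gene padded
#' by `padding_bp` on both sides (clipped at the chromosome start) and
#' summarizes them into windows. Unphased sites are excluded. A series'
#' `read_support` is its total valid haplotagged call count; series below
#' the support floor are later marked not assessable.
#'
#' @param sites Tibble of methylation sites with `chrom`, `pos`,
#'   `n_modified`, `n_valid`, `haplotype` (H1/H2/unphased) and `sample`
#'   (tumor/normal).
#' @param gene_intervals Tibble `gene`, `chrom`, `start`, `end`.
#' @param padding_bp Padding added to each side of a gene (default 2000,
#'   covering promoter regions).
#' @param window_bp,min_valid Windowing parameters (see
#'   [summarize_windows()]); ASM windows default to 1 kb.
#' @return Tibble with one row per (gene, sample, haplotype, window):
#'   `gene`, `sample`, `haplotype`, `chrom`, `start`, `end`, `n_valid`,
#'   `n_modified`, `fraction`, `read_support`.
#' @export
build_gene_series <- function(sites, gene_intervals, padding_bp = 2000,
                              window_bp = 1000, min_valid = 5) {
  assert_columns(
    sites, c("chrom", "pos", "n_modified", "n_valid", "haplotype", "sample"),
    "`sites`"
  )
  assert_columns(gene_intervals, c("gene", "chrom", "start", "end"), "`gene_intervals`")
  if (nrow(gene_intervals) == 0) abort("gene panel is empty")
  phased <- filter(sites, .data$haplotype %in% c("H1", "H2"))
  purrr::pmap_dfr(gene_intervals, function(gene, chrom, start, end, ...) {
    lo <- max(0L, start - padding_bp)
    hi <- end + padding_bp
    in_gene <- filter(phased, .data$chrom == !!chrom, .data$pos >= lo, .data$pos < hi)
    if (nrow(in_gene) == 0) return(NULL)
    in_gene %>%
      group_by(.data$sample, .data$haplotype) %>%
      dplyr::group_map(function(g, key) {
        win <- summarize_windows(g, window_bp = window_bp, min_valid = min_valid)
        win$gene <- gene
        win$sample <- key$sample[[1]]
        win$haplotype <- key$haplotype[[1]]
        win$read_support <- sum(g$n_valid)
        win
      }) %>%
      bind_rows()
  }) %>%
    select(dplyr::any_of(c(
      "gene", "sample", "haplotype", "chrom", "start", "end",
      "n_valid", "n_modified", "fraction", "read_support"
    )))
}

#' All-vs-all allele-specific methylation comparison
#'
#' For each gene, compares every unordered pair among the (up to four)
#' haplotype series window-wise. A pair's `max_difference_pp` is the
#' largest absolute per-window fraction difference in percentage points.
#' `asm_flag` is raised for within-sample pairs (tumor H1 vs tumor H2, or
#' normal H1 vs normal H2) meeting the threshold; cross-sample pairs carry
#' the haplotype-resolved tumor-normal change without the flag. A pair is
#' `assessable` only when both series reach `min_support` haplotagged
#' calls and share at least one defined window — a lost allele (few tumor
#' reads after LoH) therefore surfaces as a not-assessable pair.
#'
#' @param series Tibble from [build_gene_series()].
#' @param threshold_pp ASM threshold in percentage points (default 33,
#'   shared with the cDMR scale).
#' @param min_support Minimum haplotagged valid calls per series
#'   (default 5).
#' @return Tibble `gene`, `series_a`, `series_b`, `max_difference_pp`,
#'   `n_windows_compared`, `within_sample`, `asm_flag`, `assessable`.
#' @export
asm_compare <- function(series, threshold_pp = 33, min_support = 5) {
  assert_columns(
    series,
    c("gene", "sample", "haplotype", "chrom", "start", "fraction", "read_support"),
    "`series`"
  )
  series <- mutate(series, label = paste(.data$sample, .data$haplotype, sep = "_"))
  series %>%
    group_by(.data$gene) %>%
    dplyr::group_map(function(g, key) {
      labels <- sort(unique(g$label))
      if (length(labels) < 2) return(NULL)
      pairs <- utils::combn(labels, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(pr) {
        a <- filter(g, .data$label == pr[1])
        b <- filter(g, .data$label == pr[2])
        support_ok <- a$read_support[1] >= min_support && b$read_support[1] >= min_support
        j <- inner_join(
          select(a, "chrom", "start", fa = "fraction"),
          select(b, "chrom", "start", fb = "fraction"),
          by = c("chrom", "start")
        ) %>%
          filter(!is.na(.data$fa), !is.na(.data$fb))
        assessable <- support_ok && nrow(j) > 0
        max_diff <- if (nrow(j) > 0) max(abs(j$fa - j$fb)) * 100 else NA_real_
        within <- sub("_H[12]$", "", pr[1]) == sub("_H[12]$", "", pr[2])
        tibble(
          gene = key$gene[[1]],
          series_a = pr[1], series_b = pr[2],
          max_difference_pp = max_diff,
          n_windows_compared = nrow(j),
          within_sample = within,
          assessable = assessable,
          asm_flag = assessable && within && !is.na(max_diff) &&
            max_diff >= threshold_pp
        )
      })
    }) %>%
    bind_rows()
}
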