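# HLA loss-of-heterozygosity scoring from per-allele read counts. Reads
# are re-mapped upstream to two-field allele references; this module
# compares the normal and tumor Allele1:Allele2 ratios. Under copy-neutral
# loss of allele 2 at purity p, the tumor allele-1 ratio rises from 0.5 to
# (2p + (1 - p)) / 2 = (1 + p) / 2, a shift of p/2; the default decision
# cut sits halfway, at p/4.

#' Allele-1 read-count ratio
#'
#' @param c1,c2 Read counts supporting allele 1 and allele 2 (vectorised).
#' @return `c1 / (c1 + c2)`; NA when the total is zero (propagated as
#'   no_call downstream).
#' @export
allele_ratio <- function(c1, c2) {
  total <- c1 + c2
  dplyr::if_else(total > 0, c1 / total, NA_real_)
}

#' Score HLA loss of heterozygosity per gene
#'
#' Compares the tumor allele ratio with the normal allele ratio per typed
#' gene. Germline-homozygous genes (identical two-field alleles)
#' short-circuit; genes with fewer than `min_total_reads` in either sample
#' are no_call. Otherwise the ratio difference
#' `delta_r = ratio_tumor - ratio_normal` is thresholded at `delta_cut`
#' (default p/4, half the purity-expected full-LoH shift, so sensitivity
#' scales with stated purity). A two-sided binomial test of the tumor
#' counts against the normal ratio is reported as an auxiliary column and
#' plays no part in classification.
#'
#' @param counts Tibble from [read_hla_counts()].
#' @param model A [purity_model()].
#' @param min_total_reads Minimum reads per sample per gene (default 10).
#' @param delta_cut Decision threshold on `delta_r`; default
#'   `model$purity / 4`.
#' @return The input tibble with `ratio_normal`, `ratio_tumor`,
#'   `delta_r`, `binom_p`, `classification` (loh_allele1_lost /
#'   loh_allele2_lost / none / germline_homozygous / no_call).
#' @export
score_hla_loh <- function(counts, model, min_total_reads = 10, delta_cut = NULL) {
  stopifnot(inherits(model, "purity_model"))
  assert_columns(
    counts,
    c("gene", "allele1", "allele2", "normal_c1", "normal_c2", "tumor_c1", "tumor_c2"),
    "`counts`"
  )
  if (is.null(delta_cut)) delta_cut <- model$purity / 4
  out <- counts %>%
    mutate(
      ratio_normal = allele_ratio(.data$normal_c1, .data$normal_c2),
      ratio_tumor = allele_ratio(.data$tumor_c1, .data$tumor_c2),
      delta_r = .data$ratio_tumor - .data$ratio_normal
    )
  out$binom_p <- vapply(seq_len(nrow(out)), function(i) {
    nt <- out$tumor_c1[i] + out$tumor_c2[i]
    if (nt == 0 || is.na(out$ratio_normal[i])) return(NA_real_)
    stats::binom.test(out$tumor_c1[i], nt, p = out$ratio_normal[i])$p.value
  }, numeric(1))
  mutate(out, classification = case_when(
    .data$allele1 == .data$allele2 ~ "germline_homozygous",
    (.data$normal_c1 + .data$normal_c2) < min_total_reads |
      (.data$tumor_c1 + .data$tumor_c2) < min_total_reads |
      is.na(.data$delta_r) ~ "no_call",
    .data$delta_r >= delta_cut ~ "loh_allele2_lost",
    .data$delta_r <= -delta_cut ~ "loh_allele1_lost",
    TRUE ~ "none"
  ))
}

#' Tumor-only homozygosity hints
#'
#' Without a matched normal, genes typed homozygous at two-field
#' resolution are flagged as candidate-LoH *hints* (typing cannot
#' distinguish germline homozygosity from somatic allele loss).
#'
#' @param typing Tibble with `gene`, `allele1`, `allele2` (two-field).
#' @return Tibble `gene`, `homozygous_hint`.
#' @export
tumor_only_homozygosity <- function(typing) {
  assert_columns(typing, c("gene", "allele1", "allele2"), "`typing`")
  typing %>%
    filter(!is.na(.data$allele1), !is.na(.data$allele2)) %>%
    mutate(
      allele1 = two_field(.data$allele1),
      allele2 = two_field(.data$allele2),
      homozygous_hint = .data$allele1 == .data$allele2
    ) %>%
    select("gene", "homozygous_hint")
}
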