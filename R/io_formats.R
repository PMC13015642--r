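# Readers and writers for the genomic formats the pipeline touches.
# Coordinate discipline: BED and bedMethyl are 0-based half-open on disk,
# VCF is 1-based; all in-memory tables use 0-based half-open `start`/`end`
# and 1-based `pos` only for point records that came from / go to VCF.

#' Read a binned coverage track (BED)
#'
#' Reads a 4-column, optionally gzipped BED file of fixed-width coverage
#' windows (chrom, start, end, mean depth), as produced by standard depth
#' summarizers run with a 1 kb window.
#'
#' @param path Path to the BED(.gz) file.
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`, sorted
#'   by (chrom, start). Overlapping bins on one chromosome are rejected.
#' @export
read_coverage <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), depth = double()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    abort(sprintf(
      "malformed coverage BED line %d: expected 4 tab-separated fields",
      which(nf < 4)[1]
    ))
  }
  bins <- tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3))),
    depth = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4)))
  )
  bad <- which(is.na(bins$start) | is.na(bins$end) | is.na(bins$depth))
  if (length(bad) > 0) {
    abort(sprintf("malformed coverage BED line %d: non-numeric field", bad[1]))
  }
  if (any(bins$depth < 0)) {
    abort("coverage BED contains negative depth values")
  }
  if (any(bins$end <= bins$start) || any(bins$start < 0)) {
    abort("coverage BED contains invalid intervals (end <= start or start < 0)")
  }
  bins <- arrange(bins, factor(.data$chrom, levels = unique(.data$chrom)), .data$start)
  ovl <- bins %>%
    group_by(.data$chrom) %>%
    summarise(bad = any(.data$start < lag(.data$end, default = -1L)), .groups = "drop")
  if (any(ovl$bad)) {
    abort("coverage BED contains overlapping bins on one chromosome")
  }
  bins
}

#' Read SNV calls from a VCF
#'
#' Reads biallelic SNVs with an allele-fraction filter mirroring the
#' pipeline's small-variant post-processing (PASS records with allele
#' fraction greater than `min_allele_fraction`). Allele fraction is taken
#' from the per-sample `AF` annotation when present, otherwise computed as
#' alt depth / total depth from `AD`. Phase is preserved: for phased het
#' genotypes, `haplotype` names the haplotype carrying the alt allele.
#' Multi-allelic records are rejected (not decomposed).
#'
#' @param path Path to a VCF(.gz) file with one sample column.
#' @param min_allele_fraction Lower AF bound, exclusive (default 0.10).
#' @param pass_only Keep only FILTER == PASS records (default TRUE).
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref_allele`,
#'   `alt_allele`, `allele_fraction`, `depth`, `genotype`
#'   (hom_ref/het/hom_alt/missing), `haplotype` (H1/H2/unphased),
#'   `filter_pass`.
#' @export
read_snvs <- function(path, min_allele_fraction = 0.10, pass_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble(
    chrom = character(), pos = integer(), ref_allele = character(),
    alt_allele = character(), allele_fraction = double(), depth = integer(),
    genotype = character(), haplotype = character(), filter_pass = logical()
  )
  if (nrow(v@fix) == 0) {
    return(empty)
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  fmt_keys <- strsplit(v@gt[, 1], ":", fixed = TRUE)[[1]]
  if (!any(c("AF", "AD") %in% fmt_keys)) {
    abort(paste(
      "VCF lacks allele-fraction information:",
      "a per-sample AF or AD FORMAT annotation is required"
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  af <- if ("AF" %in% fmt_keys) {
    suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "AF")[, 1]))
  } else {
    rep(NA_real_, nrow(fix))
  }
  dp <- if ("DP" %in% fmt_keys) {
    suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  } else {
    rep(NA_integer_, nrow(fix))
  }
  if ("AD" %in% fmt_keys) {
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    ad2 <- strsplit(ad, ",", fixed = TRUE)
    ref_d <- suppressWarnings(as.integer(vapply(ad2, function(x) x[1], "")))
    alt_d <- suppressWarnings(as.integer(vapply(ad2, function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    }, "")))
    af <- ifelse(is.na(af), alt_d / pmax(1L, ref_d + alt_d), af)
    dp <- ifelse(is.na(dp), ref_d + alt_d, dp)
  }
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  a1 <- vapply(alleles, function(x) x[1], "")
  a2 <- vapply(alleles, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  genotype <- case_when(
    is.na(a1) | a1 == "." | is.na(a2) | a2 == "." ~ "missing",
    a1 == "0" & a2 == "0" ~ "hom_ref",
    a1 == "1" & a2 == "1" ~ "hom_alt",
    (a1 == "0" & a2 == "1") | (a1 == "1" & a2 == "0") ~ "het",
    TRUE ~ "missing"
  )
  haplotype <- dplyr::if_else(
    phased & genotype == "het",
    dplyr::if_else(a1 == "1", "H1", "H2"),
    "unphased"
  )
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    allele_fraction = af,
    depth = dplyr::coalesce(dp, 0L),
    genotype = genotype,
    haplotype = haplotype,
    filter_pass = fix$FILTER %in% c("PASS", ".")
  )
  is_snv <- nchar(out$ref_allele) == 1 & nchar(out$alt_allele) == 1 &
    !grepl(",", out$alt_allele, fixed = TRUE)
  out <- out[is_snv & !is.na(out$allele_fraction), , drop = FALSE]
  if (pass_only) out <- filter(out, .data$filter_pass)
  out <- filter(out, .data$allele_fraction > min_allele_fraction)
  arrange(out, factor(.data$chrom, levels = unique(.data$chrom)), .data$pos)
}

#' Read a per-CpG methylation pileup (bedMethyl)
#'
#' Reads the 9+-column bedMethyl format: per-CpG modified and valid call
#' counts. Only the columns the downstream window summarizer needs are
#' retained. An optional trailing `haplotype` column (H1/H2/unphased
#' dialect) is preserved when present, supporting haplotype-split pileups.
#'
#' @param path Path to a bedMethyl(.gz) file.
#' @return A tibble with columns `chrom`, `pos` (0-based CpG position),
#'   `n_modified`, `n_valid`, and `haplotype` when the file carries one;
#'   sites with zero valid calls are retained (uninformative).
#' @export
read_methyl_pileup <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), pos = integer(),
      n_modified = integer(), n_valid = integer()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12)) {
    abort(sprintf(
      "malformed bedMethyl line %d: expected >= 12 tab-separated fields",
      which(nf < 12)[1]
    ))
  }
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 2)),
    n_valid = as.integer(vapply(parts, `[[`, "", 10)),
    n_modified = as.integer(vapply(parts, `[[`, "", 12))
  )
  if (any(nf >= 19)) {
    out$haplotype <- vapply(parts, function(x) {
      if (length(x) >= 19) x[19] else "unphased"
    }, "")
  }
  if (any(out$n_modified > out$n_valid)) {
    abort("bedMethyl record with n_modified > n_valid")
  }
  if (any(out$n_modified < 0 | out$n_valid < 0)) {
    abort("bedMethyl record with negative counts")
  }
  select(out, "chrom", "pos", "n_modified", "n_valid", dplyr::any_of("haplotype"))
}

#' Read structural variants from a VCF
#'
#' Parses SVTYPE, SVLEN, END and (for breakends) CHR2 from INFO. An
#' optional `population_hits` column can be attached later by joining a
#' population-presence table (see [read_population_index()]).
#'
#' @param path Path to an SV VCF(.gz).
#' @param pass_only Keep only FILTER == PASS records (default TRUE).
#' @return Tibble with `chrom`, `pos`, `sv_type`, `length`, `end_chrom`,
#'   `end_pos`.
#' @export
read_svs <- function(path, pass_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), sv_type = character(),
      length = integer(), end_chrom = character(), end_pos = integer()
    ))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    m <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    sv_type = info_get("SVTYPE"),
    length = suppressWarnings(as.integer(info_get("SVLEN"))),
    end_chrom = info_get("CHR2"),
    end_pos = suppressWarnings(as.integer(info_get("END"))),
    filter_pass = fix$FILTER %in% c("PASS", ".")
  )
  if (pass_only) out <- filter(out, .data$filter_pass)
  bnd <- !is.na(out$sv_type) & out$sv_type == "BND"
  if (any(bnd & (is.na(out$end_chrom) | is.na(out$end_pos)))) {
    abort("BND record lacks CHR2/END second breakpoint")
  }
  if (any(!bnd & is.na(out$length))) {
    abort("non-BND SV record lacks SVLEN")
  }
  select(out, -"filter_pass")
}

#' Read a population-presence annotation for SVs
#'
#' Tab-separated table keyed by (chrom, pos, sv_type, length) with a hit
#' count against a population SV index; zero hits marks a variant as absent
#' from the population.
#'
#' @param path Path to the TSV (columns: chrom, pos, sv_type, length, hits).
#' @return Tibble with those five columns.
#' @export
read_population_index <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      sv_type = readr::col_character(), length = readr::col_integer(),
      hits = readr::col_integer()
    )
  )
  assert_columns(out, c("chrom", "pos", "sv_type", "length", "hits"), "population index")
  out
}

#' Read per-allele HLA read counts
#'
#' @param path TSV with columns gene, allele1, allele2, normal_c1,
#'   normal_c2, tumor_c1, tumor_c2. Allele names are truncated to two
#'   fields on input.
#' @return Tibble with the same columns, alleles at two-field resolution.
#' @export
read_hla_counts <- function(path) {
  # allele names like "01:01" must never be parsed as clock times
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      allele1 = readr::col_character(),
      allele2 = readr::col_character(),
      .default = readr::col_integer()
    )
  )
  assert_columns(
    out,
    c("gene", "allele1", "allele2", "normal_c1", "normal_c2", "tumor_c1", "tumor_c2"),
    "HLA counts table"
  )
  mutate(
    out,
    allele1 = two_field(.data$allele1),
    allele2 = two_field(.data$allele2)
  )
}

# Truncate an HLA allele name to two-field resolution (protein level):
# "A*01:01:02" -> "A*01:01".
two_field <- function(allele) {
  vapply(strsplit(allele, ":", fixed = TRUE), function(x) {
    paste(x[seq_len(min(2, length(x)))], collapse = ":")
  }, "")
}

#' Write CNV, LoH and DMR calls
#'
#' Emits CNV/LoH calls as a VCF 4.2 with symbolic ALT alleles
#' (`<DEL>`/`<DUP>`/`<LOH>`) and INFO keys `END`, `SVLEN`, `CN` and the
#' `SOMATIC=1` flag, plus companion BED files; DMRs as a BED with
#' direction and percentage-point difference columns. Output is
#' byte-stable across runs given identical input.
#'
#' @param cnvs Tibble of CNV calls ([call_cnv()]) or NULL.
#' @param lohs Tibble of LoH regions ([detect_loh()]) or NULL.
#' @param dmrs Tibble of DMR calls ([call_cdmr()]) or NULL.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, named character vector of files written.
#' @export
write_calls <- function(cnvs = NULL, lohs = NULL, dmrs = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))
  }
  files <- c()
  header <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=LOH,Description=\"Loss of heterozygosity\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Event length in bp\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Event type\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Purity-calibrated tumor copy number\">",
    "##INFO=<ID=OBSCN,Number=1,Type=Float,Description=\"Observed (mixture) copy number\">",
    "##INFO=<ID=SOMATIC,Number=1,Type=Integer,Description=\"Somatic flag (1 = somatic)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  vcf_rows <- character()
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    vcf_rows <- c(vcf_rows, sprintf(
      "%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;CN=%d;OBSCN=%s;SOMATIC=%d",
      cnvs$chrom, cnvs$start + 1L,
      sprintf("cnv_%s_%d", cnvs$chrom, cnvs$start),
      cnvs$cnv_type, cnvs$cnv_type, cnvs$end,
      cnvs$end - cnvs$start, cnvs$calibrated_cn,
      formatC(cnvs$observed_cn, format = "f", digits = 4),
      as.integer(cnvs$somatic)
    ))
  }
  if (!is.null(lohs) && nrow(lohs) > 0) {
    vcf_rows <- c(vcf_rows, sprintf(
      "%s\t%d\t%s\tN\t<LOH>\t.\tPASS\tSVTYPE=LOH;END=%d;SVLEN=%d%s;SOMATIC=1",
      lohs$chrom, lohs$start + 1L,
      sprintf("loh_%s_%d", lohs$chrom, lohs$start),
      lohs$end, lohs$end - lohs$start,
      ifelse(is.na(lohs$concurrent_cn), "", sprintf(";CN=%d", lohs$concurrent_cn))
    ))
  }
  vcf_path <- file.path(out_dir, "somatic_calls.vcf")
  writeLines(c(header, vcf_rows), vcf_path)
  files["vcf"] <- vcf_path

  cnv_bed <- file.path(out_dir, "cnv_calls.bed")
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s",
      cnvs$chrom, cnvs$start, cnvs$end, cnvs$cnv_type, cnvs$calibrated_cn,
      ifelse(cnvs$somatic, "SOMATIC", "GERMLINE")
    ), cnv_bed)
  } else {
    writeLines(character(), cnv_bed)
  }
  files["cnv_bed"] <- cnv_bed

  loh_bed <- file.path(out_dir, "loh_regions.bed")
  if (!is.null(lohs) && nrow(lohs) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%d\tLOH\t%d\t%d",
      lohs$chrom, lohs$start, lohs$end,
      lohs$n_adjusted_hom_sites, lohs$n_persistent_het_sites
    ), loh_bed)
  } else {
    writeLines(character(), loh_bed)
  }
  files["loh_bed"] <- loh_bed

  dmr_bed <- file.path(out_dir, "dmr_calls.bed")
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    writeLines(sprintf(
      "%s\t%d\t%d\t%s\t%s\t%s\t%s",
      dmrs$chrom, dmrs$start, dmrs$end, dmrs$direction,
      formatC(dmrs$tumor_fraction, format = "f", digits = 6),
      formatC(dmrs$control_fraction, format = "f", digits = 6),
      formatC(dmrs$difference_pp, format = "f", digits = 4)
    ), dmr_bed)
  } else {
    writeLines(character(), dmr_bed)
  }
  files["dmr_bed"] <- dmr_bed
  invisible(files)
}

#' Read back a CNV/LoH call VCF written by [write_calls()]
#'
#' @param path Path to the `somatic_calls.vcf`.
#' @return A list with tibbles `cnvs` and `lohs` matching the column layout
#'   of [call_cnv()] / [detect_loh()] output.
#' @export
read_call_vcf <- function(path) {
  lines <- read_text_lines(path)
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parse_info <- function(info, key) {
    stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  }
  if (length(rows) == 0) {
    return(list(
      cnvs = tibble(
        chrom = character(), start = integer(), end = integer(),
        cnv_type = character(), observed_cn = double(),
        calibrated_cn = integer(), somatic = logical()
      ),
      lohs = tibble(
        chrom = character(), start = integer(), end = integer(),
        concurrent_cn = integer()
      )
    ))
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1)
  pos <- as.integer(vapply(parts, `[[`, "", 2))
  alt <- vapply(parts, `[[`, "", 5)
  info <- vapply(parts, `[[`, "", 8)
  type <- parse_info(info, "SVTYPE")
  end <- as.integer(parse_info(info, "END"))
  is_loh <- type == "LOH"
  cn <- suppressWarnings(as.integer(parse_info(info, "CN")))
  list(
    cnvs = tibble(
      chrom = chrom[!is_loh], start = pos[!is_loh] - 1L, end = end[!is_loh],
      cnv_type = type[!is_loh],
      observed_cn = as.numeric(parse_info(info[!is_loh], "OBSCN")),
      calibrated_cn = cn[!is_loh],
      somatic = parse_info(info[!is_loh], "SOMATIC") == "1"
    ),
    lohs = tibble(
      chrom = chrom[is_loh], start = pos[is_loh] - 1L, end = end[is_loh],
      concurrent_cn = cn[is_loh]
    )
  )
}

# Read lines from a plain or gzipped text file.
read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
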