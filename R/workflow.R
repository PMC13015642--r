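# Workflow layer: paired and tumor-only end-to-end runs over on-disk
# inputs, plus a machine-readable summary report. A thin command-line
# wrapper around these functions ships in inst/cli/somaticsift.R.

#' Build and validate a run configuration
#'
#' @param mode `"paired"` or `"tumor_only"`.
#' @param purity Tumor content in (0, 1].
#' @param ploidy Normal ploidy (default 2).
#' @param paths Named list of input paths. Paired mode requires
#'   `tumor_cov`, `normal_cov`, `tumor_snv`, `normal_snv`; tumor-only mode
#'   forbids the normal-sample paths. Optional entries: `tumor_methyl`,
#'   `normal_methyl`, `tumor_sv`, `normal_sv`, `hla_counts`, `population`,
#'   `blacklist`, `gene_panel`.
#' @param thresholds Named list overriding defaults: `cdmr_pp` (33),
#'   `high_cut` (0.90), `low_cut` (0.10), `sv_dist` (1000),
#'   `overlap_frac` (0.7), `cnv_min_bp` (100000 paired / 1e6 tumor-only),
#'   `loh_min_bp`, `neutral_band` (0.1), `window_bp` (10000),
#'   `min_sites` (25), `max_het_frac` (0.15).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the report.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("paired", "tumor_only"), purity, ploidy = 2,
                       paths = list(), thresholds = list(),
                       out_dir = tempfile("somaticsift_run_"), seed = 1) {
  mode <- match.arg(mode)
  if (!is_scalar_number(purity) || purity <= 0 || purity > 1) {
    abort("`purity` must be a single number in (0, 1]")
  }
  normal_keys <- c("normal_cov", "normal_snv", "normal_methyl", "normal_sv")
  if (mode == "paired") {
    req <- c("tumor_cov", "normal_cov", "tumor_snv", "normal_snv")
    missing <- setdiff(req, names(paths))
    if (length(missing) > 0) {
      abort(sprintf("paired mode requires paths: %s", paste(missing, collapse = ", ")))
    }
  } else {
    bad <- intersect(normal_keys, names(paths))
    if (length(bad) > 0) {
      abort(sprintf("tumor_only mode forbids normal-sample paths: %s",
                    paste(bad, collapse = ", ")))
    }
    if (!"tumor_cov" %in% names(paths)) {
      abort("tumor_only mode requires the `tumor_cov` path")
    }
  }
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      abort(sprintf("input file for `%s` not found: '%s'", nm, paths[[nm]]))
    }
  }
  floor_bp <- if (mode == "paired") 100000 else 1000000
  defaults <- list(
    cdmr_pp = 33, high_cut = 0.90, low_cut = 0.10, sv_dist = 1000,
    overlap_frac = 0.7, cnv_min_bp = floor_bp, loh_min_bp = floor_bp,
    neutral_band = 0.1, window_bp = 10000, min_sites = 25,
    max_het_frac = 0.15, min_valid = 5
  )
  thresholds <- utils::modifyList(defaults, thresholds)
  structure(
    list(
      mode = mode, purity = purity, ploidy = ploidy, paths = paths,
      thresholds = thresholds, out_dir = out_dir, seed = seed
    ),
    class = "run_config"
  )
}

#' Run the paired tumor/normal workflow
#'
#' Executes purity-aware CNV and LoH calling, cDMR calling (when
#' methylation inputs are present), somatic SV subtraction and HLA-LoH
#' scoring, writes call files into the configured output directory and
#' returns a report bundle.
#'
#' @param config A `run_config` with mode `"paired"`.
#' @return A `somatic_run` list with per-category call tibbles, counts,
#'   the effective configuration and the files written.
#' @export
run_paired <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "paired") abort("config mode must be 'paired'")
  th <- config$thresholds
  model <- purity_model(config$purity, config$ploidy)
  pth <- config$paths

  blacklist <- if (!is.null(pth$blacklist)) read_bed3(pth$blacklist) else NULL
  tumor_cov <- read_coverage(pth$tumor_cov)
  normal_cov <- read_coverage(pth$normal_cov)
  ratio <- normalize_ratio(tumor_cov, normal_cov, blacklist)
  segs <- segment_ratio(ratio, min_segment_bp = th$cnv_min_bp)
  cnvs <- call_cnv(segs, model, neutral_band = th$neutral_band,
                   min_size_bp = th$cnv_min_bp, somatic = TRUE)

  tumor_snv <- read_snvs(pth$tumor_snv)
  normal_snv <- read_snvs(pth$normal_snv)
  lohs <- detect_loh(
    tumor_snv, normal_snv, model,
    min_sites = th$min_sites, max_het_frac = th$max_het_frac,
    min_size_bp = th$loh_min_bp, cnv_calls = cnvs
  )

  dmrs <- NULL
  if (!is.null(pth$tumor_methyl) && !is.null(pth$normal_methyl)) {
    tw <- summarize_windows(read_methyl_pileup(pth$tumor_methyl),
                            window_bp = th$window_bp, min_valid = th$min_valid)
    nw <- summarize_windows(read_methyl_pileup(pth$normal_methyl),
                            window_bp = th$window_bp, min_valid = th$min_valid)
    dmrs <- call_cdmr(tw, nw, threshold_pp = th$cdmr_pp)
  }

  sv_report <- NULL
  if (!is.null(pth$tumor_sv) && !is.null(pth$normal_sv)) {
    sv_report <- subtract_somatic(
      read_svs(pth$tumor_sv), read_svs(pth$normal_sv),
      sv_match_config(max_breakpoint_dist = th$sv_dist,
                      min_size_similarity = th$overlap_frac)
    )
  }

  hla <- NULL
  if (!is.null(pth$hla_counts)) {
    hla <- score_hla_loh(read_hla_counts(pth$hla_counts), model)
  }

  files <- write_calls(cnvs, lohs, dmrs, config$out_dir)
  new_somatic_run(
    config = config,
    cnvs = cnvs, lohs = lohs, dmrs = dmrs,
    somatic_svs = if (is.null(sv_report)) NULL else sv_report$somatic,
    shared_svs = if (is.null(sv_report)) NULL else sv_report$shared,
    hla = hla, files = files
  )
}

#' Run the tumor-only workflow
#'
#' Without a matched normal, calls are prioritized rather than declared
#' somatic: CNV and LoH calls carry the 1 Mb size floor and are labeled
#' candidates; methylation windows are classified into extreme states
#' (and compared against a panel-of-normals reference when provided); SVs
#' are classified pseudo-somatic against a population index; homozygous
#' HLA typings are flagged as hints.
#'
#' @param config A `run_config` with mode `"tumor_only"`. Optional extra
#'   paths: `panel` (long TSV of panel windows: sample, chrom, start, end,
#'   fraction), `hla_typing` (TSV gene/allele1/allele2).
#' @return A `somatic_run` bundle; all call labels are "candidate".
#' @export
run_tumor_only <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "tumor_only") abort("config mode must be 'tumor_only'")
  th <- config$thresholds
  model <- purity_model(config$purity, config$ploidy)
  pth <- config$paths

  blacklist <- if (!is.null(pth$blacklist)) read_bed3(pth$blacklist) else NULL
  tumor_cov <- read_coverage(pth$tumor_cov)
  ratio <- normalize_ratio(tumor_cov, NULL, blacklist)
  segs <- segment_ratio(ratio, min_segment_bp = th$cnv_min_bp)
  cnvs <- call_cnv(segs, model, neutral_band = th$neutral_band,
                   min_size_bp = th$cnv_min_bp, somatic = FALSE)

  lohs <- NULL
  if (!is.null(pth$tumor_snv)) {
    lohs <- detect_loh(
      read_snvs(pth$tumor_snv), NULL, model,
      min_sites = th$min_sites, max_het_frac = th$max_het_frac,
      min_size_bp = th$loh_min_bp, cnv_calls = cnvs
    )
  }

  extreme <- NULL
  dmrs <- NULL
  if (!is.null(pth$tumor_methyl)) {
    tw <- summarize_windows(read_methyl_pileup(pth$tumor_methyl),
                            window_bp = th$window_bp, min_valid = th$min_valid)
    extreme <- classify_extreme(tw, th$high_cut, th$low_cut)
    if (!is.null(pth$panel)) {
      panel <- readr::read_tsv(pth$panel, col_types = readr::cols())
      ref <- panel_reference(panel)
      dmrs <- call_cdmr(tw, ref, threshold_pp = th$cdmr_pp)
    }
  }

  pseudo <- NULL
  if (!is.null(pth$tumor_sv)) {
    if (!is.null(pth$population)) {
      pseudo <- classify_pseudo_somatic(
        read_svs(pth$tumor_sv), read_population_index(pth$population)
      )
    } else {
      inform("no population annotation supplied; SV prioritization skipped")
    }
  }

  hla_hints <- NULL
  if (!is.null(pth$hla_typing)) {
    hla_hints <- tumor_only_homozygosity(
      readr::read_tsv(pth$hla_typing, col_types = readr::cols())
    )
  }

  files <- write_calls(cnvs, lohs, dmrs, config$out_dir)
  new_somatic_run(
    config = config,
    cnvs = cnvs, lohs = lohs, dmrs = dmrs,
    extreme = extreme,
    pseudo_somatic = if (is.null(pseudo)) NULL else
      filter(pseudo, .data$population_state == "pseudo_somatic"),
    hla_hints = hla_hints, files = files
  )
}

new_somatic_run <- function(config, ..., files) {
  parts <- list(...)
  counts <- purrr::imap_dfr(parts, function(x, nm) {
    tibble(category = nm, n = if (is.null(x)) NA_integer_ else nrow(x))
  })
  structure(
    list(config = config, results = parts, counts = counts, files = files),
    class = "somatic_run"
  )
}

#' @exportS3Method base::print
print.somatic_run <- function(x, ...) {
  cat(sprintf("<somatic_run> mode %s, purity %.2f\n", x$config$mode, x$config$purity))
  run <- x$counts[!is.na(x$counts$n), ]
  for (i in seq_len(nrow(run))) {
    cat(sprintf("  %-16s %d\n", run$category[i], run$n[i]))
  }
  invisible(x)
}

#' @export
tidy.somatic_run <- function(x, ...) {
  x$counts
}

#' @export
glance.somatic_run <- function(x, ...) {
  cnt <- function(nm) {
    v <- x$counts$n[x$counts$category == nm]
    if (length(v) == 0) NA_integer_ else v
  }
  tibble(
    mode = x$config$mode,
    purity = x$config$purity,
    n_cnv = cnt("cnvs"),
    n_loh = cnt("lohs"),
    n_dmr = cnt("dmrs"),
    n_somatic_sv = cnt("somatic_svs"),
    n_pseudo_somatic_sv = cnt("pseudo_somatic")
  )
}

#' Render a run report to disk
#'
#' Writes per-category summary tables (counts, size distributions,
#' per-chromosome tallies) as TSV plus a JSON index with stable field
#' order; re-rendering the same bundle reproduces identical bytes.
#'
#' @param run A `somatic_run` from [run_paired()] / [run_tumor_only()].
#' @param out_dir Output directory (defaults to the run's).
#' @return Invisibly, the path of the JSON index.
#' @export
render_report <- function(run, out_dir = run$config$out_dir) {
  stopifnot(inherits(run, "somatic_run"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary_tbl <- run$counts %>%
    mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    arrange(.data$category)
  readr::write_tsv(summary_tbl, file.path(out_dir, "summary_counts.tsv"))

  per_chrom <- purrr::imap_dfr(run$results, function(x, nm) {
    if (is.null(x) || nrow(x) == 0 || !"chrom" %in% names(x)) return(NULL)
    x %>% count(.data$chrom, name = "n") %>% mutate(category = nm)
  })
  if (nrow(per_chrom) == 0) {
    per_chrom <- tibble(chrom = character(), n = integer(), category = character())
  }
  per_chrom <- arrange(per_chrom, .data$category, .data$chrom) %>%
    select("category", "chrom", "n")
  readr::write_tsv(per_chrom, file.path(out_dir, "per_chromosome.tsv"))

  sizes <- purrr::imap_dfr(run$results, function(x, nm) {
    if (is.null(x) || nrow(x) == 0 || !all(c("start", "end") %in% names(x))) {
      return(NULL)
    }
    tibble(
      category = nm,
      n = nrow(x),
      min_bp = min(x$end - x$start),
      median_bp = median(x$end - x$start),
      max_bp = max(x$end - x$start)
    )
  })
  if (nrow(sizes) == 0) {
    sizes <- tibble(category = character(), n = integer(), min_bp = double(),
                    median_bp = double(), max_bp = double())
  }
  readr::write_tsv(arrange(sizes, .data$category), file.path(out_dir, "size_summary.tsv"))

  index <- list(
    mode = run$config$mode,
    purity = run$config$purity,
    ploidy = run$config$ploidy,
    seed = run$config$seed,
    thresholds = run$config$thresholds,
    counts = setNames(
      as.list(dplyr::coalesce(summary_tbl$n, 0L)), summary_tbl$category
    ),
    files = as.list(run$files)
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(index, json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  cfg_path <- file.path(out_dir, "effective_config.yaml")
  yaml::write_yaml(
    list(
      mode = run$config$mode, purity = run$config$purity,
      ploidy = run$config$ploidy, seed = run$config$seed,
      thresholds = run$config$thresholds,
      paths = run$config$paths
    ),
    cfg_path
  )
  invisible(json_path)
}

# 3+-column BED reader for blacklist / gene panels.
read_bed3 <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.integer(vapply(parts, `[[`, "", 2)),
    end = as.integer(vapply(parts, `[[`, "", 3))
  )
}
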