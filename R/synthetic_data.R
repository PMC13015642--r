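# Synthetic tumor/normal summary data with planted CNV, LoH, DMR, SV and
# HLA-LoH events at a stated purity, plus in-silico titration mixing.
# The generator emits the same summary-level substrates the real pipeline
# consumes (binned coverage, SNV calls, per-CpG methylation pileups, SV
# records, per-allele HLA counts) together with a ground-truth ledger, so
# every caller is testable without downloads. Depth noise is Poisson;
# allele and methylation counts are binomial; titration mixing thins reads
# binomially so allele fractions mix at the count level.

HLA_GENES <- c(
  "HLA-A", "HLA-B", "HLA-C", "HLA-DPA1", "HLA-DPB1",
  "HLA-DQA1", "HLA-DQB1", "HLA-DRB1"
)

#' Define a synthetic genome
#'
#' @param n_chrom Number of chromosomes (default 10).
#' @param chrom_bp Length of each chromosome in bp (default 10 Mb).
#' @return Tibble `chrom`, `length`.
#' @export
genome_spec <- function(n_chrom = 10, chrom_bp = 1e7) {
  tibble(chrom = paste0("chr", seq_len(n_chrom)), length = as.integer(chrom_bp))
}

#' Plant non-overlapping truth events on a genome
#'
#' Draws CNV, LoH, DMR, somatic-SV and HLA-LoH events at random positions
#' (no two events overlap, any kind, with a 200 kb margin) and returns the
#' ground-truth ledger consumed by [simulate_pair()] and by recovery
#' tests.
#'
#' @param genome A [genome_spec()] tibble.
#' @param n_cnv,n_loh,n_dmr,n_sv,n_hla_loh Event counts per kind.
#' @param cnv_bp,loh_bp,dmr_bp Event widths in bp.
#' @param cn_states Tumor copy numbers sampled for CNV events.
#' @param dmr_delta_pp Planted methylation differences (percentage points,
#'   magnitude) sampled for DMR events; sign is drawn separately.
#' @param seed Integer seed.
#' @return Truth tibble: `kind`, `chrom`, `start`, `end`, `cn`,
#'   `retained_hap`, `delta_pp`, `sv_type`, `sv_length`, `gene`,
#'   `lost_allele`.
#' @export
plant_events <- function(genome, n_cnv = 5, n_loh = 5, n_dmr = 30, n_sv = 25,
                         n_hla_loh = 3, cnv_bp = 2e6, loh_bp = 2e6,
                         dmr_bp = 5e4, cn_states = c(1, 3, 4),
                         dmr_delta_pp = c(40, 45, 50, 55, 60), seed = 1) {
  withr::with_seed(derive_seed(seed, "events"), {
    placed <- tibble(chrom = character(), start = double(), end = double())
    margin <- 2e5
    place <- function(width) {
      for (try in 1:2000) {
        ci <- sample.int(nrow(genome), 1)
        len <- genome$length[ci]
        if (len < width + 2 * margin) next
        s <- floor(runif(1, margin, len - width - margin))
        clash <- overlaps_any(
          genome$chrom[ci], s - margin, s + width + margin, placed
        )
        if (!any(clash)) {
          placed <<- bind_rows(placed, tibble(
            chrom = genome$chrom[ci], start = s, end = s + width
          ))
          return(c(ci, s))
        }
      }
      abort("could not place event without overlap; genome too crowded")
    }
    mk <- function(kind, n, width) {
      if (n == 0) return(NULL)
      purrr::map_dfr(seq_len(n), function(i) {
        ps <- place(width)
        tibble(
          kind = kind, chrom = genome$chrom[ps[1]],
          start = as.integer(ps[2]), end = as.integer(ps[2] + width)
        )
      })
    }
    draw <- function(choices, n) {
      # sample() on a length-1 numeric would enumerate 1:x
      choices[sample.int(length(choices), n, replace = TRUE)]
    }
    cnv <- mk("cnv", n_cnv, cnv_bp)
    if (!is.null(cnv)) cnv$cn <- draw(cn_states, n_cnv)
    loh <- mk("loh", n_loh, loh_bp)
    if (!is.null(loh)) loh$retained_hap <- draw(c("H1", "H2"), n_loh)
    dmr <- mk("dmr", n_dmr, dmr_bp)
    if (!is.null(dmr)) {
      dmr$delta_pp <- draw(dmr_delta_pp, n_dmr) * draw(c(-1, 1), n_dmr)
    }
    sv <- mk("sv", n_sv, 1e4)
    if (!is.null(sv)) {
      sv$sv_type <- sample(c("DEL", "DUP", "INS", "INV"), n_sv, replace = TRUE)
      sv$sv_length <- as.integer(round(runif(n_sv, 1e3, 1e4)))
    }
    hla <- if (n_hla_loh > 0) {
      tibble(
        kind = "hla_loh",
        gene = sample(HLA_GENES, n_hla_loh),
        lost_allele = sample(1:2, n_hla_loh, replace = TRUE)
      )
    } else {
      NULL
    }
    bind_rows(cnv, loh, dmr, sv, hla)
  })
}

#' Simulate a tumor/normal summary-data pair with planted events
#'
#' Generates matched tumor and normal samples on one genome: Poisson
#' binned coverage (tumor bins inside CNV events scale by the purity
#' mixture expectation), binomial het-SNV allele counts (tumor sites
#' inside LoH events draw at the purity-adjusted allele fraction of the
#' retained haplotype), binomial per-CpG methylation (DMR windows shift by
#' the planted difference, attenuated by purity), germline plus somatic SV
#' records, and binomial per-allele HLA counts. Regenerating with the same
#' seed reproduces the output exactly.
#'
#' @param truth Truth tibble from [plant_events()] (same-kind events must
#'   not overlap).
#' @param model A [purity_model()] giving the tumor sample's purity.
#' @param genome A [genome_spec()] tibble.
#' @param depth Mean sequencing depth (default 30).
#' @param bin_bp Coverage bin width (default 1000).
#' @param het_density Germline het SNVs per kb (default 0.5).
#' @param cpg_density Assessed CpG sites per kb (default 2).
#' @param n_germline_sv Shared germline SVs (default 30).
#' @param sv_jitter_bp Breakpoint jitter of germline SVs between the two
#'   samples (default 100, uniform in +/- this value).
#' @param hla_depth Reads per HLA gene per sample (default 200).
#' @param seed Integer seed.
#' @return A list with elements `tumor` and `normal`, each a `sim_sample`
#'   list carrying `coverage`, `snvs`, `methyl`, `svs`, `hla`, `truth`,
#'   `purity`, `seed`.
#' @export
simulate_pair <- function(truth, model, genome = genome_spec(), depth = 30,
                          bin_bp = 1000, het_density = 0.5, cpg_density = 2,
                          n_germline_sv = 30, sv_jitter_bp = 100,
                          hla_depth = 200, seed = 1) {
  stopifnot(inherits(model, "purity_model"))
  truth <- normalize_truth(truth)
  check_no_same_kind_overlap(truth)
  p <- model$purity

  ev <- function(kind) filter(truth, .data$kind == !!kind)

  # --- coverage -------------------------------------------------------
  grid <- purrr::pmap_dfr(genome, function(chrom, length) {
    s <- seq(0L, length - 1L, by = bin_bp)
    tibble(chrom = chrom, start = s, end = pmin(s + as.integer(bin_bp), length))
  })
  cnvs <- ev("cnv")
  mean_cn <- rep(model$normal_ploidy, nrow(grid))
  if (nrow(cnvs) > 0) {
    for (i in seq_len(nrow(cnvs))) {
      inside <- grid$chrom == cnvs$chrom[i] &
        grid$start >= cnvs$start[i] & grid$end <= cnvs$end[i]
      mean_cn[inside] <- cnvs$cn[i]
    }
  }
  tumor_mu <- depth * expected_observed_cn(model, mean_cn) / model$normal_ploidy
  cov_n <- withr::with_seed(
    derive_seed(seed, "coverage"),
    tibble(grid, depth = as.numeric(rpois(nrow(grid), depth)))
  )
  cov_t <- withr::with_seed(
    derive_seed(seed + 1L, "coverage"),
    tibble(grid, depth = as.numeric(rpois(nrow(grid), tumor_mu)))
  )

  # --- SNVs -----------------------------------------------------------
  lohs <- ev("loh")
  snv_pair <- withr::with_seed(derive_seed(seed, "snv"), {
    sites <- purrr::pmap_dfr(genome, function(chrom, length) {
      n <- round(length / 1000 * het_density)
      tibble(chrom = chrom, pos = sort(sample.int(length, n)))
    })
    sites$alt_hap <- sample(c("H1", "H2"), nrow(sites), replace = TRUE)
    # normal: balanced germline het
    d_n <- rpois(nrow(sites), depth)
    a_n <- rbinom(nrow(sites), d_n, 0.5)
    # tumor: purity-adjusted fraction by local event state
    p_alt <- rep(0.5, nrow(sites))
    if (nrow(lohs) > 0) {
      for (i in seq_len(nrow(lohs))) {
        inside <- sites$chrom == lohs$chrom[i] &
          sites$pos > lohs$start[i] & sites$pos <= lohs$end[i]
        retained_alt <- sites$alt_hap == lohs$retained_hap[i]
        p_alt[inside & retained_alt] <- expected_alt_fraction(model, 2, 2)
        p_alt[inside & !retained_alt] <- expected_alt_fraction(model, 0, 2)
      }
    }
    d_t <- rpois(nrow(sites), depth)
    a_t <- rbinom(nrow(sites), d_t, p_alt)
    list(sites = sites, d_n = d_n, a_n = a_n, d_t = d_t, a_t = a_t)
  })
  snv_tbl <- function(d, a, phase_hap) {
    af <- ifelse(d > 0, round(a / d, 6), 0)
    tibble(
      chrom = snv_pair$sites$chrom,
      pos = snv_pair$sites$pos,
      ref_allele = "A", alt_allele = "G",
      alt_count = a, depth = d, allele_fraction = af,
      genotype = case_when(
        af <= 0.25 ~ "hom_ref", af >= 0.75 ~ "hom_alt", TRUE ~ "het"
      ),
      haplotype = phase_hap,
      filter_pass = TRUE
    )
  }
  snv_n <- snv_tbl(snv_pair$d_n, snv_pair$a_n, snv_pair$sites$alt_hap)
  snv_n$genotype <- "het" # germline truth: all planted sites are het
  snv_t <- snv_tbl(snv_pair$d_t, snv_pair$a_t, snv_pair$sites$alt_hap)

  # --- methylation ----------------------------------------------------
  dmrs <- ev("dmr")
  window_bp <- 10000
  methyl <- withr::with_seed(derive_seed(seed, "methyl"), {
    step <- max(1L, as.integer(round(1000 / cpg_density)))
    sites <- purrr::pmap_dfr(genome, function(chrom, length) {
      tibble(chrom = chrom, pos = seq(0L, length - 1L, by = step))
    })
    win_id <- paste0(sites$chrom, ":", sites$pos %/% window_bp)
    uw <- unique(win_id)
    # baseline methylation landscape: mostly-methylated bulk genome with
    # hypomethylated island-like windows and an intermediate fraction
    comp <- sample.int(3, length(uw), replace = TRUE, prob = c(0.2, 0.2, 0.6))
    base <- setNames(dplyr::case_when(
      comp == 1 ~ runif(length(uw), 0.02, 0.10),
      comp == 2 ~ runif(length(uw), 0.20, 0.55),
      TRUE ~ runif(length(uw), 0.55, 0.97)
    ), uw)
    f_n <- unname(base[win_id])
    f_t_target <- f_n
    if (nrow(dmrs) > 0) {
      for (i in seq_len(nrow(dmrs))) {
        inside <- sites$chrom == dmrs$chrom[i] &
          sites$pos >= dmrs$start[i] & sites$pos < dmrs$end[i]
        delta <- dmrs$delta_pp[i] / 100
        f_n[inside] <- 0.5 - delta / 2
        f_t_target[inside] <- 0.5 + delta / 2
      }
    }
    f_t <- p * f_t_target + (1 - p) * f_n
    v_n <- rpois(nrow(sites), depth)
    m_n <- rbinom(nrow(sites), v_n, f_n)
    v_t <- rpois(nrow(sites), depth)
    m_t <- rbinom(nrow(sites), v_t, f_t)
    list(
      normal = tibble(chrom = sites$chrom, pos = sites$pos,
                      n_modified = m_n, n_valid = v_n),
      tumor = tibble(chrom = sites$chrom, pos = sites$pos,
                     n_modified = m_t, n_valid = v_t)
    )
  })

  # --- SVs ------------------------------------------------------------
  svs <- withr::with_seed(derive_seed(seed, "sv"), {
    germ <- if (n_germline_sv > 0) {
      ci <- sample.int(nrow(genome), n_germline_sv, replace = TRUE)
      tibble(
        chrom = genome$chrom[ci],
        pos = as.integer(floor(runif(n_germline_sv, 1e4, genome$length[ci] - 1e4))),
        sv_type = sample(c("DEL", "DUP", "INS", "INV"), n_germline_sv, replace = TRUE),
        length = as.integer(round(runif(n_germline_sv, 1e3, 1e4))),
        germline = TRUE
      )
    } else {
      tibble(chrom = character(), pos = integer(), sv_type = character(),
             length = integer(), germline = logical())
    }
    som <- ev("sv")
    som_tbl <- if (nrow(som) > 0) {
      tibble(
        chrom = som$chrom, pos = som$start, sv_type = som$sv_type,
        length = som$sv_length, germline = FALSE
      )
    } else {
      germ[0, ]
    }
    # signed length convention: deletions negative
    sign_len <- function(x) {
      mutate(x, length = ifelse(.data$sv_type == "DEL", -abs(.data$length), abs(.data$length)))
    }
    germ <- sign_len(germ)
    som_tbl <- sign_len(som_tbl)
    germ_t <- germ
    if (nrow(germ_t) > 0) {
      germ_t$pos <- germ_t$pos +
        as.integer(round(runif(nrow(germ_t), -sv_jitter_bp, sv_jitter_bp)))
    }
    list(
      normal = mutate(germ, population_hits = rpois(nrow(germ), 20) + 1L),
      tumor = bind_rows(
        mutate(germ_t, population_hits = rpois(nrow(germ_t), 20) + 1L),
        mutate(som_tbl, population_hits = 0L)
      )
    )
  })
  add_sv_cols <- function(x) {
    mutate(
      arrange(x, factor(.data$chrom, levels = genome$chrom), .data$pos),
      end_chrom = NA_character_, end_pos = NA_integer_
    )
  }

  # --- HLA ------------------------------------------------------------
  hla_events <- ev("hla_loh")
  hla <- withr::with_seed(derive_seed(seed, "hla"), {
    tbl <- tibble(
      gene = HLA_GENES,
      allele1 = sprintf("%02d:01", seq_along(HLA_GENES)),
      allele2 = sprintf("%02d:02", seq_along(HLA_GENES))
    )
    tbl$normal_c1 <- rbinom(nrow(tbl), hla_depth, 0.5)
    tbl$normal_c2 <- hla_depth - tbl$normal_c1
    p1 <- rep(0.5, nrow(tbl))
    if (nrow(hla_events) > 0) {
      for (i in seq_len(nrow(hla_events))) {
        j <- match(hla_events$gene[i], tbl$gene)
        # copy-neutral loss: retained allele at 2p + (1-p), lost at (1-p)
        retained_frac <- (1 + p) / 2
        p1[j] <- if (hla_events$lost_allele[i] == 2) retained_frac else 1 - retained_frac
      }
    }
    tbl$tumor_c1 <- rbinom(nrow(tbl), hla_depth, p1)
    tbl$tumor_c2 <- hla_depth - tbl$tumor_c1
    tbl
  })

  mk_sample <- function(coverage, snvs, methyl_sites, sv_tbl, purity, s) {
    structure(
      list(
        coverage = coverage, snvs = snvs, methyl = methyl_sites,
        svs = add_sv_cols(sv_tbl), hla = hla, truth = truth,
        genome = genome, purity = purity, seed = s
      ),
      class = "sim_sample"
    )
  }
  list(
    tumor = mk_sample(cov_t, snv_t, methyl$tumor, svs$tumor, p, seed),
    normal = mk_sample(cov_n, snv_n, methyl$normal, svs$normal, 0, seed)
  )
}

normalize_truth <- function(truth) {
  if (is.null(truth) || nrow(truth) == 0) {
    return(tibble(
      kind = character(), chrom = character(), start = integer(),
      end = integer(), cn = double(), retained_hap = character(),
      delta_pp = double(), sv_type = character(), sv_length = integer(),
      gene = character(), lost_allele = integer()
    ))
  }
  defaults <- list(
    cn = NA_real_, retained_hap = NA_character_, delta_pp = NA_real_,
    sv_type = NA_character_, sv_length = NA_integer_, gene = NA_character_,
    lost_allele = NA_integer_, chrom = NA_character_, start = NA_integer_,
    end = NA_integer_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(truth)) truth[[nm]] <- defaults[[nm]]
  }
  as_tibble(truth)
}

check_no_same_kind_overlap <- function(truth) {
  spatial <- filter(truth, .data$kind %in% c("cnv", "loh", "dmr", "sv"))
  for (k in unique(spatial$kind)) {
    ev <- arrange(filter(spatial, .data$kind == k), .data$chrom, .data$start)
    if (nrow(ev) < 2) next
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)])) {
      abort(sprintf("overlapping '%s' truth events", k))
    }
  }
  invisible(truth)
}

#' @exportS3Method base::print
print.sim_sample <- function(x, ...) {
  cat(sprintf(
    "<sim_sample> purity %.2f | %d bins, %d SNVs, %d CpGs, %d SVs, %d HLA genes | seed %d\n",
    x$purity, nrow(x$coverage), nrow(x$snvs), nrow(x$methyl), nrow(x$svs),
    nrow(x$hla), x$seed
  ))
  invisible(x)
}

#' Mix a pure tumor sample with its matched normal (in-silico titration)
#'
#' Produces a sample whose effective purity is `alpha` (when the tumor
#' input is pure): coverage is the convex combination of the two depth
#' tracks; SNV, methylation and HLA counts are mixed by binomially
#' thinning each compartment's reads with probability `alpha` and
#' `1 - alpha`, so allele fractions mix at the count level rather than by
#' averaging fractions. The SV set of the mixture is the tumor's.
#'
#' @param tumor,normal `sim_sample` objects from one [simulate_pair()]
#'   call (shared grids).
#' @param alpha Tumor fraction of the mixture, in \[0, 1\].
#' @param seed Integer seed for the thinning draws.
#' @return A `sim_sample` at effective purity `alpha * tumor$purity`.
#' @export
mix_titration <- function(tumor, normal, alpha, seed = 1) {
  stopifnot(inherits(tumor, "sim_sample"), inherits(normal, "sim_sample"))
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (alpha == 1) return(tumor)
  if (alpha == 0) return(normal)
  if (nrow(tumor$coverage) != nrow(normal$coverage) ||
      !all(tumor$coverage$start == normal$coverage$start &
             tumor$coverage$chrom == normal$coverage$chrom)) {
    abort("tumor and normal samples are not on the same grids")
  }
  withr::with_seed(derive_seed(seed, "mix"), {
    coverage <- tumor$coverage
    coverage$depth <- alpha * tumor$coverage$depth + (1 - alpha) * normal$coverage$depth

    thin2 <- function(x_t, x_n) {
      rbinom(length(x_t), x_t, alpha) + rbinom(length(x_n), x_n, 1 - alpha)
    }
    st <- tumor$snvs; sn <- normal$snvs
    alt <- thin2(st$alt_count, sn$alt_count)
    ref <- thin2(st$depth - st$alt_count, sn$depth - sn$alt_count)
    d <- alt + ref
    af <- ifelse(d > 0, round(alt / d, 6), 0)
    snvs <- mutate(
      st,
      alt_count = alt, depth = d, allele_fraction = af,
      genotype = case_when(
        af <= 0.25 ~ "hom_ref", af >= 0.75 ~ "hom_alt", TRUE ~ "het"
      )
    )

    mt <- tumor$methyl; mn <- normal$methyl
    mod <- thin2(mt$n_modified, mn$n_modified)
    unmod <- thin2(mt$n_valid - mt$n_modified, mn$n_valid - mn$n_modified)
    methyl <- mutate(mt, n_modified = mod, n_valid = mod + unmod)

    ht <- tumor$hla; hn <- normal$hla
    hla <- mutate(
      ht,
      tumor_c1 = thin2(ht$tumor_c1, hn$normal_c1),
      tumor_c2 = thin2(ht$tumor_c2, hn$normal_c2),
      normal_c1 = hn$normal_c1, normal_c2 = hn$normal_c2
    )

    structure(
      list(
        coverage = coverage, snvs = snvs, methyl = methyl, svs = tumor$svs,
        hla = hla, truth = tumor$truth, genome = tumor$genome,
        purity = alpha * tumor$purity, seed = seed
      ),
      class = "sim_sample"
    )
  })
}

#' Export a simulated sample to standard on-disk formats
#'
#' Writes the sample as the file formats the readers consume: gzipped
#' coverage BED, SNV VCF, bedMethyl, SV VCF, HLA counts TSV, population
#' index TSV and a truth-ledger JSON.
#'
#' @param sample A `sim_sample`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sample").
#' @return Invisibly, a named character vector of the paths written.
#' @export
export_fixture <- function(sample, out_dir, prefix = "sample") {
  stopifnot(inherits(sample, "sim_sample"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c()

  cov_path <- file.path(out_dir, paste0(prefix, ".coverage.bed.gz"))
  con <- gzfile(cov_path, "wt")
  writeLines(sprintf(
    "%s\t%d\t%d\t%s",
    sample$coverage$chrom, sample$coverage$start, sample$coverage$end,
    formatC(sample$coverage$depth, format = "fg", digits = 10)
  ), con)
  close(con)
  paths["coverage"] <- cov_path

  snv_path <- file.path(out_dir, paste0(prefix, ".snv.vcf"))
  s <- sample$snvs
  gt <- dplyr::case_when(
    s$genotype == "hom_ref" ~ "0|0",
    s$genotype == "hom_alt" ~ "1|1",
    s$haplotype == "H1" ~ "1|0",
    s$haplotype == "H2" ~ "0|1",
    TRUE ~ "0/1"
  )
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE",
    sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AF\t%s:%d:%s",
      s$chrom, s$pos, s$ref_allele, s$alt_allele, gt, s$depth,
      formatC(s$allele_fraction, format = "f", digits = 6)
    )
  ), snv_path)
  paths["snv"] <- snv_path

  bm_path <- file.path(out_dir, paste0(prefix, ".bedmethyl"))
  m <- sample$methyl
  pct <- ifelse(m$n_valid > 0, 100 * m$n_modified / m$n_valid, 0)
  writeLines(sprintf(
    "%s\t%d\t%d\tm\t%d\t+\t%d\t%d\t255,0,0\t%d\t%s\t%d\t%d\t0\t0\t0\t0\t0",
    m$chrom, m$pos, m$pos + 1L, m$n_valid, m$pos, m$pos + 1L,
    m$n_valid, formatC(pct, format = "f", digits = 2), m$n_modified,
    m$n_valid - m$n_modified
  ), bm_path)
  paths["methyl"] <- bm_path

  sv_path <- file.path(out_dir, paste0(prefix, ".sv.vcf"))
  v <- sample$svs
  sv_end <- ifelse(v$sv_type == "INS", v$pos, v$pos + abs(v$length))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    if (nrow(v) > 0) {
      sprintf(
        "%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d",
        v$chrom, v$pos, seq_len(nrow(v)), v$sv_type, v$sv_type,
        v$length, sv_end
      )
    } else {
      character()
    }
  ), sv_path)
  paths["sv"] <- sv_path

  pop_path <- file.path(out_dir, paste0(prefix, ".population.tsv"))
  readr::write_tsv(
    tibble(
      chrom = v$chrom, pos = v$pos, sv_type = v$sv_type,
      length = v$length, hits = v$population_hits
    ),
    pop_path
  )
  paths["population"] <- pop_path

  hla_path <- file.path(out_dir, paste0(prefix, ".hla_counts.tsv"))
  readr::write_tsv(sample$hla, hla_path)
  paths["hla"] <- hla_path

  truth_path <- file.path(out_dir, paste0(prefix, ".truth.json"))
  jsonlite::write_json(
    list(purity = sample$purity, seed = sample$seed, events = sample$truth),
    truth_path,
    digits = NA, na = "null", pretty = TRUE
  )
  paths["truth"] <- truth_path
  invisible(paths)
}
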