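#' Tumor purity mixture model
#'
#' A sequenced tumor sample is a mixture of malignant cells at fraction
#' `purity` (p) and contaminating normal cells at fraction 1 - p. Coverage
#' and allele fractions observed in the mixture are convex combinations of
#' the tumor and normal compartments. This constructor captures the two
#' parameters every purity-aware computation needs: p and the normal-cell
#' ploidy (2 for autosomes).
#'
#' @param purity Fraction of malignant cells, in \[0, 1\].
#' @param normal_ploidy Copy number of the normal compartment (default 2).
#' @return An object of class `purity_model`.
#' @examples
#' m <- purity_model(0.5)
#' expected_observed_cn(m, 4) # a CN=4 event observed at 50% purity reads as 3
#' @export
purity_model <- function(purity, normal_ploidy = 2L) {
  if (!is_scalar_number(purity) || purity < 0 || purity > 1) {
    abort("`purity` must be a single number in [0, 1]")
  }
  if (!is_scalar_number(normal_ploidy) || normal_ploidy < 1) {
    abort("`normal_ploidy` must be an integer >= 1")
  }
  structure(
    list(purity = as.numeric(purity), normal_ploidy = as.integer(round(normal_ploidy))),
    class = "purity_model"
  )
}

#' @exportS3Method base::print
print.purity_model <- function(x, ...) {
  cat(sprintf(
    "<purity_model> purity = %.3f, normal ploidy = %d\n",
    x$purity, x$normal_ploidy
  ))
  invisible(x)
}

#' Expected observed copy number of a tumor event in a mixture
#'
#' The coverage-implied copy number of a region with true tumor copy number
#' `cn_tumor` in a sample containing tumor cells at fraction p is
#' `p * cn_tumor + (1 - p) * normal_ploidy`: a CN=4 triplication at 50%
#' purity is observed as CN=3.
#'
#' @param model A [purity_model()].
#' @param cn_tumor True copy number in the tumor compartment (>= 0; vectorised).
#' @return Numeric vector of observed (mixture) copy numbers.
#' @export
expected_observed_cn <- function(model, cn_tumor) {
  stopifnot(inherits(model, "purity_model"))
  if (any(cn_tumor < 0)) abort("`cn_tumor` must be >= 0")
  model$purity * cn_tumor + (1 - model$purity) * model$normal_ploidy
}

#' Calibrate an observed copy number back to the tumor compartment
#'
#' Inverts [expected_observed_cn()] on integer tumor states:
#' `round((observed - (1 - p) * normal_ploidy) / p)`, clamped at zero. Ties
#' (residual exactly 0.5) round half away from the normal ploidy, favoring
#' reporting an event over no event.
#'
#' @param model A [purity_model()]; its purity must be > 0.
#' @param observed_cn Observed (mixture) copy number (vectorised).
#' @return Integer vector of calibrated tumor copy numbers.
#' @export
calibrate_tumor_cn <- function(model, observed_cn) {
  stopifnot(inherits(model, "purity_model"))
  if (model$purity <= 0) {
    abort("tumor content must be positive for calibration")
  }
  if (any(observed_cn < 0)) abort("`observed_cn` must be >= 0")
  raw <- (observed_cn - (1 - model$purity) * model$normal_ploidy) / model$purity
  frac <- raw - floor(raw)
  # round half away from the normal ploidy
  tie <- abs(frac - 0.5) < 1e-9
  out <- round(raw)
  up <- floor(raw) + 1
  down <- floor(raw)
  away <- ifelse(abs(up - model$normal_ploidy) >= abs(down - model$normal_ploidy), up, down)
  out[tie] <- away[tie]
  as.integer(pmax(0, out))
}

#' Expected alternate-allele fraction in a tumor/normal mixture
#'
#' The allele fraction observed at a site is the read-weighted mixture of
#' the two compartments:
#' `(p * alt_t + (1 - p) * alt_n) / (p * tot_t + (1 - p) * tot_n)`.
#' For a germline het (1 of 2 in the normal) under copy-neutral LoH
#' retaining the alt allele (2 of 2 in the tumor) this gives (1 + p) / 2.
#'
#' @param model A [purity_model()].
#' @param alt_copies_tumor,total_copies_tumor Allele copies in the tumor
#'   compartment (vectorised).
#' @param alt_copies_normal,total_copies_normal Allele copies in the normal
#'   compartment (defaults: germline het of a diploid normal).
#' @return Numeric vector of expected allele fractions.
#' @export
expected_alt_fraction <- function(model, alt_copies_tumor, total_copies_tumor,
                                  alt_copies_normal = 1, total_copies_normal = 2) {
  stopifnot(inherits(model, "purity_model"))
  if (any(alt_copies_tumor < 0) || any(alt_copies_normal < 0)) {
    abort("allele copy counts must be >= 0")
  }
  if (any(total_copies_tumor < alt_copies_tumor) ||
      any(total_copies_normal < alt_copies_normal)) {
    abort("total copies must be >= alt copies")
  }
  p <- model$purity
  denom <- p * total_copies_tumor + (1 - p) * total_copies_normal
  if (any(denom <= 0)) {
    abort("homozygous deletion has no allele fraction")
  }
  (p * alt_copies_tumor + (1 - p) * alt_copies_normal) / denom
}

#' Expected VAF bands for a germline het site
#'
#' The three allele-fraction bands a germline-heterozygous site can occupy
#' in the tumor mixture: ref-retained copy-neutral LoH, persistent het, and
#' alt-retained copy-neutral LoH. With `mode = "deletion"` the LoH bands
#' assume single-copy loss instead of copy-neutral loss.
#'
#' @param model A [purity_model()].
#' @param mode `"copy_neutral"` (default) or `"deletion"`.
#' @return Named numeric vector `c(hom_ref_adjusted, het, hom_alt_adjusted)`.
#' @export
vaf_bands <- function(model, mode = c("copy_neutral", "deletion")) {
  mode <- match.arg(mode)
  retained <- if (mode == "copy_neutral") 2L else 1L
  c(
    hom_ref_adjusted = expected_alt_fraction(model, 0, retained),
    het = 0.5,
    hom_alt_adjusted = expected_alt_fraction(model, retained, retained)
  )
}

#' Classify a tumor site against purity-adjusted VAF bands
#'
#' Each site's allele fraction is compared with the three expected bands
#' from [vaf_bands()]. A site is assigned the band strictly within
#' `tolerance`; when no band, or more than one band, lies within tolerance
#' the classes are not separable and the site is `ambiguous`. Two further
#' separability guards reflect what the data can support: when the
#' hom-to-het band separation (p/2 for copy-neutral loss) falls below
#' `tolerance` the LoH classes are unresolvable at this purity and every
#' site is `ambiguous`; and an adjusted-hom assignment additionally
#' requires the allele fraction to sit outside the het binomial noise
#' interval `0.5 +/- 2 * sqrt(0.25 / depth)`, so low-depth noise around
#' 0.5 is never mistaken for allele loss. Sites with zero depth are
#' uninformative (`ambiguous`).
#'
#' @param model A [purity_model()].
#' @param sites Data frame of SNV sites with at least `allele_fraction` and
#'   `depth` columns (see [read_snvs()]).
#' @param tolerance Half-width of each band in VAF units (default 0.10).
#' @param mode LoH mode passed to [vaf_bands()].
#' @return The input tibble with a `site_class` column: one of
#'   `"het"`, `"hom_alt_adjusted"`, `"hom_ref_adjusted"`, `"ambiguous"`.
#' @export
classify_site <- function(model, sites, tolerance = 0.10,
                          mode = c("copy_neutral", "deletion")) {
  mode <- match.arg(mode)
  assert_columns(sites, c("allele_fraction", "depth"), "`sites`")
  bands <- vaf_bands(model, mode)
  separation <- bands[["hom_alt_adjusted"]] - bands[["het"]]
  af <- sites$allele_fraction
  if (separation < tolerance) {
    return(dplyr::mutate(
      as_tibble(sites),
      site_class = rep("ambiguous", length(af))
    ))
  }
  d <- vapply(bands, function(b) abs(af - b), numeric(length(af)))
  if (length(af) == 1) d <- matrix(d, nrow = 1)
  # strict comparison, guarded against floating-point noise so a distance
  # of exactly `tolerance` never qualifies
  within <- d < tolerance - 1e-9
  n_within <- rowSums(within)
  nearest <- names(bands)[max.col(-d, ties.method = "first")]
  cls <- ifelse(n_within == 1, nearest, "ambiguous")
  # depth-aware guard: hom calls must clear the het binomial noise floor
  het_margin <- 2 * sqrt(0.25 / pmax(1, sites$depth))
  noisy_het <- abs(af - 0.5) <= het_margin
  cls[cls %in% c("hom_alt_adjusted", "hom_ref_adjusted") & noisy_het] <- "ambiguous"
  cls[sites$depth == 0] <- "ambiguous"
  dplyr::mutate(as_tibble(sites), site_class = cls)
}
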