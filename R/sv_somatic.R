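# Somatic structural variant identification: paired tumor-vs-normal
# breakpoint subtraction, and tumor-only pseudo-somatic classification
# against a population-presence index.

#' Structural-variant matching configuration
#'
#' @param max_breakpoint_dist Maximum start-breakpoint distance in bp
#'   (default 1000, the standard SV benchmarking reference distance).
#' @param require_same_type Require identical SVTYPE (default TRUE).
#' @param min_size_similarity Minimum length-ratio similarity
#'   min(|a|,|b|)/max(|a|,|b|) in (0, 1] (default 0.7); skipped for BND.
#' @return A list of class `sv_match_config`.
#' @export
sv_match_config <- function(max_breakpoint_dist = 1000,
                            require_same_type = TRUE,
                            min_size_similarity = 0.7) {
  if (max_breakpoint_dist < 0) abort("`max_breakpoint_dist` must be >= 0")
  if (min_size_similarity <= 0 || min_size_similarity > 1) {
    abort("`min_size_similarity` must be in (0, 1]")
  }
  structure(
    list(
      max_breakpoint_dist = max_breakpoint_dist,
      require_same_type = require_same_type,
      min_size_similarity = min_size_similarity
    ),
    class = "sv_match_config"
  )
}

#' Do two SV records match?
#'
#' Records match when they sit on the same chromosome, their start
#' breakpoints lie within `max_breakpoint_dist` (inclusive), their types
#' agree (when required), and their length similarity reaches
#' `min_size_similarity` (BND pairs skip the size check).
#'
#' @param a,b Single-row SV tibbles or lists with `chrom`, `pos`,
#'   `sv_type`, `length`.
#' @param cfg An [sv_match_config()].
#' @return Logical scalar.
#' @export
match_sv <- function(a, b, cfg = sv_match_config()) {
  if (a$chrom != b$chrom) return(FALSE)
  if (abs(a$pos - b$pos) > cfg$max_breakpoint_dist) return(FALSE)
  if (cfg$require_same_type && a$sv_type != b$sv_type) return(FALSE)
  if (a$sv_type == "BND" || b$sv_type == "BND") return(TRUE)
  la <- abs(a$length); lb <- abs(b$length)
  if (la == 0 || lb == 0) return(la == lb)
  min(la, lb) / max(la, lb) >= cfg$min_size_similarity
}

#' Subtract germline SVs to obtain somatic calls
#'
#' Somatic SVs are those present only in the tumor: every tumor record
#' without a matching normal record is somatic. Matching is greedy
#' nearest-first (smallest breakpoint distance first), each normal record
#' consumable once.
#'
#' @param tumor,normal SV tibbles from [read_svs()].
#' @param cfg An [sv_match_config()].
#' @return A list with `somatic` and `shared` tumor-record tibbles and
#'   `normal_only_count`.
#' @export
subtract_somatic <- function(tumor, normal, cfg = sv_match_config()) {
  tumor <- as_tibble(tumor)
  normal <- as_tibble(normal)
  nt <- nrow(tumor)
  nn <- nrow(normal)
  if (nt == 0) {
    return(list(somatic = tumor, shared = tumor, normal_only_count = nn))
  }
  # candidate pairs within distance, ranked by breakpoint distance
  cand <- purrr::map_dfr(seq_len(nt), function(i) {
    ok <- normal$chrom == tumor$chrom[i] &
      abs(normal$pos - tumor$pos[i]) <= cfg$max_breakpoint_dist
    if (cfg$require_same_type) ok <- ok & normal$sv_type == tumor$sv_type[i]
    js <- which(ok)
    if (length(js) == 0) return(NULL)
    keep <- vapply(js, function(j) {
      match_sv(tumor[i, ], normal[j, ], cfg)
    }, TRUE)
    js <- js[keep]
    if (length(js) == 0) return(NULL)
    tibble(ti = i, nj = js, dist = abs(normal$pos[js] - tumor$pos[i]))
  })
  matched_t <- rep(FALSE, nt)
  if (nrow(cand) > 0) {
    cand <- arrange(cand, .data$dist, .data$ti, .data$nj)
    used_n <- rep(FALSE, nn)
    for (r in seq_len(nrow(cand))) {
      i <- cand$ti[r]; j <- cand$nj[r]
      if (!matched_t[i] && !used_n[j]) {
        matched_t[i] <- TRUE
        used_n[j] <- TRUE
      }
    }
    normal_only <- nn - sum(used_n)
  } else {
    normal_only <- nn
  }
  list(
    somatic = tumor[!matched_t, , drop = FALSE],
    shared = tumor[matched_t, , drop = FALSE],
    normal_only_count = normal_only
  )
}

#' Classify tumor-only SVs as pseudo-somatic
#'
#' Looks each tumor SV up in a population-presence annotation by
#' (chrom, pos, sv_type, length). Records with zero population hits are
#' pseudo-somatic; records with hits are excluded; records whose lookup is
#' missing are labeled `unknown` and conservatively kept out of the
#' pseudo-somatic set.
#'
#' @param tumor SV tibble from [read_svs()].
#' @param population Annotation tibble from [read_population_index()].
#' @return The tumor tibble with `population_hits` and `population_state`
#'   (pseudo_somatic / population / unknown).
#' @export
classify_pseudo_somatic <- function(tumor, population) {
  assert_columns(population, c("chrom", "pos", "sv_type", "length", "hits"), "`population`")
  out <- left_join(
    as_tibble(tumor),
    rename(population, population_hits = "hits"),
    by = c("chrom", "pos", "sv_type", "length")
  )
  mutate(out, population_state = case_when(
    is.na(.data$population_hits) ~ "unknown",
    .data$population_hits == 0 ~ "pseudo_somatic",
    TRUE ~ "population"
  ))
}
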