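# Tumor mutational burden from a targeted panel.
#
# Eligible somatic variants are counted over the 1.3 Mb of coding sequence
# the panel evaluates (panel TMB, mutations/Mb) and extrapolated to an
# exome-equivalent TMB through a log10-log10 linear model:
#   eTMB = 10^(-0.944 + 1.397 * log10(pTMB))

#' TMB variant-filter configuration
#'
#' Defaults follow the assay's highest-correlation filter set: coding
#' variants (synonymous and nonsynonymous alike) with more than 3 supporting
#' observations and mutant allele fraction above 5%, after removal of
#' cancer-database hotspots, common germline variants (high population
#' frequency in any database column), and private germline variants flagged
#' by their allele-fraction band.
#'
#' @param min_maf Strict MAF lower bound (default 0.05).
#' @param min_obs Strict lower bound on supporting observations (default 3,
#'   i.e. a variant needs more than 3).
#' @param min_quality Minimum caller confidence score (default 0.75).
#' @param cosmic_max Cancer-database observation count at or above which a
#'   variant is excluded as a recurrent hotspot (default 25).
#' @param pop_freq_max Population-frequency cutoff applied to every `pop_*`
#'   column (default 0.01).
#' @param germline_bands Matrix of MAF intervals treated as private germline
#'   (rows `lo`,`hi`; default `[0.40, 0.60]` and `[0.90, 1.00]`).
#' @param consequences Consequence classes counted as coding.
#' @return A `tmb_filter_config` list.
#' @export
tmb_filter_config <- function(min_maf = 0.05, min_obs = 3L,
                              min_quality = 0.75, cosmic_max = 25L,
                              pop_freq_max = 0.01,
                              germline_bands = rbind(c(0.40, 0.60),
                                                     c(0.90, 1.00)),
                              consequences = c("synonymous", "nonsynonymous",
                                               "splice", "insertion",
                                               "deletion")) {
  if (min_maf <= 0 || min_maf >= 1) stop("min_maf must lie in (0, 1)")
  structure(list(min_maf = min_maf, min_obs = min_obs,
                 min_quality = min_quality, cosmic_max = cosmic_max,
                 pop_freq_max = pop_freq_max, germline_bands = germline_bands,
                 consequences = consequences),
            class = "tmb_filter_config")
}

#' Filter variants eligible for TMB
#'
#' Applies the TMB candidate filters to an annotated variant table and
#' returns the eligible subset in the original order. Missing annotations
#' (`NA` population frequency or cancer-database count) never exclude a
#' variant.
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @param cfg A [tmb_filter_config()].
#' @return The eligible rows of `variants`, with a `filter_tally` attribute
#'   counting removals per rule.
#' @export
filter_tmb_variants <- function(variants, cfg = tmb_filter_config()) {
  validate_variants(variants)
  n <- nrow(variants)
  keep <- rep(TRUE, n)
  tally <- c(consequence = 0L, quality = 0L, n_obs = 0L, maf = 0L,
             cosmic = 0L, population = 0L, private_germline = 0L)
  drop_rule <- function(bad, rule) {
    bad[is.na(bad)] <- FALSE  # missing annotation never excludes
    bad <- bad & keep
    tally[rule] <<- sum(bad)
    keep <<- keep & !bad
  }
  drop_rule(!variants$consequence %in% cfg$consequences, "consequence")
  drop_rule(variants$quality_score < cfg$min_quality, "quality")
  drop_rule(variants$n_obs <= cfg$min_obs, "n_obs")
  drop_rule(variants$maf <= cfg$min_maf, "maf")
  if ("cosmic_n" %in% names(variants))
    drop_rule(!is.na(variants$cosmic_n) & variants$cosmic_n >= cfg$cosmic_max,
              "cosmic")
  pop_cols <- grep("^pop_", names(variants), value = TRUE)
  if (length(pop_cols)) {
    popmax <- do.call(pmax, c(lapply(pop_cols, function(cc) variants[[cc]]),
                              list(na.rm = TRUE)))
    drop_rule(!is.na(popmax) & popmax >= cfg$pop_freq_max, "population")
  }
  in_band <- rep(FALSE, n)
  for (b in seq_len(nrow(cfg$germline_bands)))
    in_band <- in_band | (variants$maf >= cfg$germline_bands[b, 1] &
                            variants$maf <= cfg$germline_bands[b, 2])
  drop_rule(in_band, "private_germline")
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_tally") <- tally
  out
}

#' Panel TMB
#'
#' @param n_eligible Eligible variant count.
#' @param coding_panel_mb Coding territory of the panel in Mb (default 1.3).
#' @return Mutations per Mb.
#' @export
compute_ptmb <- function(n_eligible, coding_panel_mb = 1.3) {
  if (coding_panel_mb <= 0) stop("coding_panel_mb must be > 0")
  if (n_eligible < 0) stop("n_eligible must be >= 0")
  n_eligible / coding_panel_mb
}

#' Exome-equivalent TMB model
#'
#' @param intercept,slope Coefficients of the log10-log10 regression
#'   (defaults -0.944 and 1.397, the shipped assay model).
#' @param coding_panel_mb Panel coding size in Mb (default 1.3).
#' @return An `etmb_model` list.
#' @export
etmb_model <- function(intercept = -0.944, slope = 1.397,
                       coding_panel_mb = 1.3) {
  if (slope <= 0) stop("slope must be > 0")
  structure(list(intercept = intercept, slope = slope,
                 coding_panel_mb = coding_panel_mb), class = "etmb_model")
}

#' Convert panel TMB to exome-equivalent TMB
#'
#' `etmb = 10^(intercept + slope * log10(ptmb))`; a mutation-free panel
#' (`ptmb = 0`) maps to 0 by convention since the log model is undefined
#' there.
#'
#' @param ptmb Panel TMB (mutations/Mb), vectorized; must be >= 0.
#' @param model An [etmb_model()].
#' @return Exome-equivalent TMB (mutations/Mb).
#' @export
ptmb_to_etmb <- function(ptmb, model = etmb_model()) {
  if (any(ptmb < 0)) stop("ptmb must be >= 0")
  ifelse(ptmb == 0, 0, 10^(model$intercept + model$slope * log10(ptmb)))
}

#' Full panel-TMB computation from a variant table
#'
#' @param variants Variant data frame.
#' @param cfg A [tmb_filter_config()].
#' @param model An [etmb_model()].
#' @return List: `n_eligible`, `ptmb`, `etmb`, `filter_tally`.
#' @export
compute_tmb <- function(variants, cfg = tmb_filter_config(),
                        model = etmb_model()) {
  elig <- filter_tmb_variants(variants, cfg)
  ptmb <- compute_ptmb(nrow(elig), model$coding_panel_mb)
  list(n_eligible = nrow(elig), ptmb = ptmb,
       etmb = ptmb_to_etmb(ptmb, model),
       filter_tally = attr(elig, "filter_tally"))
}

#' Fit the exome-equivalent regression
#'
#' Ordinary least squares of `log10(wes_tmb)` on `log10(ptmb)` over paired
#' panel / whole-exome TMB measurements. Non-positive pairs cannot enter the
#' log model and are excluded with a warning.
#'
#' @param ptmb,wes_tmb Paired TMB values (mutations/Mb).
#' @param coding_panel_mb Recorded on the returned model (default 1.3).
#' @return An [etmb_model()] with fitted `intercept` and `slope`.
#' @export
fit_etmb_model <- function(ptmb, wes_tmb, coding_panel_mb = 1.3) {
  stopifnot(length(ptmb) == length(wes_tmb))
  ok <- ptmb > 0 & wes_tmb > 0 & is.finite(ptmb) & is.finite(wes_tmb)
  if (any(!ok))
    warning(sum(!ok), " pair(s) with non-positive TMB excluded from the fit")
  if (sum(ok) < 3L) stop("need at least 3 usable pairs")
  fit <- stats::lm(log10(wes_tmb[ok]) ~ log10(ptmb[ok]))
  etmb_model(intercept = unname(stats::coef(fit)[1]),
             slope = unname(stats::coef(fit)[2]),
             coding_panel_mb = coding_panel_mb)
}

#' Tiered reporting filter for clinical variants
#'
#' Reporting requires 4 supporting observations and MAF above 0.4% for
#' variants in the high-actionability tier, and 6 observations with MAF
#' above 5% otherwise. Variants flagged germline are suppressed, except
#' deleterious BRCA1/BRCA2 variants, which are reported regardless of
#' germline status when they pass the thresholds.
#'
#' @param variants Variant data frame with annotation columns `tier`
#'   (`"high"` or `"standard"`), and optionally `gene`, `is_germline`,
#'   `is_deleterious` (logical).
#' @param high_min_obs,high_min_maf Thresholds for the high tier (4 and
#'   0.004).
#' @param std_min_obs,std_min_maf Thresholds for all other variants (6 and
#'   0.05).
#' @return The reportable rows of `variants`.
#' @export
apply_reporting_filters <- function(variants, high_min_obs = 4L,
                                    high_min_maf = 0.004, std_min_obs = 6L,
                                    std_min_maf = 0.05) {
  if (!"tier" %in% names(variants)) stop("variants must carry a 'tier' column")
  bad <- setdiff(unique(variants$tier), c("high", "standard"))
  if (length(bad)) stop("unknown actionability tier: ", paste(bad, collapse = ", "))
  high <- variants$tier == "high"
  pass <- ifelse(high,
                 variants$n_obs >= high_min_obs & variants$maf > high_min_maf,
                 variants$n_obs >= std_min_obs & variants$maf > std_min_maf)
  germ <- if ("is_germline" %in% names(variants))
    !is.na(variants$is_germline) & variants$is_germline else rep(FALSE, nrow(variants))
  brca_rescue <- rep(FALSE, nrow(variants))
  if (all(c("gene", "is_deleterious") %in% names(variants)))
    brca_rescue <- variants$gene %in% c("BRCA1", "BRCA2") &
      !is.na(variants$is_deleterious) & variants$is_deleterious
  variants[pass & (!germ | brca_rescue), , drop = FALSE]
}

#' Limit of blank (CLSI EP17-A, nonparametric)
#'
#' Sorts the blank-sample measurements and takes the value at rank
#' `0.5 + (percentile/100) * n`, linearly interpolating between bracketing
#' order statistics and clamping to the observed extremes.
#'
#' @param values Measurements from analyte-free samples (e.g. exome-
#'   equivalent TMB of noncancerous tissue).
#' @param percentile Percentile (default 95).
#' @return List: `n`, `rank`, `lob`.
#' @export
compute_lob <- function(values, percentile = 95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 blank measurements")
  s <- sort(values)
  rank <- 0.5 + (percentile / 100) * n
  lo <- floor(rank); hi <- ceiling(rank)
  lob <- if (lo < 1) s[1] else if (hi > n) s[n] else
    s[lo] + (rank - lo) * (s[min(hi, n)] - s[lo])
  list(n = n, rank = rank, lob = lob)
}
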