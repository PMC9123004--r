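# Validation statistics for diagnostic concordance and precision studies.

#' Positive and negative percent agreement
#'
#' @param tp,fn,tn,fp Concordance counts against the reference method.
#' @return List with `ppa` and `npa` in percent (full precision; `NA` when a
#'   metric's denominator is zero — explicitly undefined, never 0).
#' @export
ppa_npa <- function(tp, fn, tn = 0L, fp = 0L) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  list(ppa = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       npa = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Wilson score confidence interval
#'
#' Wilson's score interval for a binomial proportion, with the continuity
#' correction applied by default; bounds are clamped to `[0, 1]`.
#'
#' @param k Successes.
#' @param n Trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @param continuity Apply the continuity correction (default TRUE).
#' @return Numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95, continuity = TRUE) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  if (!continuity) {
    c0 <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- c0 - hw; hi <- c0 + hw
  } else {
    lo <- (2 * n * p + z^2 - 1 -
             z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
    hi <- (2 * n * p + z^2 + 1 +
             z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
    if (p == 0) lo <- 0
    if (p == 1) hi <- 1
  }
  c(lo = max(0, lo), hi = min(1, hi))
}

#' Average pairwise agreement across replicates
#'
#' For every sample, every unordered pair of replicate binary calls is
#' compared in both directions (each replicate in turn serving as the
#' reference); directional positive agreement is defined when the reference
#' replicate is positive, negative agreement when it is negative. All defined
#' directional agreements are averaged across pairs and samples.
#'
#' @param calls Data frame with columns `sample`, `replicate`, `call`
#'   (logical or `"positive"`/`"negative"`).
#' @return List: `avg_positive` and `avg_negative`, in percent.
#' @export
average_agreement <- function(calls) {
  x <- calls$call
  if (!is.logical(x)) x <- x %in% c("positive", "MSI-H", "TRUE", "amplified")
  pos_num <- 0; pos_den <- 0; neg_num <- 0; neg_den <- 0
  for (s in unique(calls$sample)) {
    v <- x[calls$sample == s]
    if (length(v) < 2L) next
    pr <- utils::combn(length(v), 2)
    for (j in seq_len(ncol(pr))) {
      a <- v[pr[1, j]]; b <- v[pr[2, j]]
      for (ref in list(c(a, b), c(b, a))) {
        if (ref[1]) { pos_den <- pos_den + 1; pos_num <- pos_num + ref[2] }
        else { neg_den <- neg_den + 1; neg_num <- neg_num + !ref[2] }
      }
    }
  }
  list(avg_positive = if (pos_den > 0) 100 * pos_num / pos_den else NA_real_,
       avg_negative = if (neg_den > 0) 100 * neg_num / neg_den else NA_real_)
}

#' Variance-component coefficients of variation
#'
#' Decomposes replicate-to-replicate variability of a quantitative result
#' (e.g. exome-equivalent TMB) into nested random components — between-site,
#' between-operator, between-day, optionally between-instrument, and
#' within-run — by the closed-form nested-ANOVA method of moments, and
#' reports each component as a CV (%) of the grand mean.
#'
#' Mean squares are computed at every nesting depth (sum of squares of group
#' means around their parent-group mean, on degrees of freedom `G_k -
#' G_{k-1}`); components follow the recursion `sigma_k^2 = (MS_k -
#' MS_{k+1}) / m_k`, with `m_k` the (average) number of observations per
#' depth-`k` group and `MS_{K+1}` the within-cell residual. Negative moment
#' estimates are truncated to zero; a factor with fewer than two observed
#' levels inside any parent is marked inestimable (`NA`). The design is
#' assumed (near-)balanced, as in the shipped precision-study layout.
#'
#' @param values Data frame with a numeric `value` column and factor columns;
#'   nesting order outermost to innermost is given by `factors`.
#' @param factors Character vector of column names, outermost first
#'   (default `c("site", "operator", "day")`; add `"instrument"` to estimate
#'   it as a separate component).
#' @return List: `cv` named vector (one entry per factor plus `within_run`
#'   and `overall`), `variance` the matching variance components, and
#'   `grand_mean`.
#' @export
variance_component_cv <- function(values,
                                  factors = c("site", "operator", "day")) {
  stopifnot("value" %in% names(values))
  y <- values$value
  gm <- mean(y)
  K <- length(factors)
  grp <- lapply(seq_len(K), function(k)
    interaction(values[factors[seq_len(k)]], drop = TRUE, lex.order = TRUE))
  # residual: pooled within-cell variance
  cell <- grp[[K]]
  ns <- tapply(y, cell, length)
  ms <- numeric(K + 1L)
  df_resid <- sum(ns - 1L)
  ms[K + 1L] <- if (df_resid > 0)
    sum(tapply(y, cell, function(v) sum((v - mean(v))^2))) / df_resid
  else NA_real_
  g_counts <- c(1L, vapply(grp, nlevels, 0L))
  estimable <- logical(K)
  for (k in seq_len(K)) {
    gk <- grp[[k]]
    df <- g_counts[k + 1L] - g_counts[k]
    estimable[k] <- df >= 1L
    if (!estimable[k]) { ms[k] <- NA_real_; next }
    nk <- tapply(y, gk, length)
    mk <- tapply(y, gk, mean)
    pidx <- tapply(seq_along(y), gk, `[`, 1L)    # one row of each group
    pmean <- if (k == 1L) rep(gm, length(mk))
             else tapply(y, grp[[k - 1L]], mean)[as.character(grp[[k - 1L]][pidx])]
    ms[k] <- sum(nk * (mk - pmean)^2) / df
  }
  m_per_group <- nrow(values) / vapply(grp, nlevels, 0L)
  comps <- stats::setNames(rep(NA_real_, K), factors)
  for (k in seq_len(K)) {
    nxt <- ms[k + 1L]
    if (estimable[k] && !is.na(nxt))
      comps[k] <- max(0, (ms[k] - nxt) / m_per_group[k])
  }
  comp_all <- c(comps,
                within_run = if (is.na(ms[K + 1L])) NA_real_
                             else max(0, ms[K + 1L]))
  total <- sum(comp_all, na.rm = TRUE)
  cv <- 100 * sqrt(comp_all) / gm
  list(cv = c(cv, overall = 100 * sqrt(total) / gm),
       variance = comp_all, grand_mean = gm)
}

#' Observed tumor purity of a dilution replicate
#'
#' The median ratio of each shared variant's MAF in the diluted replicate to
#' its MAF in the undiluted replicate, scaled by the pathological purity of
#' the undiluted specimen. Variants with zero undiluted MAF are excluded.
#'
#' @param diluted_mafs,undiluted_mafs Matched MAF vectors (same variants).
#' @param pathological_purity Purity of the undiluted specimen from
#'   pathologic review (default 1).
#' @return Purity fraction.
#' @export
observed_dilution_purity <- function(diluted_mafs, undiluted_mafs,
                                     pathological_purity = 1) {
  stopifnot(length(diluted_mafs) == length(undiluted_mafs))
  ok <- !is.na(undiluted_mafs) & undiluted_mafs > 0 & !is.na(diluted_mafs)
  if (!any(ok)) stop("no shared variant with nonzero undiluted MAF")
  stats::median(diluted_mafs[ok] / undiluted_mafs[ok]) * pathological_purity
}

#' Clonality score
#'
#' Median somatic MAF divided by the pathologic tumor purity; 0.5 for a fully
#' clonal heterozygous diploid tumor.
#'
#' @param mafs Somatic variant MAFs (non-empty).
#' @param pathological_purity Purity fraction (> 0).
#' @return Numeric score.
#' @export
clonality_score <- function(mafs, pathological_purity) {
  if (!length(mafs)) stop("no variant MAFs supplied")
  if (is.na(pathological_purity) || pathological_purity <= 0)
    stop("pathological purity must be > 0")
  stats::median(mafs) / pathological_purity
}
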