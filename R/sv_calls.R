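# Simplified coverage-based amplification calling (Digital Karyotyping
# style) and discordant-read-pair translocation calling (PARE style).

#' Estimate tumor purity from somatic mutation allele fractions
#'
#' Under a diploid-heterozygous model a clonal somatic variant is present at
#' MAF = purity / 2, so purity is estimated as twice the median somatic MAF,
#' clamped to 1.
#'
#' @param somatic_mafs Numeric MAFs of clonal-candidate somatic variants.
#' @param min_variants Minimum usable variants before the estimate is
#'   attempted (default 5).
#' @return Purity in (0, 1], or `NA` (undetermined) with fewer than
#'   `min_variants` usable values.
#' @export
estimate_purity <- function(somatic_mafs, min_variants = 5L) {
  m <- somatic_mafs[!is.na(somatic_mafs) & somatic_mafs > 0]
  if (length(m) < min_variants) return(NA_real_)
  min(1, 2 * stats::median(m))
}

#' Build a panel-of-normals baseline
#'
#' @param control_profiles Matrix of normalized coverage, ROIs x control
#'   samples (>= 2 columns; 20 FFPE noncancerous controls in routine use).
#' @param low_coverage_threshold Baseline mean below which an ROI is masked
#'   (default 0.1).
#' @return List: `mean`, `sd` (per ROI), `low_mask` (logical).
#' @export
normal_baseline <- function(control_profiles, low_coverage_threshold = 0.1) {
  control_profiles <- as.matrix(control_profiles)
  if (ncol(control_profiles) < 2L) stop("need at least 2 control profiles")
  list(mean = rowMeans(control_profiles),
       sd = apply(control_profiles, 1, stats::sd),
       low_mask = rowMeans(control_profiles) < low_coverage_threshold)
}

#' Call gene amplifications from normalized coverage
#'
#' Per ROI, the coverage ratio against the baseline mean is converted to a
#' purity-adjusted copy number `CN = (2 r - 2 (1 - p)) / p` and a fold change
#' `CN / 2`. ROIs that are baseline-masked, or whose deviation from the
#' baseline is insignificant under a z-test at `alpha`, are excluded. A gene
#' is amplified when the fold change exceeds its gene-specific threshold in
#' more than 25% of evaluated ROIs. With undetermined purity, a gene whose
#' rule would pass at a hypothetical 20% purity is reported indeterminate.
#'
#' @param sample_coverage Numeric vector of the sample's normalized coverage
#'   per ROI.
#' @param genes Character grouping label per ROI.
#' @param baseline From [normal_baseline()].
#' @param purity Tumor purity fraction, or `NA` when undetermined.
#' @param thresholds Named per-gene fold-change cutoffs (default 2 for every
#'   gene).
#' @param alpha Significance level of the deviation z-test (default 0.01;
#'   `NA` disables the test so every unmasked ROI is evaluated).
#' @param min_fraction Fraction of evaluated ROIs that must exceed the
#'   threshold (default 0.25, strict).
#' @return Data frame per gene: `gene`, `n_evaluated`, `fraction_above`,
#'   `median_fold_change`, `status` (`amplified` / `not_amplified` /
#'   `indeterminate` / `no_call`).
#' @export
call_amplification <- function(sample_coverage, genes, baseline, purity,
                               thresholds = NULL, alpha = 0.01,
                               min_fraction = 0.25) {
  stopifnot(length(sample_coverage) == length(genes),
            length(baseline$mean) == length(genes))
  gene_set <- unique(genes)
  if (is.null(thresholds))
    thresholds <- stats::setNames(rep(2, length(gene_set)), gene_set)
  z <- (sample_coverage - baseline$mean) / ifelse(baseline$sd > 0,
                                                  baseline$sd, Inf)
  # alpha = NA disables the deviation test (keeps all unmasked ROIs evaluable)
  insignificant <- if (is.na(alpha)) rep(FALSE, length(z))
                   else abs(z) < stats::qnorm(1 - alpha / 2)
  masked <- baseline$low_mask | insignificant
  fold <- function(p) {
    r <- sample_coverage / baseline$mean
    cn <- (2 * r - 2 * (1 - p)) / p
    cn / 2
  }
  rule <- function(fc, g) {
    f <- fc[genes == g & !masked]
    if (!length(f)) return(NULL)
    list(n = length(f), frac = mean(f > thresholds[[g]]),
         med = stats::median(f))
  }
  do.call(rbind, lapply(gene_set, function(g) {
    if (!any(genes == g & !masked))
      return(data.frame(gene = g, n_evaluated = 0L, fraction_above = NA_real_,
                        median_fold_change = NA_real_, status = "no_call"))
    if (is.na(purity)) {
      hyp <- rule(fold(0.20), g)
      status <- if (hyp$frac > min_fraction) "indeterminate" else "not_amplified"
      return(data.frame(gene = g, n_evaluated = hyp$n,
                        fraction_above = hyp$frac,
                        median_fold_change = hyp$med, status = status))
    }
    r <- rule(fold(purity), g)
    data.frame(gene = g, n_evaluated = r$n, fraction_above = r$frac,
               median_fold_change = r$med,
               status = if (r$frac > min_fraction) "amplified" else "not_amplified")
  }))
}

#' Collect discordant read pairs into breakpoint clusters
#'
#' Retains pairs whose mates map more than `max_insert` bp apart (default
#' 2 kb), to different chromosomes, or in improper orientation, after
#' removing low-mapping-quality reads. Retained pairs are greedily clustered
#' by breakpoint proximity on both sides.
#'
#' @param reads Read-record data frame (one row per read; mate fields
#'   populated).
#' @param max_insert Intra-chromosomal distance above which a pair is
#'   discordant (default 2000, strict).
#' @param min_mapq Minimum mapping quality (default 30).
#' @param window Clustering window in bp (default 500).
#' @return Data frame of clusters: `chrom_a`, `pos_a`, `chrom_b`, `pos_b`
#'   (cluster medians), `n_support` (distinct fragments).
#' @export
collect_discordant_pairs <- function(reads, max_insert = 2000L,
                                     min_mapq = 30L, window = 500L) {
  keep <- reads$mapq >= min_mapq &
    (reads$chrom != reads$mate_chrom |
       abs(reads$mate_pos - reads$pos) > max_insert |
       !reads$is_proper_pair)
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      n_support = integer()))
  # orient each pair deterministically, deduplicate fragments by coordinates
  swap <- r$chrom > r$mate_chrom | (r$chrom == r$mate_chrom & r$pos > r$mate_pos)
  ca <- ifelse(swap, r$mate_chrom, r$chrom)
  pa <- ifelse(swap, r$mate_pos, r$pos)
  cb <- ifelse(swap, r$chrom, r$mate_chrom)
  pb <- ifelse(swap, r$pos, r$mate_pos)
  dup <- duplicated(paste(ca, pa, cb, pb))
  ca <- ca[!dup]; pa <- pa[!dup]; cb <- cb[!dup]; pb <- pb[!dup]
  out <- list()
  for (key in unique(paste(ca, cb))) {
    sel <- paste(ca, cb) == key
    x <- pa[sel]; y <- pb[sel]
    ord <- order(x, y)
    x <- x[ord]; y <- y[ord]
    cl <- integer(length(x)); cur <- 1L; cl[1] <- 1L
    if (length(x) > 1L) for (i in 2:length(x)) {
      prev <- which(cl == cur)
      if (x[i] - max(x[prev]) <= window &&
          min(abs(y[i] - y[prev])) <= window) cl[i] <- cur
      else { cur <- cur + 1L; cl[i] <- cur }
    }
    for (g in unique(cl)) {
      sel2 <- cl == g
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = ca[sel][1], pos_a = as.integer(stats::median(x[sel2])),
        chrom_b = cb[sel][1], pos_b = as.integer(stats::median(y[sel2])),
        n_support = sum(sel2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Call translocations from discordant-pair clusters
#'
#' A cluster is reported as a translocation only when both breakpoints fall
#' in annotated genes, the joined segments maintain a coding strand (5'->3'
#' continuity given the gene strands), the event is absent from the
#' germline/noncancerous control database, and it is supported by at least
#' `min_support` distinct fragments.
#'
#' @param clusters Data frame from [collect_discordant_pairs()].
#' @param gene_annotation Interval data frame with additional columns `gene`
#'   and `strand` (`"+"`/`"-"`); positions 0-based half-open.
#' @param control_db Optional data frame of known benign events with columns
#'   `gene_a`, `gene_b` (order-insensitive match).
#' @param min_support Minimum distinct supporting fragments (default 5).
#' @return Data frame of reported calls: `gene_a`, `gene_b`, breakpoints,
#'   `n_support`, `fusion_productive`.
#' @export
call_translocation <- function(clusters, gene_annotation, control_db = NULL,
                               min_support = 5L) {
  if (is.null(clusters) || !nrow(clusters))
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      n_support = integer(), fusion_productive = logical()))
  annotate <- function(chrom, pos) {
    hit <- which(gene_annotation$chrom == chrom &
                   gene_annotation$start <= pos & pos < gene_annotation$end)
    if (!length(hit)) return(c(NA_character_, NA_character_))
    c(gene_annotation$gene[hit[1]], gene_annotation$strand[hit[1]])
  }
  aa <- t(mapply(annotate, clusters$chrom_a, clusters$pos_a))
  bb <- t(mapply(annotate, clusters$chrom_b, clusters$pos_b))
  gene_a <- aa[, 1]; strand_a <- aa[, 2]
  gene_b <- bb[, 1]; strand_b <- bb[, 2]
  productive <- !is.na(strand_a) & !is.na(strand_b) & strand_a == strand_b
  in_control <- rep(FALSE, nrow(clusters))
  if (!is.null(control_db) && nrow(control_db)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    in_control <- key(gene_a, gene_b) %in%
      key(control_db$gene_a, control_db$gene_b)
  }
  keep <- !is.na(gene_a) & !is.na(gene_b) & gene_a != gene_b & productive &
    !in_control & clusters$n_support >= min_support
  data.frame(gene_a = gene_a, gene_b = gene_b,
             chrom_a = clusters$chrom_a, pos_a = clusters$pos_a,
             chrom_b = clusters$chrom_b, pos_b = clusters$pos_b,
             n_support = clusters$n_support,
             fusion_productive = productive,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
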