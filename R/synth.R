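# Synthetic-data generators. Every generator is deterministic under `seed`
# and returns the ground truth alongside the data, so downstream callers can
# be tested against planted answers.

.other_bases <- function(base) setdiff(c("A", "C", "G", "T"), base)

rand_seq <- function(n, exclude = NULL) {
  pool <- setdiff(c("A", "C", "G", "T"), exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic mononucleotide tract panel
#'
#' Random tract definitions (reference lengths 13-30 bp, 10-bp flanking
#' seeds that never extend the repeat) spaced along one chromosome.
#'
#' @param n Number of tracts (default 68, the shipped panel size).
#' @param seed RNG seed.
#' @return List of [tract_definition()] objects.
#' @export
simulate_tract_panel <- function(n = 68L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- sample(c("A", "C", "G", "T"), 1)
    len <- sample(13:30, 1)
    start <- 1000L * i
    tract_definition("chr1", start, base, len,
                     seed5 = paste0(rand_seq(9, exclude = base),
                                    sample(.other_bases(base), 1)),
                     seed3 = paste0(sample(.other_bases(base), 1),
                                    rand_seq(9, exclude = base)),
                     id = sprintf("tract%02d", i))
  })
}

#' Simulate reads over one tract
#'
#' Emulates a tumor/normal DNA mixture at a single mononucleotide tract: a
#' fraction `purity * unstable_fraction` of fragments carries the planted
#' deletion; symmetric +/-1 bp PCR stutter is applied on top at
#' `stutter_rate` per read (deletion bias configurable). All reads carry
#' MAPQ 60, full-length match CIGARs, and randomized mate positions so
#' coordinate deduplication keeps distinct fragments distinct.
#'
#' @param tract A [tract_definition()].
#' @param depth Number of fragments (default 500).
#' @param purity Tumor fraction of the mixture, in `[0, 1]`.
#' @param unstable_offset Planted deletion in bp (negative; default -3).
#' @param unstable_fraction Fraction of tumor fragments carrying the planted
#'   allele (default 0.6).
#' @param stutter_rate Per-read probability of a 1-bp slippage (default
#'   0.05; must be < 0.5).
#' @param deletion_bias Probability that a stutter event shortens rather
#'   than lengthens the tract (default 0.5, symmetric).
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @return List: `reads` (read-record data frame) and `truth` (planted
#'   parameters and the expected unstable flag).
#' @export
simulate_tract_reads <- function(tract, depth = 500L, purity = 1,
                                 unstable_offset = -3L,
                                 unstable_fraction = 0.6,
                                 stutter_rate = 0.05, deletion_bias = 0.5,
                                 seed = NULL) {
  stopifnot(purity >= 0, purity <= 1, stutter_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  is_tumor <- stats::runif(depth) < purity
  planted <- is_tumor & stats::runif(depth) < unstable_fraction
  offs <- ifelse(planted, unstable_offset, 0L)
  stut <- stats::runif(depth) < stutter_rate
  offs <- offs + ifelse(stut,
                        ifelse(stats::runif(depth) < deletion_bias, -1L, 1L),
                        0L)
  pad5 <- sample(9:15, depth, replace = TRUE)
  pad3 <- sample(9:15, depth, replace = TRUE)
  flank_pool <- .other_bases(tract$base)
  pad_strings <- function(lens) {
    chars <- paste(sample(flank_pool, sum(lens), replace = TRUE),
                   collapse = "")
    ends <- cumsum(lens)
    substring(chars, ends - lens + 1L, ends)
  }
  lpad <- pad_strings(pad5)
  rpad <- pad_strings(pad3)
  seqs <- paste0(lpad, tract$seed5,
                 strrep(tract$base, pmax(tract$ref_length + offs, 0L)),
                 tract$seed3, rpad)
  pos <- tract$start - nchar(tract$seed5) - pad5
  reads <- read_records(
    read_id = sprintf("%s_r%04d", tract$id, seq_len(depth)),
    chrom = tract$chrom, pos = pos,
    cigar = paste0(nchar(seqs), "M"), mapq = 60L, sequence = seqs,
    mate_pos = pos + sample(150:2000, depth, replace = TRUE),
    softclip_total = 0L)
  expected_frac <- purity * unstable_fraction
  list(reads = reads,
       truth = list(tract_id = tract$id, planted_offset = unstable_offset,
                    planted_fraction = expected_frac,
                    planted_reads = sum(planted),
                    expect_unstable = expected_frac >= 0.08))
}

#' Simulate a whole MSI sample over a tract panel
#'
#' Plants instability (the same offset/fractions) in the first
#' `n_unstable` tracts of the panel; remaining tracts receive pure
#' reference-length reads plus stutter.
#'
#' @param panel List of tracts from [simulate_tract_panel()].
#' @param n_unstable Number of tracts planted unstable.
#' @param seed RNG seed (per-tract seeds are derived from it).
#' @inheritParams simulate_tract_reads
#' @return List: `reads_by_tract` (list of read-record frames, one per
#'   tract) and `truth`.
#' @export
simulate_msi_sample <- function(panel, n_unstable, depth = 500L, purity = 1,
                                unstable_offset = -3L, unstable_fraction = 0.6,
                                stutter_rate = 0.05, seed = 1L) {
  set.seed(seed)
  tract_seeds <- sample.int(.Machine$integer.max, length(panel))
  reads <- lapply(seq_along(panel), function(i) {
    simulate_tract_reads(panel[[i]], depth = depth, purity = purity,
                         unstable_offset = unstable_offset,
                         unstable_fraction = if (i <= n_unstable)
                           unstable_fraction else 0,
                         stutter_rate = stutter_rate,
                         seed = tract_seeds[i])$reads
  })
  list(reads_by_tract = reads,
       truth = list(n_unstable = n_unstable, purity = purity,
                    expect_msih = n_unstable > 10L))
}

# Signature presets: canonical-class probabilities and flank base
# composition. The MMR preset concentrates on C>T / T>C in an A-rich flank;
# the POLE-like preset is C>A dominant in a T-rich flank; UV-like is C>T in
# a pyrimidine-rich flank; flat is uniform everywhere.
signature_presets <- function() {
  cls <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  list(
    flat = list(class_probs = stats::setNames(rep(1 / 6, 6), cls),
                flank_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
    mmr = list(class_probs = stats::setNames(
                 c(0.02, 0.02, 0.55, 0.02, 0.35, 0.04), cls),
               flank_probs = c(A = 0.55, C = 0.15, G = 0.15, T = 0.15)),
    pole_like = list(class_probs = stats::setNames(
                       c(0.65, 0.05, 0.20, 0.05, 0.03, 0.02), cls),
                     flank_probs = c(A = 0.10, C = 0.15, G = 0.15, T = 0.60)),
    uv_like = list(class_probs = stats::setNames(
                     c(0.02, 0.02, 0.85, 0.02, 0.05, 0.04), cls),
                   flank_probs = c(A = 0.10, C = 0.40, G = 0.10, T = 0.40)))
}

#' Simulate a substitution catalog with a known context signature
#'
#' Events are emitted on the canonical (pyrimidine-reference) strand; window
#' flank bases are drawn i.i.d. from the preset's base composition, so the
#' triplet probability at any flank-only position is the product of base
#' probabilities and trained PWM entries have analytically known
#' expectations. `revcomp_fraction` optionally flips a share of events to
#' the purine strand to exercise canonicalization.
#'
#' @param n Number of substitutions.
#' @param signature `"mmr"`, `"flat"`, `"uv_like"`, or `"pole_like"`.
#' @param revcomp_fraction Share of events emitted reverse-complemented
#'   (default 0).
#' @param seed RNG seed.
#' @return List: `events` (data frame `ref`, `alt`, `window11`) and `truth`
#'   (the preset's class and flank probabilities).
#' @export
simulate_mutation_catalog <- function(n, signature = "flat",
                                      revcomp_fraction = 0, seed = 1L) {
  preset <- signature_presets()[[match.arg(signature,
                                           names(signature_presets()))]]
  set.seed(seed)
  cls <- sample(names(preset$class_probs), n, replace = TRUE,
                prob = preset$class_probs)
  ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
  flanks <- matrix(sample(names(preset$flank_probs), 10L * n, replace = TRUE,
                          prob = preset$flank_probs), nrow = n)
  window <- paste0(apply(flanks[, 1:5, drop = FALSE], 1, paste0, collapse = ""),
                   ref,
                   apply(flanks[, 6:10, drop = FALSE], 1, paste0, collapse = ""))
  if (revcomp_fraction > 0) {
    flip <- stats::runif(n) < revcomp_fraction
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    window[flip] <- revcomp(window[flip])
  }
  list(events = data.frame(ref = ref, alt = alt, window11 = window,
                           stringsAsFactors = FALSE),
       truth = preset)
}

#' Simulate an exon catalog
#'
#' Exon intervals on one chromosome with gamma-distributed lengths
#' (mean ~1.5 kb) separated by intergenic gaps; default settings give a
#' ~30 Mb catalog.
#'
#' @param n_exons Number of exons (default 20000).
#' @param mean_len Mean exon length in bp (default 1500).
#' @param seed RNG seed.
#' @return Interval data frame.
#' @export
simulate_exon_catalog <- function(n_exons = 20000L, mean_len = 1500,
                                  seed = 1L) {
  set.seed(seed)
  lens <- pmax(50L, as.integer(stats::rgamma(n_exons, shape = 3,
                                             scale = mean_len / 3)))
  gaps <- as.integer(stats::rexp(n_exons, rate = 1 / 2000))
  starts <- cumsum(as.numeric(gaps)) + c(0, cumsum(as.numeric(lens)))[1:n_exons]
  genomic_intervals("chr1", starts, starts + lens,
                    sprintf("exon%05d", seq_len(n_exons)))
}

#' Simulate a weighted pan-cancer tumor cohort
#'
#' Cancer types are drawn from the metastatic-population weights; each
#' tumor's exome TMB target is drawn from a per-type log-normal (default
#' median 4 mutations/Mb, log10-sd 0.6, with melanoma and lung medians
#' doubled); qualifying mutation counts are Poisson around
#' `target * exome_mb`, positions uniform over the exon catalog, MAFs
#' uniform in `[0.1, 0.9]`.
#'
#' @param n_tumors Cohort size.
#' @param exons Exon catalog interval data frame.
#' @param weights Named type weights (default [population_weights()]).
#' @param median_tmb Baseline per-type median TMB in mutations/Mb
#'   (default 4).
#' @param log10_sd Log10-scale standard deviation (default 0.6).
#' @param boosted_types Types whose median is doubled (default melanoma and
#'   lung).
#' @param exome_mb Reference exome size in Mb (default 33.4).
#' @param synonymous_fraction Extra synonymous mutations as a fraction of
#'   the qualifying count (default 0.1; these never count toward TMB).
#' @param seed RNG seed.
#' @return List of tumor catalogs; each is a list with `tumor_id`,
#'   `cancer_type`, `mutations` (data frame `chrom`, `pos`, `maf`,
#'   `consequence`), `exome_mb`, and `target_tmb` (the drawn truth).
#' @export
simulate_tumor_cohort <- function(n_tumors, exons,
                                  weights = population_weights(),
                                  median_tmb = 4, log10_sd = 0.6,
                                  boosted_types = c("melanoma", "lung"),
                                  exome_mb = 33.4,
                                  synonymous_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  if (n_tumors == 0L) return(list())
  types <- sample(names(weights), n_tumors, replace = TRUE, prob = weights)
  medians <- ifelse(types %in% boosted_types, 2 * median_tmb, median_tmb)
  target <- 10^(stats::rnorm(n_tumors, mean = log10(medians), sd = log10_sd))
  lens <- exons$end - exons$start
  cumlen <- cumsum(as.numeric(lens))
  total <- cumlen[length(cumlen)]
  draw_pos <- function(k) {
    u <- ceiling(stats::runif(k) * total)        # 1..total over exonic bases
    i <- findInterval(u - 1, cumlen) + 1L        # exon containing base u
    exons$start[i] + (u - c(0, cumlen)[i])       # 1-based genomic position
  }
  lapply(seq_len(n_tumors), function(j) {
    n_q <- stats::rpois(1, target[j] * exome_mb)
    n_s <- stats::rpois(1, synonymous_fraction * target[j] * exome_mb)
    k <- n_q + n_s
    mut <- if (k > 0)
      data.frame(chrom = "chr1", pos = as.integer(draw_pos(k)),
                 maf = stats::runif(k, 0.1, 0.9),
                 consequence = c(rep("nonsynonymous", n_q),
                                 rep("synonymous", n_s)),
                 stringsAsFactors = FALSE)
    else
      data.frame(chrom = character(), pos = integer(), maf = numeric(),
                 consequence = character(), stringsAsFactors = FALSE)
    list(tumor_id = sprintf("tumor%05d", j), cancer_type = types[j],
         mutations = mut, exome_mb = exome_mb, target_tmb = target[j])
  })
}

#' Simulate normalized coverage profiles with planted amplifications
#'
#' Control (panel-of-normals) profiles are log-normal around 1; the tumor
#' sample's ROIs in amplified genes are scaled by the expected mixture ratio
#' `(p CN + 2 (1 - p)) / 2`.
#'
#' @param genes Character vector of gene names.
#' @param n_rois_per_gene ROIs per gene (default 8).
#' @param planted_cn Named numeric: copy number per amplified gene (others
#'   stay at CN 2).
#' @param purity Tumor purity of the simulated sample.
#' @param noise_cv Multiplicative log-normal noise CV (default 0.05).
#' @param n_controls Number of control profiles (default 20).
#' @param seed RNG seed.
#' @return List: `sample` (numeric coverage per ROI), `gene` (label per
#'   ROI), `controls` (ROI x control matrix), `truth`.
#' @export
simulate_coverage_profiles <- function(genes, n_rois_per_gene = 8L,
                                       planted_cn = c(), purity = 0.6,
                                       noise_cv = 0.05, n_controls = 20L,
                                       seed = 1L) {
  set.seed(seed)
  gene_lab <- rep(genes, each = n_rois_per_gene)
  n_roi <- length(gene_lab)
  sdlog <- sqrt(log(1 + noise_cv^2))
  controls <- matrix(stats::rlnorm(n_roi * n_controls, -sdlog^2 / 2, sdlog),
                     nrow = n_roi)
  cn <- ifelse(gene_lab %in% names(planted_cn),
               unname(planted_cn[gene_lab]), 2)
  expected <- (purity * cn + 2 * (1 - purity)) / 2
  smpl <- expected * stats::rlnorm(n_roi, -sdlog^2 / 2, sdlog)
  list(sample = smpl, gene = gene_lab, controls = controls,
       truth = list(planted_cn = planted_cn, purity = purity,
                    expected_fold = stats::setNames(
                      (purity * planted_cn + 2 * (1 - purity)) / 2 / 1,
                      names(planted_cn))))
}

#' Simulate read pairs with planted gene fusions
#'
#' Generates discordant pairs joining two gene regions (`n_support` distinct
#' fragments per planted fusion) on top of concordant background pairs.
#'
#' @param fusions Data frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `n_support`.
#' @param n_background Concordant background pairs (default 200).
#' @param seed RNG seed.
#' @return Read-record data frame (one row per fragment; mate fields encode
#'   the junction).
#' @export
simulate_fusion_reads <- function(fusions, n_background = 200L, seed = 1L) {
  set.seed(seed)
  mk <- function(chrom, pos, mate_chrom, mate_pos, n, tag, proper) {
    jitter_a <- sample(0:200, n, replace = TRUE)
    jitter_b <- sample(0:200, n, replace = TRUE)
    read_records(read_id = sprintf("%s_%03d", tag, seq_len(n)),
                 chrom = chrom, pos = pos + jitter_a,
                 cigar = "100M", mapq = 60L,
                 sequence = strrep("A", 100),
                 mate_chrom = mate_chrom, mate_pos = mate_pos + jitter_b,
                 is_proper_pair = proper)
  }
  bg <- mk("chr1", sample.int(1e6, 1), "chr1", 0L, n_background, "bg", TRUE)
  bg$mate_pos <- bg$pos + sample(150:400, n_background, replace = TRUE)
  parts <- list(bg)
  if (!is.null(fusions) && nrow(fusions))
    for (i in seq_len(nrow(fusions)))
      parts[[i + 1L]] <- mk(fusions$chrom_a[i], fusions$pos_a[i],
                            fusions$chrom_b[i], fusions$pos_b[i],
                            fusions$n_support[i], sprintf("fus%d", i), FALSE)
  do.call(rbind, parts)
}

#' Simulate a nested precision-study table
#'
#' Draws values from the random-effects model `value = mean + site + operator
#' + day + residual` over a balanced nested design, for testing
#' variance-component recovery.
#'
#' @param mean Grand mean.
#' @param sd_site,sd_operator,sd_day,sd_within Component standard
#'   deviations.
#' @param n_sites,n_operators,n_days,n_reps Balanced design sizes.
#' @param seed RNG seed.
#' @return Data frame with columns `site`, `operator`, `day`, `value`, plus
#'   a `truth` attribute of the component variances.
#' @export
simulate_replicate_table <- function(mean = 10, sd_site = 0.5,
                                     sd_operator = 0.3, sd_day = 0.2,
                                     sd_within = 0.4, n_sites = 3L,
                                     n_operators = 2L, n_days = 3L,
                                     n_reps = 2L, seed = 1L) {
  set.seed(seed)
  rows <- expand.grid(rep = seq_len(n_reps), day = seq_len(n_days),
                      operator = seq_len(n_operators),
                      site = seq_len(n_sites))
  eff_site <- stats::rnorm(n_sites, 0, sd_site)
  key_op <- interaction(rows$site, rows$operator, drop = TRUE)
  eff_op <- stats::rnorm(nlevels(key_op), 0, sd_operator)
  key_day <- interaction(rows$site, rows$operator, rows$day, drop = TRUE)
  eff_day <- stats::rnorm(nlevels(key_day), 0, sd_day)
  val <- mean + eff_site[rows$site] + eff_op[as.integer(key_op)] +
    eff_day[as.integer(key_day)] + stats::rnorm(nrow(rows), 0, sd_within)
  out <- data.frame(site = paste0("S", rows$site),
                    operator = paste0("O", rows$operator),
                    day = paste0("D", rows$day), value = val,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- c(site = sd_site^2, operator = sd_operator^2,
                          day = sd_day^2, within_run = sd_within^2)
  out
}
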