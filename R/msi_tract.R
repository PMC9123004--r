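# Per-tract microsatellite instability calling from aligned reads.
#
# The caller works on mononucleotide tracts (13-30 bp in the reference).
# Standard alignment misplaces indels inside homopolymers, so tract length is
# re-measured by local realignment: locate exact 5'/3' seed sequences flanking
# the tract in the read and count the bases between them.

#' Define a mononucleotide tract
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the tract in the reference.
#' @param base Repeat unit base (one of A/C/G/T).
#' @param ref_length Reference tract length in bp, 13-30.
#' @param seed5,seed3 Flanking anchor sequences (>= 8 bp each) immediately
#'   5' and 3' of the tract on the forward strand.
#' @param id Tract identifier (defaults to `chrom:start`).
#' @return A `tract_definition` list.
#' @export
tract_definition <- function(chrom, start, base, ref_length, seed5, seed3,
                             id = sprintf("%s:%d", chrom, start)) {
  ref_length <- as.integer(ref_length)
  if (ref_length < 13L || ref_length > 30L)
    stop("ref_length must be within 13-30 bp")
  if (!base %in% c("A", "C", "G", "T")) stop("base must be A/C/G/T")
  if (nchar(seed5) < 8L || nchar(seed3) < 8L)
    stop("seeds must be at least 8 bp")
  structure(list(id = id, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(start) + ref_length,
                 base = base, ref_length = ref_length,
                 seed5 = toupper(seed5), seed3 = toupper(seed3)),
            class = "tract_definition")
}

#' Read a tract panel BED with seed columns
#'
#' Expects a BED whose 4th column is `base:ref_length` and whose 5th and 6th
#' columns carry the 5' and 3' seed sequences.
#'
#' @param path Path to the tract panel file.
#' @return List of [tract_definition()] objects, in file order.
#' @export
read_tract_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 6L)
      stop(sprintf("tract panel line %d: need 6 columns (bed3 + base:len + seeds)", i))
    br <- strsplit(f[4], ":", fixed = TRUE)[[1]]
    if (length(br) != 2L)
      stop(sprintf("tract panel line %d: 4th column must be base:ref_length", i))
    td <- tract_definition(f[1], as.integer(f[2]), br[1], as.integer(br[2]),
                           f[5], f[6])
    if (td$end - td$start != as.integer(f[3]) - as.integer(f[2]))
      stop(sprintf("tract panel line %d: interval length != ref_length", i))
    td
  })
}

# Locate the seed pair flanking the tract in each read. Seeds can match more
# than once (e.g. periodic anchors extended by flanking sequence), so the
# anchors adjacent to the tract are used: the last 5' seed match before the
# 3' seed, and the first 3' seed match after it. Returns 1-based positions of
# the first and last base of the tract segment (-1/-2 when a seed is absent).
locate_seed_segment <- function(sequences, seed5, seed3) {
  n5 <- nchar(seed5)
  # zero-width lookahead finds overlapping occurrences (seeds are plain ACGT)
  m5 <- gregexpr(paste0("(?=", seed5, ")"), sequences, perl = TRUE)
  m3 <- gregexpr(paste0("(?=", seed3, ")"), sequences, perl = TRUE)
  seg <- vapply(seq_along(sequences), function(i) {
    a <- as.integer(m5[[i]]); b <- as.integer(m3[[i]])
    if (a[1] < 0L || b[1] < 0L) return(c(-1L, -2L))
    p3 <- b[1]
    av <- a[a + n5 - 1L < p3]
    if (!length(av)) return(c(-1L, -2L))
    p5 <- max(av)
    bv <- b[b > p5 + n5 - 1L]
    p3 <- bv[1]
    c(p5 + n5, p3 - 1L)
  }, integer(2))
  list(start = seg[1, ], end = seg[2, ])
}

# Vectorized eligibility + realignment over all reads at one tract.
# Returns a data frame: read_id, indel_offset, eligible, reason, fragment_key.
tract_observations <- function(reads, tract, max_indel = 12L,
                               required_mapq = 60L, max_softclip = 20L,
                               min_flank = 8L) {
  n <- nrow(reads)
  off <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  seg <- locate_seed_segment(reads$sequence, tract$seed5, tract$seed3)
  seg_start <- seg$start                             # first tract base (1-based)
  seg_end <- seg$end                                 # last tract base
  len <- nchar(reads$sequence)
  seed_ok <- seg_start > 0L & seg_end >= seg_start - 1L
  reason[!seed_ok] <- "seed"
  seg_len <- ifelse(seed_ok, seg_end - seg_start + 1L, NA_integer_)
  o <- seg_len - tract$ref_length
  # criteria applied in order; reason records the first failure
  flank_ok <- seed_ok & (seg_start - 1L > min_flank) & (len - seg_end > min_flank)
  reason[seed_ok & !flank_ok] <- "flank"
  indel_ok <- flank_ok & abs(o) <= max_indel
  reason[flank_ok & !indel_ok] <- "indel"
  seg <- substr(reads$sequence, seg_start, seg_end)
  pure <- indel_ok & (seg_len == 0L |
                        seg == strrep(tract$base, pmax(seg_len, 0L)))
  reason[indel_ok & !pure] <- "basechange"
  mq_ok <- pure & reads$mapq == required_mapq
  reason[pure & !mq_ok] <- "mapq"
  sc_ok <- mq_ok & reads$softclip_total <= max_softclip
  reason[mq_ok & !sc_ok] <- "softclip"
  off[sc_ok] <- o[sc_ok]
  data.frame(read_id = reads$read_id, indel_offset = off,
             eligible = sc_ok, reason = reason,
             fragment_key = paste(reads$pos, reads$mate_pos, o, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Assess one read's eligibility at a tract
#'
#' A read contributes to the tract length distribution only if all five
#' criteria hold: the tract lies more than 8 bases inside both read ends, the
#' measured indel is at most 12 bp from the reference length, no single-base
#' change occurs within the realigned repeat segment, the mapping quality
#' equals the required value (default 60), and at most 20 bases are
#' soft-clipped. The rejection reason records the first criterion violated
#' (`"seed"` when a flanking anchor cannot be located at all).
#'
#' @param read One-row read-record data frame.
#' @param tract A [tract_definition()].
#' @param max_indel,required_mapq,max_softclip,min_flank Criterion thresholds.
#' @return List with `read_id`, `indel_offset` (NA when ineligible),
#'   `eligible`, `reason`.
#' @export
filter_read <- function(read, tract, max_indel = 12L, required_mapq = 60L,
                        max_softclip = 20L, min_flank = 8L) {
  stopifnot(nrow(read) == 1L)
  rw <- cigar_ref_width(read$cigar)
  if (read$chrom != tract$chrom || read$pos >= tract$end ||
      read$pos + rw <= tract$start)
    stop("read does not overlap the tract interval")
  obs <- tract_observations(read, tract, max_indel, required_mapq,
                            max_softclip, min_flank)
  as.list(obs[1L, c("read_id", "indel_offset", "eligible", "reason")])
}

#' Measure a tract's length in one read by seed realignment
#'
#' @inheritParams filter_read
#' @return Signed indel offset relative to the reference length (negative =
#'   contraction), or `NA` with attribute `reason = "seed"` when either seed
#'   cannot be located exactly.
#' @export
measure_tract_length <- function(read, tract) {
  stopifnot(nrow(read) == 1L)
  seg <- locate_seed_segment(read$sequence, tract$seed5, tract$seed3)
  if (seg$start < 0L)
    return(structure(NA_integer_, reason = "seed"))
  (seg$end - seg$start + 1L) - tract$ref_length
}

#' Error-corrected tract length distribution
#'
#' Builds the per-tract indel-length histogram from eligible reads, after
#' collapsing duplicate fragments. Fragment identity is (read start, mate
#' start, measured offset) — a coordinate proxy in the absence of molecular
#' barcodes.
#'
#' @param reads Read-record data frame overlapping the tract.
#' @param tract A [tract_definition()].
#' @param ... Passed to the eligibility filter (see [filter_read()]).
#' @return List with `counts` (named vector: offset -> distinct fragments)
#'   and `absolute_coverage` (total distinct eligible fragments).
#' @export
tract_length_distribution <- function(reads, tract, ...) {
  obs <- tract_observations(reads, tract, ...)
  obs <- obs[obs$eligible, , drop = FALSE]
  obs <- obs[!duplicated(obs$fragment_key), , drop = FALSE]
  counts <- table(obs$indel_offset)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  list(counts = counts, absolute_coverage = sum(counts))
}

#' Find tract alleles by peak finding
#'
#' An offset `L` is called as an allele when its distinct fragment count is a
#' strict local maximum against all four neighbors `L - 2 .. L + 2` (absent
#' lengths count as zero), exceeds `min_fragments` distinct fragments, and
#' reaches at least `min_fraction` of the absolute coverage. Ties with a
#' neighbor disqualify both (conservative toward stability).
#'
#' @param dist Length distribution from [tract_length_distribution()].
#' @param min_fragments Strict lower bound on fragment count (default 5,
#'   i.e. an allele needs more than 5 distinct fragments).
#' @param min_fraction Minimum share of absolute coverage (default 0.08).
#' @return Sorted integer vector of allele offsets.
#' @export
find_alleles <- function(dist, min_fragments = 5, min_fraction = 0.08) {
  if (is.null(dist$counts) || dist$absolute_coverage <= 0)
    stop("no eligible fragments")
  counts <- dist$counts
  offs <- as.integer(names(counts))
  at <- function(L) ifelse(is.na(match(L, offs)), 0, counts[match(L, offs)])
  keep <- vapply(seq_along(offs), function(i) {
    L <- offs[i]; c0 <- counts[i]
    all(c0 > c(at(L - 1L), at(L + 1L), at(L - 2L), at(L + 2L))) &&
      c0 > min_fragments &&
      c0 / dist$absolute_coverage >= min_fraction
  }, logical(1))
  sort(offs[keep])
}

#' Classify a tract as stable or unstable
#'
#' A tract exhibits instability when any called allele is at least 2 bp
#' shorter than the reference length. Insertions never mark instability.
#'
#' @param alleles Integer offsets from [find_alleles()].
#' @param tract A [tract_definition()].
#' @return List with `tract_id`, `alleles`, `unstable`.
#' @export
classify_tract <- function(alleles, tract) {
  list(tract_id = tract$id, alleles = alleles,
       unstable = any(alleles <= -2L))
}

#' Call one tract from reads
#'
#' Convenience pipeline: eligibility filter, duplicate collapse, peak
#' finding, classification. A tract with no eligible fragments is returned
#' non-evaluable instead of erroring, so panels with coverage dropouts can
#' still be scored.
#'
#' @inheritParams tract_length_distribution
#' @param min_fragments,min_fraction Passed to [find_alleles()].
#' @return List: `tract_id`, `n_fragments`, `alleles`, `unstable`,
#'   `evaluable`.
#' @export
call_tract <- function(reads, tract, min_fragments = 5, min_fraction = 0.08,
                       ...) {
  dist <- tract_length_distribution(reads, tract, ...)
  if (dist$absolute_coverage <= 0)
    return(list(tract_id = tract$id, n_fragments = 0, alleles = integer(),
                unstable = FALSE, evaluable = FALSE))
  alleles <- find_alleles(dist, min_fragments, min_fraction)
  cl <- classify_tract(alleles, tract)
  list(tract_id = tract$id, n_fragments = dist$absolute_coverage,
       alleles = alleles, unstable = cl$unstable, evaluable = TRUE)
}

#' Sample-level tract score
#'
#' Counts unstable tracts across the panel; a sample is tract-level MSI-H
#' when strictly more than `threshold` tracts (default 10, on the 68-tract
#' panel) exhibit instability.
#'
#' @param calls List of per-tract calls (from [call_tract()] or
#'   [classify_tract()]).
#' @param threshold Unstable-tract count that must be exceeded (default 10).
#' @return List: `n_evaluated`, `n_unstable`, `fraction_unstable`,
#'   `tract_msih`.
#' @export
score_msi_sample <- function(calls, threshold = 10L) {
  ev <- vapply(calls, function(x) is.null(x$evaluable) || x$evaluable,
               logical(1))
  if (!any(ev)) stop("no evaluable tracts")
  unstable <- vapply(calls[ev], function(x) isTRUE(x$unstable), logical(1))
  n_eval <- sum(ev); n_un <- sum(unstable)
  list(n_evaluated = n_eval, n_unstable = n_un,
       fraction_unstable = n_un / n_eval,
       tract_msih = n_un > threshold)
}

#' Select discriminative tracts from a labeled cohort
#'
#' Panel curation over candidate tracts: drops tracts with systematically
#' insufficient coverage, tracts polymorphic within the MSS subset (multiple
#' observed allele lengths risk specificity), and tracts whose instability
#' rates do not differ between MSI-H and MSS classes.
#'
#' @param cohort_calls List over samples; each element a list of per-tract
#'   calls as from [call_tract()] (all samples over the same tract set, same
#'   order).
#' @param labels Character vector per sample: `"MSI-H"` or `"MSS"`.
#' @param min_coverage Minimum distinct fragments for a tract to count as
#'   covered in a sample (default 20).
#' @param min_sample_fraction Minimum fraction of samples in which a tract
#'   must be covered (default 0.8).
#' @param effect_threshold Minimum difference in unstable-call rate between
#'   classes (default 0.2).
#' @return Character vector of retained tract ids.
#' @export
select_tracts <- function(cohort_calls, labels, min_coverage = 20,
                          min_sample_fraction = 0.8, effect_threshold = 0.2) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("cohort must contain both MSI-H and MSS samples")
  stopifnot(length(cohort_calls) == length(labels))
  tract_ids <- vapply(cohort_calls[[1]], `[[`, "", "tract_id")
  n_tracts <- length(tract_ids)
  cov <- sapply(cohort_calls, function(s)
    vapply(s, function(x) as.numeric(x$n_fragments), 0))
  un <- sapply(cohort_calls, function(s)
    vapply(s, function(x) isTRUE(x$unstable), logical(1)))
  cov <- matrix(cov, nrow = n_tracts); un <- matrix(un, nrow = n_tracts)
  mss <- labels == "MSS"; msi <- labels == "MSI-H"
  covered_ok <- rowMeans(cov >= min_coverage) >= min_sample_fraction
  # distinct allele offsets observed across the MSS subset
  mss_alleles <- lapply(seq_len(n_tracts), function(i)
    unique(unlist(lapply(cohort_calls[mss], function(s) s[[i]]$alleles))))
  monomorphic <- vapply(mss_alleles, function(a) length(a) <= 1L, logical(1))
  discriminative <- abs(rowMeans(un[, msi, drop = FALSE]) -
                          rowMeans(un[, mss, drop = FALSE])) >= effect_threshold
  tract_ids[covered_ok & monomorphic & discriminative]
}
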