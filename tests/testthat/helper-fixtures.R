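# Shared fixture builders; everything is generated in code at test time.

make_variant_df <- function(n = 10, maf = 0.2, n_obs = 12L,
                            consequence = "nonsynonymous",
                            quality_score = 0.9) {
  data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
             ref = "C", alt = "T",
             maf = rep_len(maf, n), n_obs = rep_len(as.integer(n_obs), n),
             consequence = rep_len(consequence, n),
             quality_score = rep_len(quality_score, n),
             cosmic_n = NA_integer_, pop_dbsnp = NA_real_,
             context11 = NA_character_,
             stringsAsFactors = FALSE)
}

# One perfectly reference-matching read spanning a tract with >=9 bp flanks.
make_perfect_read <- function(tract, offset = 0L, pad = 10L) {
  flank <- setdiff(c("A", "C", "G", "T"), tract$base)[1]
  seqs <- paste0(strrep(flank, pad), tract$seed5,
                 strrep(tract$base, tract$ref_length + offset),
                 tract$seed3, strrep(flank, pad))
  read_records(read_id = "r1", chrom = tract$chrom,
               pos = tract$start - nchar(tract$seed5) - pad,
               cigar = paste0(nchar(seqs), "M"), mapq = 60L,
               sequence = seqs, mate_pos = 5000L)
}

# Independent brute-force allele caller used as the peak-finding oracle:
# checks the three conditions at every offset on a dense count vector.
oracle_alleles <- function(counts, absolute_coverage, min_fragments = 5,
                           min_fraction = 0.08) {
  offs <- as.integer(names(counts))
  dense <- stats::setNames(rep(0, 31), as.character(-15:15))
  dense[as.character(offs)] <- counts
  out <- integer()
  for (L in -12:12) {
    cL <- dense[as.character(L)]
    neigh <- dense[as.character(c(L - 1, L + 1, L - 2, L + 2))]
    if (cL > max(neigh) && cL > min_fragments &&
        cL / absolute_coverage >= min_fraction)
      out <- c(out, L)
  }
  out
}

random_length_distribution <- function() {
  k <- sample(1:8, 1)
  offs <- sample(-12:12, k)
  counts <- stats::setNames(as.numeric(sample(0:120, k, replace = TRUE)),
                            as.character(offs))
  counts <- counts[counts > 0]
  if (!length(counts))
    counts <- stats::setNames(10, "0")
  list(counts = counts, absolute_coverage = sum(counts))
}
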