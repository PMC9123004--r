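test_that("purity is twice the median clonal MAF, clamped", {
  expect_equal(estimate_purity(rep(0.25, 6)), 0.5)
  expect_equal(estimate_purity(rep(0.60, 6)), 1.0)
  expect_true(is.na(estimate_purity(numeric())))
  expect_true(is.na(estimate_purity(c(0.2, 0.3))))  # below min_variants
  expect_equal(estimate_purity(c(0.2, 0.3), min_variants = 2), 0.5)
})

test_that("the purity-adjusted copy-number algebra is exact", {
  # r = 2.0 at p = 0.5 -> CN 6, fold change 3
  genes <- rep("G1", 8)
  base <- normal_baseline(matrix(1 + stats::rnorm(8 * 20, 0, 0.02), nrow = 8))
  amp <- call_amplification(rep(2.0, 8) * base$mean, genes, base,
                            purity = 0.5, alpha = NA)
  expect_equal(amp$median_fold_change, 3, tolerance = 1e-9)
  expect_equal(amp$status, "amplified")
  # r = 1 everywhere -> fold change 1, never amplified
  flat <- call_amplification(base$mean, genes, base, purity = 0.5, alpha = NA)
  expect_equal(flat$median_fold_change, 1, tolerance = 1e-9)
  expect_false(flat$status == "amplified")
  # identical coverage fails the significance screen -> no_call
  nc <- call_amplification(base$mean, genes, base, purity = 0.5)
  expect_equal(nc$status, "no_call")
})

test_that("planted amplifications are recovered and absent genes stay quiet", {
  genes <- c("ERBB2", "MET", "MYC", "EGFR")
  sim <- simulate_coverage_profiles(genes, planted_cn = c(ERBB2 = 8),
                                    purity = 0.6, noise_cv = 0.05, seed = 31)
  base <- normal_baseline(sim$controls)
  calls <- call_amplification(sim$sample, sim$gene, base, purity = 0.6)
  expect_equal(calls$status[calls$gene == "ERBB2"], "amplified")
  expect_false(any(calls$status[calls$gene != "ERBB2"] == "amplified"))
  # undetermined purity: amplified signal becomes indeterminate
  calls_na <- call_amplification(sim$sample, sim$gene, base, purity = NA)
  expect_equal(calls_na$status[calls_na$gene == "ERBB2"], "indeterminate")
})

test_that("the CN formula inverts the simulated mixture model", {
  for (cn in c(4, 6, 10)) for (p in c(0.3, 0.6, 0.9)) {
    sim <- simulate_coverage_profiles("G", n_rois_per_gene = 24,
                                      planted_cn = c(G = cn), purity = p,
                                      noise_cv = 0.03,
                                      seed = 1000 + cn * 10 + p * 10)
    base <- normal_baseline(sim$controls)
    call <- call_amplification(sim$sample, sim$gene, base, purity = p,
                               alpha = NA)
    expect_equal(call$median_fold_change, cn / 2, tolerance = 0.15)
  }
})

test_that("amplification status is monotone in the planted fold change", {
  statuses <- vapply(c(2, 3, 6, 12), function(cn) {
    sim <- simulate_coverage_profiles("G", planted_cn = c(G = cn),
                                      purity = 0.6, seed = 50 + cn)
    base <- normal_baseline(sim$controls)
    call_amplification(sim$sample, sim$gene, base, purity = 0.6)$status
  }, "")
  amp <- statuses == "amplified"
  expect_true(all(diff(as.integer(amp)) >= 0))
  expect_true(amp[4])
})

test_that("discordant-pair collection keeps distant, cross-chromosome and
           improper pairs", {
  mk <- function(id, chrom, pos, mate_chrom, mate_pos, mapq = 60L,
                 proper = TRUE)
    read_records(read_id = id, chrom = chrom, pos = pos, cigar = "100M",
                 mapq = mapq, sequence = strrep("A", 100),
                 mate_chrom = mate_chrom, mate_pos = mate_pos,
                 is_proper_pair = proper)
  reads <- rbind(
    mk("proper", "chr1", 1000L, "chr1", 1300L),                    # excluded
    mk("far", "chr1", 1000L, "chr1", 5000L),                       # distance
    mk("inter", "chr2", 100L, "chr7", 900L),                       # chrom
    mk("orient", "chr1", 2000L, "chr1", 2200L, proper = FALSE),    # improper
    mk("lowq", "chr3", 100L, "chr9", 900L, mapq = 5L))             # removed
  cl <- collect_discordant_pairs(reads)
  expect_equal(sum(cl$n_support), 3L)
  expect_false(any(cl$chrom_a == "chr3" | cl$chrom_b == "chr3"))

  # ten nearby fragments collapse into one cluster of support 10
  ten <- do.call(rbind, lapply(1:10, function(i)
    mk(paste0("f", i), "chr2", 100L + i * 20L, "chr7", 900L + i * 15L)))
  cl10 <- collect_discordant_pairs(ten)
  expect_equal(nrow(cl10), 1L)
  expect_equal(cl10$n_support, 10L)
})

test_that("translocation reporting applies strand, control-db and support
           rules", {
  ann <- genomic_intervals(c("chr2", "chr2", "chr7"),
                           c(0, 50000, 0), c(10000, 60000, 10000))
  ann$gene <- c("EML4", "ANTI", "ALK")
  ann$strand <- c("+", "-", "+")
  cl <- data.frame(chrom_a = "chr2", pos_a = 500L, chrom_b = "chr7",
                   pos_b = 800L, n_support = 5L)
  out <- call_translocation(cl, ann)
  expect_equal(nrow(out), 1L)       # boundary: support == min_support
  expect_equal(out$gene_a, "EML4")
  expect_true(out$fusion_productive)

  expect_equal(nrow(call_translocation(
    cl, ann, control_db = data.frame(gene_a = "ALK", gene_b = "EML4"))), 0L)
  expect_equal(nrow(call_translocation(
    transform(cl, n_support = 4L), ann)), 0L)
  # antisense join suppressed
  cl_anti <- transform(cl, pos_a = 55000L)
  expect_equal(nrow(call_translocation(cl_anti, ann)), 0L)
})

test_that("planted fusions are recovered end to end and clean samples stay
           clean", {
  ann <- genomic_intervals(c("chr2", "chr7"), c(0, 0), c(20000, 20000))
  ann$gene <- c("EML4", "ALK"); ann$strand <- c("+", "+")
  fus <- data.frame(chrom_a = "chr2", pos_a = 5000L, chrom_b = "chr7",
                    pos_b = 8000L, n_support = 12L)
  reads <- simulate_fusion_reads(fus, n_background = 300, seed = 44)
  calls <- call_translocation(collect_discordant_pairs(reads), ann)
  expect_equal(nrow(calls), 1L)
  expect_setequal(c(calls$gene_a, calls$gene_b), c("EML4", "ALK"))
  expect_gte(calls$n_support, 12L)

  clean <- simulate_fusion_reads(fus[0, ], n_background = 300, seed = 45)
  expect_equal(nrow(call_translocation(collect_discordant_pairs(clean), ann)),
               0L)
})
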