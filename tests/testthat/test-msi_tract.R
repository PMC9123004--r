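tract <- tract_definition("chr1", 1000L, "A", 15L,
                          seed5 = "CGTCGTCGTC", seed3 = "GCTGCTGCTG",
                          id = "t1")

test_that("read eligibility enforces all five criteria in order", {
  rd <- make_perfect_read(tract)
  ok <- filter_read(rd, tract)
  expect_true(ok$eligible)
  expect_equal(ok$indel_offset, 0L)

  r_mapq <- rd; r_mapq$mapq <- 59L
  expect_equal(filter_read(r_mapq, tract)$reason, "mapq")

  r_clip <- rd; r_clip$softclip_total <- 21L
  expect_equal(filter_read(r_clip, tract)$reason, "softclip")
  r_clip20 <- rd; r_clip20$softclip_total <- 20L
  expect_true(filter_read(r_clip20, tract)$eligible)

  # with minimal 8-bp seeds and no extra padding the tract sits exactly 8
  # bases inside the read ends -> flank failure ("more than 8" is strict)
  tract8 <- tract_definition("chr1", 1000L, "A", 15L,
                             seed5 = "CGTCGTCG", seed3 = "GCTGCTGC")
  r_flank <- read_records(read_id = "rf", chrom = "chr1",
                          pos = 1000L - 8L,
                          cigar = "31M", mapq = 60L,
                          sequence = paste0("CGTCGTCG", strrep("A", 15),
                                            "GCTGCTGC"),
                          mate_pos = 2000L)
  expect_equal(filter_read(r_flank, tract8)$reason, "flank")

  # single-base change inside the repeat
  r_mut <- rd
  r_mut$sequence <- sub(strrep("A", 15), paste0(strrep("A", 7), "G",
                                                strrep("A", 7)),
                        r_mut$sequence, fixed = TRUE)
  expect_equal(filter_read(r_mut, tract)$reason, "basechange")

  # indel beyond 12 bp: 15 -> 28 is +13
  r_big <- make_perfect_read(tract, offset = 13L)
  expect_equal(filter_read(r_big, tract)$reason, "indel")

  r_far <- rd; r_far$pos <- 5000L
  expect_error(filter_read(r_far, tract), "overlap")
})

test_that("seed realignment measures planted indel offsets exactly", {
  expect_equal(measure_tract_length(make_perfect_read(tract, -2L), tract), -2L)
  expect_equal(measure_tract_length(make_perfect_read(tract, 0L), tract), 0L)
  noseed <- make_perfect_read(tract)
  noseed$sequence <- strrep("G", 60)
  m <- measure_tract_length(noseed, tract)
  expect_true(is.na(m))
  expect_equal(attr(m, "reason"), "seed")

  sim <- simulate_tract_reads(tract, depth = 1000, purity = 1,
                              unstable_offset = -4L, unstable_fraction = 1,
                              stutter_rate = 0, seed = 21)
  obs <- oncoprofiler:::tract_observations(sim$reads, tract)
  expect_true(all(obs$eligible))
  expect_true(all(obs$indel_offset == -4L))
})

test_that("peak finding matches the brute-force oracle on random distributions", {
  d <- list(counts = c(`0` = 100, `-1` = 30, `-2` = 40, `-3` = 10),
            absolute_coverage = 180)
  expect_equal(find_alleles(d), 0L)
  expect_equal(find_alleles(list(counts = c(`0` = 100, `-3` = 40),
                                 absolute_coverage = 140)), c(-3L, 0L))
  expect_equal(find_alleles(list(counts = c(`0` = 100, `-3` = 6),
                                 absolute_coverage = 106)), 0L)
  expect_error(find_alleles(list(counts = numeric(), absolute_coverage = 0)),
               "no eligible fragments")

  set.seed(99)
  for (i in 1:300) {
    d <- random_length_distribution()
    expect_identical(find_alleles(d),
                     sort(oracle_alleles(d$counts, d$absolute_coverage)))
  }
})

test_that("raising an allele's count never removes it (monotonicity)", {
  set.seed(7)
  for (i in 1:50) {
    d <- random_length_distribution()
    al <- find_alleles(d)
    if (!length(al)) next
    a <- al[sample.int(length(al), 1)]
    d2 <- d
    d2$counts[as.character(a)] <- d2$counts[as.character(a)] + 50
    d2$absolute_coverage <- sum(d2$counts)
    expect_true(a %in% find_alleles(d2))
  }
})

test_that("duplicate fragments never change the length distribution", {
  sim <- simulate_tract_reads(tract, depth = 200, purity = 0.5,
                              unstable_offset = -3L, seed = 33)
  d1 <- tract_length_distribution(sim$reads, tract)
  d2 <- tract_length_distribution(rbind(sim$reads, sim$reads), tract)
  expect_identical(d1, d2)
})

test_that("instability needs a deletion of at least 2 bp", {
  expect_false(classify_tract(0L, tract)$unstable)
  expect_true(classify_tract(c(0L, -3L), tract)$unstable)
  expect_false(classify_tract(c(0L, -1L), tract)$unstable)
  expect_false(classify_tract(c(0L, 3L), tract)$unstable)  # insertions never
  expect_true(classify_tract(c(0L, -2L), tract)$unstable)  # boundary
})

test_that("sample MSI-H call requires more than 10 unstable of 68 tracts", {
  mk <- function(u, n = 68) lapply(seq_len(n), function(i)
    list(tract_id = paste0("t", i), alleles = if (i <= u) c(0L, -3L) else 0L,
         unstable = i <= u, n_fragments = 100, evaluable = TRUE))
  expect_true(score_msi_sample(mk(11))$tract_msih)
  expect_false(score_msi_sample(mk(10))$tract_msih)
  s0 <- score_msi_sample(mk(0))
  expect_equal(s0$fraction_unstable, 0)
  expect_false(s0$tract_msih)
  for (u in c(0L, 5L, 23L, 68L))
    expect_equal(score_msi_sample(mk(u))$n_unstable, u)
  expect_error(score_msi_sample(list()), "evaluable")
})

test_that("a diluted unstable tract is still called unstable end to end", {
  sim <- simulate_tract_reads(tract, depth = 500, purity = 0.4,
                              unstable_offset = -3L, unstable_fraction = 0.6,
                              stutter_rate = 0.05, seed = 13)
  call <- call_tract(sim$reads, tract)
  expect_true(call$evaluable)
  expect_true(call$unstable)
  expect_true(-3L %in% call$alleles)
})

test_that("tract selection keeps discriminative and drops polymorphic tracts", {
  mk_call <- function(id, alleles, unstable, nfrag = 100)
    list(tract_id = id, alleles = alleles, unstable = unstable,
         n_fragments = nfrag, evaluable = nfrag > 0)
  ids_disc <- sprintf("disc%02d", 1:10)
  ids_poly <- sprintf("poly%02d", 1:10)
  mk_sample <- function(label) {
    c(lapply(ids_disc, function(id)
        mk_call(id, if (label == "MSI-H") c(0L, -3L) else 0L,
                label == "MSI-H")),
      lapply(ids_poly, function(id) mk_call(id, c(0L, -4L), TRUE)),
      list(mk_call("nocov", integer(), FALSE, nfrag = 0)))
  }
  labels <- c("MSI-H", "MSI-H", "MSI-H", "MSS", "MSS", "MSS")
  cohort <- lapply(labels, mk_sample)
  kept <- select_tracts(cohort, labels)
  expect_setequal(kept, ids_disc)
  expect_error(select_tracts(cohort, rep("MSS", 6)), "both")
})
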