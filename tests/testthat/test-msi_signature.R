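test_that("canonicalization maps purine events to pyrimidine classes", {
  w <- "ACGTTGACGTA"
  ev <- canonicalize("G", "A", w)
  expect_equal(ev$canonical_class, "C>T")
  expect_equal(ev$window11, revcomp(w))
  ev2 <- canonicalize("C", "T", revcomp(w))
  expect_equal(ev2$window11, revcomp(w))  # identity case
  # idempotence
  ev3 <- canonicalize(ev$ref, ev$alt, ev$window11)
  expect_identical(ev3, ev)
  expect_error(canonicalize("N", "A", w), "distinct bases")
  expect_error(canonicalize("C", "C", sub("G", "C", w)), "distinct bases")
})

test_that("identical training catalogs give an all-zero model", {
  cat1 <- simulate_mutation_catalog(500, "flat", seed = 4)$events
  model <- train_pwm(cat1, cat1)
  for (m in model$matrices) expect_true(all(m == 0))
  expect_error(train_pwm(cat1, cat1, pseudocount = 0), "pseudocount")
})

test_that("a doubled triplet probability trains to log(2)", {
  # dMMR: triplet AAA at position 1 in half the C>T events; pMMR: a quarter.
  win <- function(first3) paste0(first3, "AA", "C", "AAAAA")
  dm <- data.frame(ref = "C", alt = "T",
                   window11 = c(win("AAA"), win("AAA"), win("GGG"),
                                win("TTT")))
  pm <- data.frame(ref = "C", alt = "T",
                   window11 = c(win("AAA"), win("GGG"), win("TTT"),
                                win("CCC")))
  model <- train_pwm(dm, pm, pseudocount = 1e-9)
  expect_equal(model$matrices[["C>T"]]["p1", "AAA"], log(2), tolerance = 1e-6)
})

test_that("trained matrices recover the generator's analytic log-ratios", {
  dm <- simulate_mutation_catalog(20000, "mmr", seed = 1)
  pm <- simulate_mutation_catalog(60000, "flat", seed = 2)
  model <- train_pwm(dm$events, pm$events)
  fp_d <- dm$truth$flank_probs
  fp_p <- pm$truth$flank_probs
  triplets <- colnames(model$matrices[[1]])
  analytic <- vapply(triplets, function(tt) {
    b <- strsplit(tt, "")[[1]]
    log(prod(fp_d[b]) / prod(fp_p[b]))
  }, 0)
  # flank-only positions (1-3, 7-9) for the dominant class
  for (p in c("p1", "p2", "p8", "p9")) {
    trained <- model$matrices[["C>T"]][p, ]
    expect_gt(stats::cor(trained, analytic), 0.95)
    # high-probability triplets are estimated tightly on average
    top <- names(sort(vapply(triplets, function(tt)
      prod(fp_d[strsplit(tt, "")[[1]]]), 0), decreasing = TRUE))[1:10]
    expect_lt(mean(abs(trained[top] - analytic[top])), 0.12)
  }
})

test_that("substitution scoring sums the nine overlapping triplets", {
  cat1 <- simulate_mutation_catalog(200, "flat", seed = 4)$events
  zero_model <- train_pwm(cat1, cat1)
  ev <- canonicalize("C", "T", "ACGTACTGACG")
  expect_equal(score_substitution(zero_model, ev), 0)

  log2_model <- zero_model
  for (cl in names(log2_model$matrices))
    log2_model$matrices[[cl]][] <- log(2)
  expect_equal(score_substitution(log2_model, ev), 9 * log(2))

  # independent summation oracle on a trained model
  model <- train_pwm(simulate_mutation_catalog(2000, "mmr", seed = 5)$events,
                     simulate_mutation_catalog(2000, "flat", seed = 6)$events)
  set.seed(30)
  for (i in 1:20) {
    ev <- with(simulate_mutation_catalog(1, "flat", seed = 100 + i)$events,
               canonicalize(ref, alt, window11))
    manual <- 0
    chars <- strsplit(ev$window11, "")[[1]]
    for (p in 1:9)
      manual <- manual +
        model$matrices[[ev$canonical_class]][p, paste(chars[p:(p + 2)],
                                                      collapse = "")]
    expect_equal(score_substitution(model, ev), unname(manual))
  }

  nwin <- list(ref = "C", alt = "T", window11 = "ACGTACNGACG",
               canonical_class = "C>T")
  expect_warning(s <- score_substitution(model, nwin), "non-ACGT")
  expect_true(is.na(s))
})

test_that("sample signature totals are additive and strand symmetric", {
  model <- train_pwm(simulate_mutation_catalog(5000, "mmr", seed = 7)$events,
                     simulate_mutation_catalog(5000, "flat", seed = 8)$events)
  expect_equal(score_sample_signature(model, NULL),
               list(total = 0, n_substitutions = 0L))
  ev <- simulate_mutation_catalog(10, "mmr", seed = 9)$events
  s1 <- score_sample_signature(model, ev[1, , drop = FALSE])$total
  s2 <- score_sample_signature(model, ev[2, , drop = FALSE])$total
  expect_equal(score_sample_signature(model, ev[1:2, ])$total, s1 + s2)
  # doubling the catalog doubles the total exactly
  s10 <- score_sample_signature(model, ev)$total
  expect_equal(score_sample_signature(model, rbind(ev, ev))$total, 2 * s10)
  # strand symmetry on every event
  flipped <- data.frame(ref = chartr("ACGT", "TGCA", ev$ref),
                        alt = chartr("ACGT", "TGCA", ev$alt),
                        window11 = revcomp(ev$window11))
  expect_equal(score_sample_signature(model, flipped)$total, s10)
})

test_that("MMR-signature samples outscore flat and hypermutator catalogs", {
  model <- train_pwm(simulate_mutation_catalog(10000, "mmr", seed = 1)$events,
                     simulate_mutation_catalog(10000, "flat", seed = 2)$events)
  s_mmr <- score_sample_signature(
    model, simulate_mutation_catalog(100, "mmr", seed = 3)$events)$total
  s_flat <- score_sample_signature(
    model, simulate_mutation_catalog(100, "flat", seed = 4)$events)$total
  expect_gt(s_mmr, s_flat)
  expect_gt(s_mmr, 0)
  # POLE-like hypermutators (many mutations, non-MMR contexts) stay negative
  s_pole <- score_sample_signature(
    model, simulate_mutation_catalog(500, "pole_like", seed = 5)$events)$total
  s_uv <- score_sample_signature(
    model, simulate_mutation_catalog(500, "uv_like", seed = 6)$events)$total
  expect_lt(s_pole, 0)
  expect_lt(s_uv, 0)
})

test_that("two-point boundary is the perpendicular bisector", {
  b <- fit_boundary(c(0.5, 0.0), c(100, -100), c("MSI-H", "MSS"))
  score <- function(fr, sg) b$w_tract * fr + b$w_sig * sg + b$intercept
  # midpoint lies on the boundary; endpoints are equidistant
  expect_equal(score(0.25, 0), 0, tolerance = 1e-6)
  expect_equal(abs(score(0.5, 100)), abs(score(0.0, -100)), tolerance = 1e-6)
  expect_gt(score(0.5, 100), 0)
  expect_lt(score(0.0, -100), 0)
})

test_that("a separable synthetic cohort is separated perfectly", {
  set.seed(77)
  n_h <- 125; n_s <- 600
  frac <- c(stats::runif(n_h, 0.2, 0.7), stats::runif(n_s, 0, 0.1))
  sig <- c(stats::rnorm(n_h, 300, 60), stats::rnorm(n_s, -300, 60))
  labels <- c(rep("MSI-H", n_h), rep("MSS", n_s))
  b <- fit_boundary(frac, sig, labels)
  pred <- ifelse(b$w_tract * frac + b$w_sig * sig + b$intercept > 0,
                 "MSI-H", "MSS")
  expect_equal(mean(pred == labels), 1)
  expect_error(fit_boundary(frac, sig, rep("MSS", length(frac))), "classes")
  # non-separable data -> warning naming violators
  expect_warning(fit_boundary(c(0, 1, 0, 1), c(0, 0, 1, 1) * 0,
                              c("MSS", "MSI-H", "MSI-H", "MSS")),
                 "violators")
})

test_that("near-boundary samples can be relabeled by MMR-gene status", {
  set.seed(42)
  frac <- c(stats::runif(20, 0.3, 0.6), stats::runif(60, 0, 0.05), 0.16)
  sig <- c(stats::rnorm(20, 200, 30), stats::rnorm(60, -200, 30), 0)
  labels <- c(rep("MSI-H", 20), rep("MSS", 60), "MSS")
  mmr <- c(rep(TRUE, 20), rep(FALSE, 60), TRUE)
  b <- fit_boundary(frac, sig, labels, mmr_deleterious = mmr,
                    relabel_band = 0.5)
  expect_s3_class(b, "boundary_model")
})

test_that("ensemble classification applies the strict positive-score rule", {
  b <- structure(list(w_tract = 2, w_sig = 0.001, intercept = -0.3),
                 class = "boundary_model")
  mk_tr <- function(f) list(fraction_unstable = f, n_unstable = round(68 * f),
                            n_evaluated = 68, tract_msih = f > 10 / 68)
  expect_equal(classify_msi(mk_tr(0.15), list(total = 0), b)$call, "MSS")
  expect_equal(classify_msi(mk_tr(0.15), list(total = 0), b)$combined_score, 0)
  expect_equal(classify_msi(mk_tr(11 / 68), list(total = 500), b)$call, "MSI-H")
  expect_equal(classify_msi(mk_tr(0), list(total = -800), b)$call, "MSS")
})

test_that("PWM models survive a JSON round trip", {
  model <- train_pwm(simulate_mutation_catalog(500, "mmr", seed = 11)$events,
                     simulate_mutation_catalog(500, "flat", seed = 12)$events)
  path <- withr::local_tempfile(fileext = ".json")
  write_pwm_model(model, path)
  back <- read_pwm_model(path)
  expect_equal(back$matrices, model$matrices, tolerance = 1e-12)
  expect_equal(back$pseudocount, model$pseudocount)
  ev <- canonicalize("C", "T", "ACGTACTGACG")
  expect_equal(score_substitution(back, ev), score_substitution(model, ev))
})
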