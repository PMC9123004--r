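# Mutation-context signature for mismatch-repair deficiency.
#
# Each somatic substitution is scored by a position weight matrix over the
# nine overlapping reference triplets inside an 11-bp window centered on the
# mutated base. Matrix entries are log-likelihood ratios (natural log) of the
# triplet under an MMR-deficient vs an MMR-proficient catalog; the per-sample
# signature score is the plain sum over all substitutions.

.canonical_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.triplets <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               c("A", "C", "G", "T")), 1, paste0, collapse = "")

#' Reverse complement of DNA sequences
#' @param s Character vector of ACGT sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Canonicalize a substitution to a pyrimidine-centered class
#'
#' When the reference base is a purine, the substitution and its 11-bp window
#' are reverse-complemented so every event falls in one of the six classes
#' C>A, C>G, C>T, T>A, T>C, T>G. Idempotent by construction.
#'
#' @param ref,alt Single reference/alternate bases (must differ).
#' @param window11 11-base reference context, 5 bases either side of the
#'   mutated position; `window11[6]` must equal `ref`.
#' @return List with fields `ref`, `alt`, `window11`, `canonical_class`.
#' @export
canonicalize <- function(ref, alt, window11) {
  ref <- toupper(ref); alt <- toupper(alt); window11 <- toupper(window11)
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T")) || ref == alt)
    stop("ref and alt must be distinct bases in {A,C,G,T}")
  if (nchar(window11) != 11L) stop("window11 must be 11 bases")
  if (substr(window11, 6, 6) != ref)
    stop("window11 center base must equal ref")
  if (ref %in% c("A", "G")) {
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
    window11 <- revcomp(window11)
  }
  list(ref = ref, alt = alt, window11 = window11,
       canonical_class = paste0(ref, ">", alt))
}

# Canonicalize a whole catalog (data frame ref/alt/window11), vectorized.
canonicalize_catalog <- function(events) {
  stopifnot(all(c("ref", "alt", "window11") %in% names(events)))
  ref <- toupper(events$ref); alt <- toupper(events$alt)
  win <- toupper(events$window11)
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  win[flip] <- revcomp(win[flip])
  data.frame(ref = ref, alt = alt, window11 = win,
             canonical_class = paste0(ref, ">", alt),
             stringsAsFactors = FALSE)
}

# Per-class, per-position triplet probability grid with additive smoothing.
.pwm_counts <- function(catalog, pseudocount) {
  grids <- list()
  for (cl in .canonical_classes) {
    win <- catalog$window11[catalog$canonical_class == cl]
    g <- matrix(pseudocount, nrow = 9, ncol = 64,
                dimnames = list(paste0("p", 1:9), .triplets))
    for (p in 1:9) {
      tri <- substr(win, p, p + 2L)
      tb <- table(factor(tri, levels = .triplets))
      g[p, ] <- g[p, ] + as.numeric(tb)
    }
    grids[[cl]] <- g / rowSums(g)
  }
  grids
}

#' Train the MMR-deficiency position weight matrices
#'
#' For each of the six canonical substitution classes, triplet probabilities
#' at the nine overlapping positions of the 11-bp window are estimated with
#' additive smoothing in a deficient-MMR and a proficient-MMR catalog; the
#' model entry is `log(P_dMMR / P_pMMR)` (natural log). The proficient
#' catalog should exclude POLE/POLD1-mutated hypermutators so the matrices
#' capture the MMR signature rather than raw mutation load.
#'
#' @param dmmr_catalog,pmmr_catalog Data frames with columns `ref`, `alt`,
#'   `window11` (catalogs are canonicalized internally; windows containing
#'   non-ACGT characters are dropped).
#' @param pseudocount Additive smoothing constant per triplet per position
#'   (default 0.5; must be > 0).
#' @return A `pwm_model` list: `matrices` (class -> 9 x 64 grid of
#'   log-likelihood ratios), `pseudocount`, `log_base`, training counts.
#' @export
train_pwm <- function(dmmr_catalog, pmmr_catalog, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  clean <- function(x) {
    x <- canonicalize_catalog(x)
    x[grepl("^[ACGT]{11}$", x$window11), , drop = FALSE]
  }
  d <- clean(dmmr_catalog); p <- clean(pmmr_catalog)
  pd <- .pwm_counts(d, pseudocount)
  pp <- .pwm_counts(p, pseudocount)
  mats <- lapply(.canonical_classes, function(cl) log(pd[[cl]] / pp[[cl]]))
  names(mats) <- .canonical_classes
  structure(list(matrices = mats, pseudocount = pseudocount, log_base = "e",
                 n_dmmr = nrow(d), n_pmmr = nrow(p)),
            class = "pwm_model")
}

#' Score one substitution under a PWM model
#'
#' Sum of the class matrix entries for the nine overlapping triplets at
#' window positions 1-3 through 9-11. Positive scores favor MMR deficiency.
#'
#' @param model A `pwm_model` from [train_pwm()].
#' @param event Canonicalized event from [canonicalize()] (a raw
#'   `list(ref, alt, window11)` is canonicalized on the fly).
#' @return Numeric score, or `NA` with a warning when the window contains a
#'   non-ACGT character.
#' @export
score_substitution <- function(model, event) {
  if (is.null(event$canonical_class))
    event <- canonicalize(event$ref, event$alt, event$window11)
  if (!grepl("^[ACGT]{11}$", event$window11)) {
    warning("window contains non-ACGT base; substitution not scored")
    return(NA_real_)
  }
  m <- model$matrices[[event$canonical_class]]
  sum(vapply(1:9, function(p) m[p, substr(event$window11, p, p + 2L)], 0))
}

#' Sample-level signature score
#'
#' @param model A `pwm_model`.
#' @param events Data frame with columns `ref`, `alt`, `window11`
#'   (substitutions only; indels do not contribute). Un-scoreable windows
#'   (non-ACGT) are skipped with a warning.
#' @return List with `total` (sum of per-substitution scores; 0 for an empty
#'   catalog) and `n_substitutions` (number actually scored).
#' @export
score_sample_signature <- function(model, events) {
  if (is.null(events) || nrow(events) == 0L)
    return(list(total = 0, n_substitutions = 0L))
  cat <- canonicalize_catalog(events)
  ok <- grepl("^[ACGT]{11}$", cat$window11)
  if (any(!ok)) warning(sum(!ok), " substitution(s) with non-ACGT window skipped")
  cat <- cat[ok, , drop = FALSE]
  total <- 0
  for (cl in unique(cat$canonical_class)) {
    m <- model$matrices[[cl]]
    win <- cat$window11[cat$canonical_class == cl]
    for (p in 1:9)
      total <- total + sum(m[p, substr(win, p, p + 2L)])
  }
  list(total = total, n_substitutions = nrow(cat))
}

#' Fit the linear ensemble decision boundary
#'
#' Fits a maximum-margin linear separator on the 2-D plane (fraction of
#' unstable tracts, signature score), features standardized internally.
#' When per-sample deleterious-MMR-mutation flags are supplied, samples
#' within a band around the initial boundary (default 10% of the training
#' margin) are relabeled by that flag and the boundary refit. If the classes
#' are not separable, the soft-margin fit is returned with a warning listing
#' the margin violators.
#'
#' @param fraction_unstable,signature_total Numeric feature vectors.
#' @param labels `"MSI-H"` / `"MSS"` per sample.
#' @param mmr_deleterious Optional logical per sample: deleterious mutation
#'   present in MLH1/MSH2/MSH6/PMS2 (input annotation, not curated here).
#' @param relabel_band Near-boundary band as a fraction of the margin
#'   (default 0.1).
#' @param cost Soft-margin cost (large value approximates a hard margin).
#' @return A `boundary_model` list: `w_tract`, `w_sig`, `intercept`, such
#'   that `w_tract * fraction + w_sig * signature + intercept > 0` calls
#'   MSI-H.
#' @export
fit_boundary <- function(fraction_unstable, signature_total, labels,
                         mmr_deleterious = NULL, relabel_band = 0.1,
                         cost = 1e4) {
  labels <- as.character(labels)
  if (length(setdiff(c("MSI-H", "MSS"), labels)) > 0L)
    stop("both classes must be present")
  fit_once <- function(lab) {
    x <- cbind(frac = fraction_unstable, sig = signature_total)
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
    xs <- scale(x, center = mu, scale = sdv)
    y <- factor(lab, levels = c("MSS", "MSI-H"))
    fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- colSums(fit$coefs[, 1] * fit$SV)
    b <- -fit$rho
    f <- as.numeric(xs %*% w + b)
    if (mean(f[lab == "MSI-H"]) < mean(f[lab == "MSS"])) { w <- -w; b <- -b }
    # back to raw feature units
    list(w_tract = w[1] / sdv[1], w_sig = w[2] / sdv[2],
         intercept = b - sum(w * mu / sdv),
         margin = min(abs(f)) / sqrt(sum(w^2)),
         dist = abs(f) / sqrt(sum(w^2)),
         decision = f)
  }
  m <- fit_once(labels)
  if (!is.null(mmr_deleterious)) {
    near <- m$dist <= relabel_band * m$margin
    if (any(near)) {
      labels[near] <- ifelse(mmr_deleterious[near], "MSI-H", "MSS")
      if (length(unique(labels)) == 2L) m <- fit_once(labels)
    }
  }
  pred <- ifelse(m$decision > 0, "MSI-H", "MSS")
  if (any(pred != labels))
    warning("classes not linearly separable; margin violators: ",
            paste(which(pred != labels), collapse = ", "))
  structure(list(w_tract = unname(m$w_tract), w_sig = unname(m$w_sig),
                 intercept = unname(m$intercept)),
            class = "boundary_model")
}

#' Classify a sample's MSI status with the ensemble model
#'
#' Combined score is `w_tract * fraction_unstable + w_sig * signature_total
#' + intercept`; MSI-H strictly above zero, MSS otherwise (a point exactly on
#' the boundary is called MSS, favoring specificity).
#'
#' @param tract_result Output of [score_msi_sample()].
#' @param signature Output of [score_sample_signature()].
#' @param boundary A `boundary_model` from [fit_boundary()].
#' @return List: `fraction_unstable`, `signature_total`, `combined_score`,
#'   `call`.
#' @export
classify_msi <- function(tract_result, signature, boundary) {
  s <- boundary$w_tract * tract_result$fraction_unstable +
    boundary$w_sig * signature$total + boundary$intercept
  list(fraction_unstable = tract_result$fraction_unstable,
       signature_total = signature$total,
       combined_score = s,
       call = if (s > 0) "MSI-H" else "MSS")
}

#' Serialize / load a PWM model as JSON
#'
#' @param model A `pwm_model`.
#' @param path Output (or input) path.
#' @return `write_pwm_model` returns `path` invisibly; `read_pwm_model`
#'   returns the restored `pwm_model`.
#' @export
write_pwm_model <- function(model, path) {
  obj <- list(pseudocount = model$pseudocount, log_base = model$log_base,
              n_dmmr = model$n_dmmr, n_pmmr = model$n_pmmr,
              matrices = lapply(model$matrices, function(m)
                as.data.frame(m)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pwm_model
#' @export
read_pwm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- lapply(obj$matrices, function(d) {
    m <- as.matrix(d)
    dimnames(m) <- list(paste0("p", 1:9), colnames(d))
    m
  })
  structure(list(matrices = mats[.canonical_classes],
                 pseudocount = obj$pseudocount, log_base = obj$log_base,
                 n_dmmr = obj$n_dmmr, n_pmmr = obj$n_pmmr),
            class = "pwm_model")
}
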