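# Coordinate conventions used throughout:
#   * interval tables (BED-derived): 0-based half-open [start, end)
#   * variant tables (VCF-convention): 1-based positions, anchored indels
#   * read positions: 0-based leftmost aligned base (BED frame)

#' Construct a genomic interval table
#'
#' Intervals are plain data frames in the 0-based half-open BED convention,
#' with columns `chrom`, `start`, `end`, `label`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, 0-based exclusive ends; must satisfy `end > start`.
#' @param label Optional character labels (recycled; default `""`).
#' @return A data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integral")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start (0-based half-open)")
  n <- length(start)
  data.frame(chrom = rep_len(as.character(chrom), n), start = start,
             end = end, label = rep_len(as.character(label), n),
             stringsAsFactors = FALSE)
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3+ column BED; the fourth column, when present, is kept as `label`.
#' Coordinates stay 0-based half-open, in file order.
#'
#' @param path Path to a BED file.
#' @return Interval data frame as from [genomic_intervals()].
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no intervals in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, 0L)
  bad <- which(n < 3L)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                 bad[1], path))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 bad[1], path))
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: empty or negative interval",
                 bad[1], path))
  label <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), "")
  genomic_intervals(chrom, start, end, label)
}

#' Write intervals to BED
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Mandatory columns of the flattened VCF-convention variant table.
.variant_required <- c("chrom", "pos", "ref", "alt", "maf", "n_obs",
                       "consequence", "quality_score")
.variant_consequences <- c("synonymous", "nonsynonymous", "splice",
                           "insertion", "deletion")

#' Validate a variant table
#' @param variants Data frame of variant records.
#' @return The validated data frame, invisibly usable.
#' @keywords internal
validate_variants <- function(variants) {
  miss <- setdiff(.variant_required, names(variants))
  if (length(miss))
    stop("variant table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(variants)) {
    if (any(variants$maf < 0 | variants$maf > 1, na.rm = TRUE))
      stop("maf must lie in [0, 1]")
    if (any(variants$n_obs < 0, na.rm = TRUE)) stop("n_obs must be >= 0")
    if (any(variants$pos < 1, na.rm = TRUE))
      stop("variant positions are 1-based; pos must be >= 1")
    badc <- setdiff(unique(variants$consequence), .variant_consequences)
    if (length(badc))
      stop("unknown consequence class: ", paste(badc, collapse = ", "))
    sub <- !is.na(variants$context11) & nzchar(variants$context11) &
      nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
      !variants$consequence %in% c("insertion", "deletion")
    if ("context11" %in% names(variants) && any(sub)) {
      ctx <- variants$context11[sub]
      if (any(nchar(ctx) != 11L))
        stop("context11 must be 11 bases")
      if (any(substr(ctx, 6, 6) != variants$ref[sub]))
        stop("context11 center base must equal ref for substitutions")
    }
  }
  invisible(variants)
}

#' Read a variant annotation table
#'
#' Reads the flattened VCF-convention TSV the toolkit uses for somatic
#' variants: mandatory columns `chrom, pos, ref, alt, maf, n_obs, consequence,
#' quality_score`; optional annotation columns (`pop_*` population
#' frequencies, `cosmic_n`, `context11`, `gene`, `tier`, germline flags) ride
#' along. Missing optional annotations stay `NA` — they are never coerced to
#' zero frequency.
#'
#' @param path Path to a tab-separated variant table with a header line.
#' @return Data frame of variant records (one row per variant).
#' @export
read_variant_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  # fix column types up front: a REF column of all "T" must stay character,
  # and all-NA annotation columns must keep their declared type
  classes <- rep(NA_character_, length(header))
  names(classes) <- header
  char_cols <- c("chrom", "ref", "alt", "consequence", "context11", "gene",
                 "tier")
  classes[header %in% char_cols] <- "character"
  classes[header %in% c("pos", "n_obs", "cosmic_n")] <- "integer"
  classes[header %in% c("maf", "quality_score") |
            startsWith(header, "pop_")] <- "numeric"
  classes[header %in% c("is_germline", "is_deleterious")] <- "logical"
  variants <- utils::read.delim(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = classes,
                                na.strings = c("NA", "."))
  if (!"context11" %in% names(variants))
    variants$context11 <- rep(NA_character_, nrow(variants))
  validate_variants(variants)
  variants
}

#' Write a variant annotation table
#'
#' Inverse of [read_variant_table()]; `write` then `read` round-trips records
#' exactly (up to numeric printing precision, which is kept at full width).
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

# --- CIGAR / SAM-convention helpers -----------------------------------------

#' Parse a CIGAR string into operation lengths and codes
#' @param cigar A single CIGAR string, e.g. `"5S45M2D10M"`.
#' @return Data frame with columns `len` and `op`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(len = integer(), op = character()))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

#' Reference span of a CIGAR string
#' @param cigar CIGAR string.
#' @return Number of reference bases consumed (M/D/N/=/X).
#' @keywords internal
cigar_ref_width <- function(cigar) {
  if (grepl("^\\d+M$", cigar))  # fast path for full-length matches
    return(as.integer(sub("M", "", cigar, fixed = TRUE)))
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

#' Soft-clipped base count of a CIGAR string
#' @param cigar CIGAR string.
#' @return Total `S` bases.
#' @keywords internal
cigar_softclip <- function(cigar) {
  if (!grepl("S", cigar, fixed = TRUE)) return(0L)
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op == "S"])
}

#' Construct a read-record table
#'
#' Read records are SAM-convention alignments held as a data frame with
#' columns `read_id, chrom, pos` (0-based leftmost), `cigar, mapq, sequence,
#' mate_chrom, mate_pos, is_proper_pair, softclip_total`. `softclip_total`
#' defaults to the value implied by the CIGAR.
#'
#' @param read_id,chrom,pos,cigar,mapq,sequence Per-read fields.
#' @param mate_chrom,mate_pos,is_proper_pair Mate fields (defaults: same
#'   chromosome, position 0, proper pair).
#' @param softclip_total Soft-clip base count; `NULL` derives it from `cigar`.
#' @return Read-record data frame.
#' @export
read_records <- function(read_id, chrom, pos, cigar, mapq, sequence,
                         mate_chrom = chrom, mate_pos = 0L,
                         is_proper_pair = TRUE, softclip_total = NULL) {
  n <- length(read_id)
  if (is.null(softclip_total))
    softclip_total <- vapply(cigar, cigar_softclip, 0L, USE.NAMES = FALSE)
  if (any(mapq < 0)) stop("mapq must be >= 0")
  data.frame(read_id = as.character(read_id), chrom = as.character(chrom),
             pos = as.integer(pos), cigar = as.character(cigar),
             mapq = as.integer(mapq), sequence = as.character(sequence),
             mate_chrom = rep_len(as.character(mate_chrom), n),
             mate_pos = rep_len(as.integer(mate_pos), n),
             is_proper_pair = rep_len(as.logical(is_proper_pair), n),
             softclip_total = as.integer(softclip_total),
             stringsAsFactors = FALSE)
}

#' Read SAM-text alignments into a read-record table
#'
#' Parses the eleven mandatory SAM columns from uncompressed SAM text
#' (headers skipped) into the package's read-record frame. POS is converted
#' from SAM's 1-based to the internal 0-based convention.
#'
#' @param path Path to a SAM text file.
#' @return Read-record data frame.
#' @export
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines))
    return(read_records(character(), character(), integer(), character(),
                        integer(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, 0L) < 11L))
    stop("SAM record with fewer than 11 fields in ", path)
  col <- function(i) vapply(f, `[`, "", i)
  flagv <- as.integer(col(2))
  rnext <- col(7)
  chrom <- col(3)
  read_records(
    read_id = col(1), chrom = chrom,
    pos = as.integer(col(4)) - 1L,
    cigar = col(6), mapq = as.integer(col(5)), sequence = col(10),
    mate_chrom = ifelse(rnext == "=", chrom, rnext),
    mate_pos = as.integer(col(8)) - 1L,
    is_proper_pair = bitwAnd(flagv, 2L) > 0L)
}

# --- Coverage ----------------------------------------------------------------

#' Coverage summary over regions of interest
#'
#' Total coverage is the mean per-base read depth over all ROI bases;
#' distinct coverage is the same after collapsing duplicate fragments.
#' Fragments are deduplicated by coordinates: (chrom, pos, reference end,
#' mate position), the only identity available without molecular barcodes.
#'
#' @param reads Read-record data frame.
#' @param rois Interval data frame (0-based half-open).
#' @return List with `total_coverage` and `distinct_coverage`
#'   (`distinct_coverage <= total_coverage` always).
#' @export
compute_coverage_summary <- function(reads, rois) {
  if (nrow(rois) == 0L) stop("empty ROI set")
  depth_over <- function(rd) {
    tot <- 0
    nbase <- sum(rois$end - rois$start)
    if (nrow(rd)) {
      ends <- rd$pos + vapply(rd$cigar, cigar_ref_width, 0L, USE.NAMES = FALSE)
      for (i in seq_len(nrow(rois))) {
        on <- rd$chrom == rois$chrom[i]
        if (!any(on)) next
        ov <- pmin(ends[on], rois$end[i]) - pmax(rd$pos[on], rois$start[i])
        tot <- tot + sum(pmax(ov, 0))
      }
    }
    tot / nbase
  }
  key <- paste(reads$chrom, reads$pos,
               reads$pos + vapply(reads$cigar, cigar_ref_width, 0L,
                                  USE.NAMES = FALSE),
               reads$mate_pos, sep = ":")
  list(total_coverage = depth_over(reads),
       distinct_coverage = depth_over(reads[!duplicated(key), , drop = FALSE]))
}

# --- Repeat-tract discovery --------------------------------------------------

#' Find repeat tracts in a reference sequence
#'
#' Scans a sequence for maximal mono-, di-, or trinucleotide repeat runs with
#' total length in `[min_len, max_len]` bp. Runs whose repeat unit itself has
#' a shorter period (e.g. "AA" as a dinucleotide unit) are attributed to the
#' smaller unit size and skipped. Output intervals are 0-based half-open on
#' the forward strand and never overlap for a given unit size.
#'
#' @param sequence Reference sequence (single character string, ACGT).
#' @param min_len,max_len Inclusive run-length bounds in bp.
#' @param unit Repeat unit size: 1, 2, or 3.
#' @param chrom Chromosome name recorded on the output intervals.
#' @return Interval data frame; `label` holds `unit_sequence:run_length`.
#' @export
find_repeat_tracts <- function(sequence, min_len = 13L, max_len = 30L,
                               unit = 1L, chrom = "seq") {
  stopifnot(unit %in% 1:3, nchar(sequence) > 0L)
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  out <- list()
  if (n >= 2L * unit) {
    # same[i] TRUE when s[i] == s[i - unit]; maximal runs of TRUE of length L
    # correspond to repeat runs of total length L + unit.
    same <- c(rep(FALSE, unit), s[(unit + 1L):n] == s[1:(n - unit)])
    r <- rle(same)
    stop_at <- cumsum(r$lengths)
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      run_len <- r$lengths[j] + unit
      start0 <- stop_at[j] - r$lengths[j] - unit  # 0-based
      u <- paste(s[(start0 + 1L):(start0 + unit)], collapse = "")
      if (unit == 2L && substr(u, 1, 1) == substr(u, 2, 2)) next
      if (unit == 3L && length(unique(strsplit(u, "")[[1]])) == 1L) next
      # trim to a whole number of units for di/tri repeats
      run_len <- run_len - (run_len %% unit)
      if (run_len < min_len || run_len > max_len) next
      out[[length(out) + 1L]] <-
        data.frame(chrom = chrom, start = start0, end = start0 + run_len,
                   label = sprintf("%s:%d", u, run_len),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(genomic_intervals(character(), integer(), integer())[0, ])
  do.call(rbind, out)
}
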