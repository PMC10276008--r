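#' Estimate mutation multiplicity from VAF, purity and allele-specific CN
#'
#' For a clonal mutation on a segment with allele-specific copy number
#' `major:minor` in a tumor of purity `p`, the expected variant allele
#' frequency is `m * p / (p * (major + minor) + 2 * (1 - p))`. Inverting and
#' rounding gives the multiplicity estimate, clamped to `[1, major]`.
#' Rounding ties use round-half-even for cross-platform determinism.
#' Subclonal mutations are out of scope.
#'
#' @param vaf Variant allele frequency in (0, 1].
#' @param major,minor Integer allele-specific copy numbers (`major >=
#'   minor`).
#' @param purity Tumor purity in (0, 1].
#' @return Integer multiplicity estimate(s) `m`.
#' @export
#' @examples
#' estimate_multiplicity(0.5, 2, 0, 1)  # 1
#' estimate_multiplicity(1.0, 2, 0, 1)  # 2
estimate_multiplicity <- function(vaf, major, minor, purity) {
  if (any(purity <= 0)) stop("purity must be positive")
  stopifnot(all(vaf > 0 & vaf <= 1), all(minor <= major))
  m <- round(vaf * (purity * (major + minor) + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(m, 1), major))
}

#' Classify mutation timing relative to the amplification
#'
#' A mutation present on every copy of the major allele (`m` equal to the
#' major allele count) must predate the amplification and is called early; a
#' mutation on fewer copies (`m` below the major allele count) is called
#' late. Note the clock cannot distinguish a pre-amplification single-copy
#' mutation from a post-amplification one, so single-copy calls on amplified
#' segments are conservatively late; the buffered/unbuffered classification
#' ([classify_buffered()]) is the complementary clock.
#'
#' @param m Integer multiplicity.
#' @param major Major allele copy number.
#' @return Character vector `"early"` / `"late"`.
#' @export
classify_timing <- function(m, major) {
  if (any(m > major)) stop("multiplicity exceeds the major allele count")
  if (any(m < 1)) stop("multiplicity below 1")
  ifelse(m == major, "early", "late")
}

#' Classify mutations as buffered or non-buffered
#'
#' A mutation is buffered when the segment retains at least two unmutated
#' copies: `(major + minor) - m >= 2`.
#'
#' @param m Integer multiplicity.
#' @param major,minor Allele-specific copy numbers.
#' @return Logical vector; `TRUE` = buffered.
#' @export
classify_buffered <- function(m, major, minor) {
  (major + minor) - m >= 2
}

#' Multiplicity, timing and buffering calls for a mutation table
#'
#' Joins each mutation to the allele-specific segment covering it (per
#' patient), estimates the multiplicity from VAF and purity, and attaches
#' the early/late and buffered labels. Mutations on sex chromosomes or not
#' covered by any segment are dropped.
#'
#' @param muts Mutation data.frame with `vaf` (and optionally `depth`).
#' @param ascn Allele-specific segment table (`patient`, `chrom`, `start`,
#'   `end`, `major`, `minor`, `purity`).
#' @return `muts` rows that matched a segment, with added columns `major`,
#'   `minor`, `purity`, `m`, `timing`, `buffered`.
#' @export
multiplicity_calls <- function(muts, ascn) {
  muts <- drop_sex_chromosomes(muts)
  muts <- muts[!is.na(muts$vaf) & muts$vaf > 0, , drop = FALSE]
  if (nrow(muts) == 0 || nrow(ascn) == 0) return(muts[0, , drop = FALSE])
  mgr <- GenomicRanges::GRanges(
    paste(muts$patient, muts$chrom, sep = "|"),
    IRanges::IRanges(muts$pos, muts$pos)
  )
  sgr <- GenomicRanges::GRanges(
    paste(ascn$patient, ascn$chrom, sep = "|"),
    IRanges::IRanges(ascn$start, ascn$end)
  )
  suppressWarnings(
    hit <- GenomicRanges::findOverlaps(mgr, sgr, select = "first")
  )
  keep <- !is.na(hit)
  out <- muts[keep, , drop = FALSE]
  seg <- ascn[hit[keep], , drop = FALSE]
  out$major <- seg$major
  out$minor <- seg$minor
  out$purity <- seg$purity
  out$m <- estimate_multiplicity(out$vaf, out$major, out$minor, out$purity)
  out$timing <- classify_timing(out$m, out$major)
  out$buffered <- classify_buffered(out$m, out$major, out$minor)
  rownames(out) <- NULL
  out
}

#' Coding vs non-coding association with late timing, per CN class
#'
#' Within each allele-specific copy-number class (e.g. 2:0, 3:1, 2:2) builds
#' the coding/non-coding x early/late contingency table and applies a
#' two-sided Fisher exact test. Classes with a degenerate margin are skipped
#' with a note. The pooled summary reports the overall early fraction, both
#' mutation-weighted and as an unweighted mean over classes.
#'
#' @param calls Output of [multiplicity_calls()] (needs `is_coding`,
#'   `timing`, `major`, `minor`).
#' @param amplified_only Restrict to amplified segments (`major >= 2`),
#'   where the early/late clock is informative. Default `TRUE`.
#' @return List with `per_class` (data.frame: `cn_class`, `n`,
#'   `coding_late`, `coding_early`, `noncoding_late`, `noncoding_early`,
#'   `odds_ratio`, `p_value`, `note`) and `pooled` (data.frame:
#'   `early_fraction_weighted`, `early_fraction_by_class`, `n_mutations`,
#'   `buffered_fraction`).
#' @export
timing_association <- function(calls, amplified_only = TRUE) {
  if (amplified_only) calls <- calls[calls$major >= 2, , drop = FALSE]
  if (nrow(calls) == 0) stop("no mutations to test")
  cls <- paste0(calls$major, ":", calls$minor)
  per <- lapply(split(seq_len(nrow(calls)), cls), function(ix) {
    cc <- calls[ix, , drop = FALSE]
    tab <- matrix(
      c(sum(cc$is_coding & cc$timing == "late"),
        sum(cc$is_coding & cc$timing == "early"),
        sum(!cc$is_coding & cc$timing == "late"),
        sum(!cc$is_coding & cc$timing == "early")),
      nrow = 2, byrow = TRUE
    )
    res <- data.frame(
      cn_class = paste0(cc$major[1], ":", cc$minor[1]), n = nrow(cc),
      coding_late = tab[1, 1], coding_early = tab[1, 2],
      noncoding_late = tab[2, 1], noncoding_early = tab[2, 2],
      odds_ratio = NA_real_, p_value = NA_real_, note = "",
      early_fraction = sum(cc$timing == "early") / nrow(cc),
      stringsAsFactors = FALSE
    )
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      res$note <- "degenerate margin, test skipped"
    } else {
      ft <- stats::fisher.test(tab)
      res$odds_ratio <- unname(ft$estimate)
      res$p_value <- ft$p.value
    }
    res
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  pooled <- data.frame(
    early_fraction_weighted = mean(calls$timing == "early"),
    early_fraction_by_class = mean(per$early_fraction),
    n_mutations = nrow(calls),
    buffered_fraction = mean(calls$buffered)
  )
  list(per_class = per, pooled = pooled)
}
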