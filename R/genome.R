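#' Define a genome build (chromosome lengths and arm boundaries)
#'
#' The coordinate frame every other function works in. Only the chromosomes
#' listed here are valid; downstream analyses use autosomes only, so X/Y are
#' typically omitted or removed with [drop_sex_chromosomes()].
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer vector of chromosome lengths in base pairs.
#' @param arm_boundary Integer vector of positions splitting the p and q arm
#'   of each chromosome (1-based; the p arm is `[1, arm_boundary]`, the q arm
#'   `(arm_boundary, length]`). Must lie strictly inside the chromosome.
#'
#' @return A `data.frame` of class `genome_build` with columns `chrom`,
#'   `length`, `arm_boundary`.
#' @export
#' @examples
#' genome_build(c("chr1", "chr2"), c(100e6, 80e6), c(60e6, 40e6))
genome_build <- function(chrom, length, arm_boundary) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  arm_boundary <- as.numeric(arm_boundary)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (any(arm_boundary <= 0 | arm_boundary >= length)) {
    stop("arm_boundary must lie strictly inside (0, chrom_length)")
  }
  out <- data.frame(
    chrom = chrom, length = length, arm_boundary = arm_boundary,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Default synthetic genome used by the cohort simulator
#'
#' Five autosomes of 200 Mbp each with the centromere at 90 Mbp, giving a
#' 1 Gbp genome that supports fixed-bin grids from 1 to 50 Mbp.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Length of each autosome in base pairs.
#' @param arm_frac Fraction of the chromosome assigned to the p arm.
#' @return A `genome_build`.
#' @export
default_genome <- function(n_chrom = 5, chrom_length = 200e6, arm_frac = 0.45) {
  genome_build(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = rep(chrom_length, n_chrom),
    arm_boundary = rep(round(chrom_length * arm_frac), n_chrom)
  )
}

sex_chrom_names <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Remove sex-chromosome records
#'
#' The central autosome filter: every analysis excludes chromosomes X and Y.
#' Works on any table with a `chrom` column.
#'
#' @param x A data.frame with a `chrom` column.
#' @return `x` without rows on X or Y.
#' @export
drop_sex_chromosomes <- function(x) {
  stopifnot(is.data.frame(x), "chrom" %in% names(x))
  x[!(x$chrom %in% sex_chrom_names), , drop = FALSE]
}

# Validate that chrom/pos columns fall inside the build; returns x invisibly,
# stops with the offending rows otherwise.
validate_coordinates <- function(x, genome, start_col = "start", end_col = "end") {
  bad_chrom <- setdiff(unique(x$chrom), genome$chrom)
  if (length(bad_chrom)) {
    stop("unknown chromosome(s): ", paste(bad_chrom, collapse = ", "))
  }
  len <- genome$length[match(x$chrom, genome$chrom)]
  if (!is.null(x[[start_col]])) {
    bad <- which(x[[start_col]] < 1 | x[[end_col]] > len | x[[start_col]] > x[[end_col]])
    if (length(bad)) {
      stop(
        "invalid coordinates at row(s): ",
        paste(utils::head(bad, 10), collapse = ", ")
      )
    }
  }
  invisible(x)
}
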