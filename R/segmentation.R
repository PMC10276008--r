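#' Build a segment grid at a chosen genomic scale
#'
#' Partitions each chromosome of the build into the index set over which
#' amplification frequencies and the copy-neutral mutation score are
#' computed: fixed-length bins of `j` base pairs (the last bin of a
#' chromosome may be shorter), chromosome arms, whole chromosomes, or gene
#' bodies.
#'
#' @param genome A `genome_build`.
#' @param scale One of `"fixed"`, `"arm"`, `"chromosome"`, `"gene"`.
#' @param j Bin length in base pairs (required for `scale = "fixed"`).
#' @param genes Gene annotation data.frame (required for `scale = "gene"`).
#' @return A data.frame of class `segment_grid` with columns `bin_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), sorted by chromosome and
#'   start; attributes `scale` and `j`.
#' @export
#' @examples
#' g <- genome_build("chr1", 100e6, 60e6)
#' build_grid(g, "fixed", j = 36e6)   # bins of 36, 36, 28 Mbp
build_grid <- function(genome, scale = c("fixed", "arm", "chromosome", "gene"),
                       j = NULL, genes = NULL) {
  scale <- match.arg(scale)
  if (scale == "fixed") {
    if (is.null(j) || j <= 0) stop("fixed scale requires bin length j > 0")
    pieces <- lapply(seq_len(nrow(genome)), function(k) {
      len <- genome$length[k]
      starts <- seq(1, len, by = j)
      data.frame(
        chrom = genome$chrom[k], start = starts,
        end = pmin(starts + j - 1, len), stringsAsFactors = FALSE
      )
    })
    grid <- do.call(rbind, pieces)
  } else if (scale == "arm") {
    grid <- data.frame(
      chrom = rep(genome$chrom, each = 2),
      start = as.vector(rbind(1, genome$arm_boundary + 1)),
      end = as.vector(rbind(genome$arm_boundary, genome$length)),
      stringsAsFactors = FALSE
    )
  } else if (scale == "chromosome") {
    grid <- data.frame(
      chrom = genome$chrom, start = 1, end = genome$length,
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(genes)) stop("gene scale requires a gene annotation table")
    genes <- drop_sex_chromosomes(genes)
    grid <- data.frame(
      chrom = genes$chrom, start = genes$start, end = genes$end,
      gene = genes$gene, stringsAsFactors = FALSE
    )
  }
  ord <- order(match(grid$chrom, genome$chrom), grid$start)
  grid <- grid[ord, , drop = FALSE]
  grid$bin_id <- if (scale == "gene") grid$gene else {
    paste0(grid$chrom, ":", format(grid$start, scientific = FALSE, trim = TRUE),
           "-", format(grid$end, scientific = FALSE, trim = TRUE))
  }
  rownames(grid) <- NULL
  grid <- grid[, c("bin_id", "chrom", "start", "end")]
  attr(grid, "scale") <- scale
  attr(grid, "j") <- j
  class(grid) <- c("segment_grid", "data.frame")
  grid
}

#' Export a grid as BED
#'
#' @param grid A `segment_grid`.
#' @param path Output path; BED is 0-based half-open.
#' @return `path`, invisibly.
#' @export
write_grid_bed <- function(grid, path) {
  utils::write.table(
    data.frame(grid$chrom, format(grid$start - 1, scientific = FALSE, trim = TRUE),
               format(grid$end, scientific = FALSE, trim = TRUE), grid$bin_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Classify a copy-number call as amplified, deleted or neutral
#'
#' Applies the standard segment-mean cutoff used for SNP-array CNA calls:
#' amplified if the log2-ratio-like `segment_mean` exceeds `+amp_cut`,
#' deleted if below `-amp_cut`, neutral otherwise. The inequalities are
#' strict, so values at exactly the cutoff are neutral.
#'
#' @param segment_mean Numeric vector of segment means.
#' @param amp_cut Positive cutoff (default 0.2).
#' @return Character vector in `c("amplified", "deleted", "neutral")`.
#' @export
classify_call <- function(segment_mean, amp_cut = 0.2) {
  stopifnot(amp_cut > 0)
  ifelse(segment_mean > amp_cut, "amplified",
         ifelse(segment_mean < -amp_cut, "deleted", "neutral"))
}

#' Classify CNA events as chromosomal, arm-level or focal
#'
#' An event is chromosomal when it covers at least 90% of its chromosome,
#' arm-level when it covers at least 50% of its arm, focal otherwise. Calls
#' spanning the centromere use the arm with the larger overlap for the arm
#' test.
#'
#' @param calls Data.frame of CNA calls (`chrom`, `start`, `end`).
#' @param genome A `genome_build`.
#' @return Character vector in `c("chromosomal", "arm", "focal")`, one per
#'   call.
#' @export
classify_event <- function(calls, genome) {
  i <- match(calls$chrom, genome$chrom)
  if (anyNA(i)) stop("call on chromosome absent from the genome build")
  chrom_len <- genome$length[i]
  bnd <- genome$arm_boundary[i]
  ev_len <- calls$end - calls$start + 1
  p_len <- bnd
  q_len <- chrom_len - bnd
  # overlap of the event with each arm (1-based inclusive)
  p_ov <- pmax(0, pmin(calls$end, bnd) - calls$start + 1)
  q_ov <- pmax(0, calls$end - pmax(calls$start, bnd + 1) + 1)
  arm_len <- ifelse(p_ov >= q_ov, p_len, q_len)
  arm_ov <- pmax(p_ov, q_ov)
  ifelse(ev_len >= 0.9 * chrom_len, "chromosomal",
         ifelse(arm_ov >= 0.5 * arm_len, "arm", "focal"))
}

#' Per-patient copy-number state of every grid bin
#'
#' For each (patient, bin) pair the bin is amplified (`A`) when amplified
#' calls passing the event-class filter cover at least `overlap_frac` of the
#' bin (union of same-state calls), deleted (`D`) under the symmetric rule,
#' and copy-neutral (`N`) otherwise -- including patients with no overlapping
#' call at all. When both states qualify, the one with larger bin coverage
#' wins; exact ties go to `A` with a warning.
#'
#' @param calls CNA call data.frame (`patient`, `chrom`, `start`, `end`,
#'   `segment_mean`).
#' @param grid A `segment_grid`.
#' @param patients Character vector defining the patient universe; every
#'   patient in `calls` must be listed.
#' @param genome A `genome_build` (needed when `event_filter` is not all
#'   classes).
#' @param amp_cut Segment-mean cutoff passed to [classify_call()].
#' @param overlap_frac Fraction of the bin that must be covered for a state
#'   to be inherited; `> 0` values behave as "any overlap" when set to a
#'   small epsilon, 0.5 is majority coverage, 1 requires full coverage.
#' @param event_filter Subset of `c("chromosomal", "arm", "focal")` to use.
#' @return A character matrix (bins x patients, values `"A"`, `"D"`, `"N"`)
#'   with `rownames = bin_id`, `colnames = patients`.
#' @export
patient_bin_states <- function(calls, grid, patients, genome = NULL,
                               amp_cut = 0.2, overlap_frac = 0.5,
                               event_filter = c("chromosomal", "arm", "focal")) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  patients <- as.character(patients)
  if (!all(calls$patient %in% patients)) {
    stop("calls contain patients outside the supplied patient universe")
  }
  states <- matrix("N", nrow = nrow(grid), ncol = length(patients),
                   dimnames = list(grid$bin_id, patients))
  if (nrow(calls) == 0) return(states)

  calls$state <- classify_call(calls$segment_mean, amp_cut)
  calls <- calls[calls$state != "neutral", , drop = FALSE]
  if (!setequal(event_filter, c("chromosomal", "arm", "focal"))) {
    if (is.null(genome)) stop("event_filter other than all classes needs a genome")
    calls <- calls[classify_event(calls, genome) %in% event_filter, , drop = FALSE]
  }
  if (nrow(calls) == 0) return(states)

  cgr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
  bgr <- GenomicRanges::GRanges(grid$chrom, IRanges::IRanges(grid$start, grid$end))
  hits <- GenomicRanges::findOverlaps(cgr, bgr)
  if (length(hits) == 0) return(states)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(calls$start[qi], grid$start[si])
  ov_end <- pmin(calls$end[qi], grid$end[si])
  ov <- ov_end - ov_start + 1

  # union coverage of same-state calls per (patient, bin, state): sorted-scan
  # union width, fully vectorized (cummax within groups)
  pat_i <- match(calls$patient[qi], patients)
  amp_i <- as.integer(calls$state[qi] == "amplified")
  n_bin <- nrow(grid)
  key <- ((pat_i - 1) * n_bin + (si - 1)) * 2 + amp_i
  o <- order(key, ov_start)
  k <- key[o]; s <- ov_start[o]; e <- ov_end[o]
  new_grp <- c(TRUE, k[-1] != k[-length(k)])
  grp <- cumsum(new_grp)
  ecm <- stats::ave(e, grp, FUN = cummax)
  prev <- c(-Inf, ecm[-length(ecm)])
  prev[new_grp] <- -Inf
  add <- pmax(0, ecm - pmax(prev, s - 1))
  cov <- rowsum(add, grp)[, 1]
  ukey <- k[new_grp]
  covdf <- data.frame(
    pat = (ukey %/% 2) %/% n_bin + 1,
    bin = (ukey %/% 2) %% n_bin + 1,
    amp = ukey %% 2 == 1,
    cov = as.numeric(cov)
  )
  bin_len <- grid$end - grid$start + 1
  covdf <- covdf[covdf$cov >= overlap_frac * bin_len[covdf$bin], , drop = FALSE]
  if (nrow(covdf) == 0) return(states)

  # resolve A/D conflicts: larger coverage wins, ties -> A with a warning
  pb <- (covdf$pat - 1) * n_bin + covdf$bin
  if (anyDuplicated(pb)) {
    o2 <- order(pb, -covdf$cov, !covdf$amp)  # best row first within (pat, bin)
    covdf <- covdf[o2, , drop = FALSE]
    pb <- pb[o2]
    dup <- duplicated(pb)
    ties <- covdf$cov[dup] == covdf$cov[!dup][match(pb[dup], pb[!dup])]
    if (any(ties)) warning("A/D coverage tie(s) resolved in favor of amplified")
    covdf <- covdf[!dup, , drop = FALSE]
  }
  states[cbind(covdf$bin, covdf$pat)] <- ifelse(covdf$amp, "A", "D")
  states
}

#' Map gene midpoints to grid bins
#'
#' Genes straddling several fixed bins are assigned to the bin containing
#' the gene midpoint, giving each gene a unique bin.
#'
#' @param genes Gene annotation data.frame.
#' @param grid A `segment_grid`.
#' @return Integer vector of grid row indices (NA when the midpoint falls in
#'   no bin, e.g. on a chromosome absent from the grid), one per gene.
#' @export
gene_bin_map <- function(genes, grid) {
  mid <- floor((genes$start + genes$end) / 2)
  assign_bins(genes$chrom, mid, grid)
}

# Assign positions to grid bins; returns row indices into grid (NA if none).
assign_bins <- function(chrom, pos, grid) {
  pgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  bgr <- GenomicRanges::GRanges(grid$chrom, IRanges::IRanges(grid$start, grid$end))
  hit <- GenomicRanges::findOverlaps(pgr, bgr, select = "first")
  as.integer(hit)
}
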