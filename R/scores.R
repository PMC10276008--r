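#' Coding base pairs per grid bin
#'
#' Apportions each gene's coding length to the bin containing the gene
#' midpoint. For gene-scale grids each gene's own `coding_bp` is used
#' directly.
#'
#' @param genes Gene annotation data.frame with `coding_bp`.
#' @param grid A `segment_grid`.
#' @return Numeric vector of coding base pairs, one per grid bin.
#' @export
bin_coding_bp <- function(genes, grid) {
  if (identical(attr(grid, "scale"), "gene")) {
    out <- genes$coding_bp[match(grid$bin_id, genes$gene)]
    out[is.na(out)] <- 0
    return(out)
  }
  bin <- gene_bin_map(genes, grid)
  out <- numeric(nrow(grid))
  ok <- !is.na(bin)
  tab <- tapply(genes$coding_bp[ok], bin[ok], sum)
  out[as.integer(names(tab))] <- as.numeric(tab)
  out
}

#' Copy-neutral mutation score for a single bin
#'
#' The mutation-rate measure at the core of the buffering analysis:
#' `mu = log10( n_mut / (coding_bp * n_N) )`, where `n_mut` counts coding
#' mutations carried by patients whose copy-number state in the bin is
#' neutral, and `n_N` is the number of copy-neutral patients. Restricting
#' the numerator to copy-neutral patients removes the trivial confounder
#' that amplified segments present more copies in which mutations can occur.
#' Undefined (`NA`) when the count is zero, `n_N = 0` or `coding_bp = 0`.
#'
#' @param n_mut_neutral Number of coding mutations in copy-neutral patients.
#' @param n_N Number of copy-neutral patients in the bin.
#' @param coding_bp Coding base pairs in the bin.
#' @return The mu score (log10 mutations per coding base per copy-neutral
#'   patient) or `NA`.
#' @export
#' @examples
#' mu_score(10, 5, 1e6)  # log10(10 / 5e6) = -5.69897
mu_score <- function(n_mut_neutral, n_N, coding_bp) {
  ifelse(n_mut_neutral > 0 & n_N > 0 & coding_bp > 0,
         log10(n_mut_neutral / (coding_bp * n_N)), NA_real_)
}

#' Per-bin scores from a precomputed state matrix
#'
#' The workhorse behind [score_table()], exposed so that stratified
#' analyses can recompute the mu score for mutation subsets without
#' re-deriving patient bin states.
#'
#' @param states Character state matrix from [patient_bin_states()].
#' @param muts Mutation data.frame; only coding, autosomal records should be
#'   passed (the function filters both as a safeguard).
#' @param grid The `segment_grid` the states were computed on.
#' @param coding_bp Numeric vector of coding base pairs per bin.
#' @param mu_zero_policy `"drop"` leaves zero-mutation bins undefined;
#'   `"pseudocount"` adds `pseudo_k` to every numerator.
#' @param pseudo_k Pseudocount used when `mu_zero_policy = "pseudocount"`.
#' @return A data.frame with one row per bin: `bin_id`, `chrom`, `start`,
#'   `end`, `amp_freq`, `del_freq`, `mu`, `n_A`, `n_D`, `n_N`, `coding_bp`,
#'   `n_mut_neutral`.
#' @export
score_from_states <- function(states, muts, grid, coding_bp,
                              mu_zero_policy = c("drop", "pseudocount"),
                              pseudo_k = 0.5) {
  mu_zero_policy <- match.arg(mu_zero_policy)
  n_pat <- ncol(states)
  n_A <- rowSums(states == "A")
  n_D <- rowSums(states == "D")
  n_N <- n_pat - n_A - n_D

  muts <- muts[muts$is_coding & !(muts$chrom %in% sex_chrom_names), , drop = FALSE]
  muts <- muts[muts$patient %in% colnames(states), , drop = FALSE]
  n_mut <- numeric(nrow(grid))
  if (nrow(muts) > 0) {
    bin <- assign_bins(muts$chrom, muts$pos, grid)
    pat <- match(muts$patient, colnames(states))
    ok <- !is.na(bin) & states[cbind(bin, pat)] == "N"
    if (any(ok)) {
      tab <- tabulate(bin[ok], nbins = nrow(grid))
      n_mut <- as.numeric(tab)
    }
  }
  numer <- if (mu_zero_policy == "pseudocount") n_mut + pseudo_k else n_mut
  data.frame(
    bin_id = grid$bin_id, chrom = grid$chrom, start = grid$start,
    end = grid$end,
    amp_freq = n_A / n_pat, del_freq = n_D / n_pat,
    mu = mu_score(numer, n_N, coding_bp),
    n_A = n_A, n_D = n_D, n_N = n_N,
    coding_bp = coding_bp, n_mut_neutral = n_mut,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-bin amplification/deletion frequencies and mu scores for a cohort
#'
#' Orchestrates one cohort: derives the per-patient bin states from the CNA
#' calls, counts coding mutations carried by copy-neutral patients in each
#' bin, and returns amplification frequency, deletion frequency and the mu
#' score per bin. The patient universe is the intersection of
#' CNA-profiled and mutation-profiled patients (a mismatch is reported via a
#' message) unless `patients` is given explicitly.
#'
#' @param cna CNA call data.frame (`patient`, `chrom`, `start`, `end`,
#'   `segment_mean`).
#' @param muts Mutation data.frame.
#' @param grid A `segment_grid`.
#' @param genes Gene annotation table used for per-bin coding base pairs
#'   (ignored when `coding_bp` is given).
#' @param genome A `genome_build` (only needed for event-class filtering).
#' @param patients Optional explicit patient universe.
#' @param coding_bp Optional precomputed per-bin coding base pairs.
#' @param amp_cut,overlap_frac,event_filter Passed to
#'   [patient_bin_states()].
#' @param mu_zero_policy,pseudo_k Passed to [score_from_states()].
#' @return A data.frame as returned by [score_from_states()].
#' @export
score_table <- function(cna, muts, grid, genes = NULL, genome = NULL,
                        patients = NULL, coding_bp = NULL,
                        amp_cut = 0.2, overlap_frac = 0.5,
                        event_filter = c("chromosomal", "arm", "focal"),
                        mu_zero_policy = "drop", pseudo_k = 0.5) {
  if (is.null(patients)) {
    pc <- unique(cna$patient)
    pm <- unique(muts$patient)
    patients <- sort(intersect(pc, pm))
    if (length(patients) == 0) stop("no patients shared between CNA and mutation tables")
    drop_n <- length(union(pc, pm)) - length(patients)
    if (drop_n > 0) {
      message(drop_n, " patient(s) present in only one of the two tables were dropped")
    }
  }
  if (is.null(coding_bp)) {
    if (is.null(genes)) stop("either genes or coding_bp must be supplied")
    coding_bp <- bin_coding_bp(genes, grid)
  }
  cna <- cna[cna$patient %in% patients, , drop = FALSE]
  states <- patient_bin_states(cna, grid, patients, genome,
                               amp_cut = amp_cut, overlap_frac = overlap_frac,
                               event_filter = event_filter)
  score_from_states(states, muts, grid, coding_bp,
                    mu_zero_policy = mu_zero_policy, pseudo_k = pseudo_k)
}

#' Cohort-level pooled summary
#'
#' Pools the per-bin scores of one cohort: mean amplification and deletion
#' frequencies, the pooled mu score computed as the mean of the
#' de-logged per-bin mu values followed by a log10 transform, and the
#' mutation burden (coding autosomal mutations per patient).
#'
#' @param scores Per-bin score table from [score_table()].
#' @param muts Mutation data.frame of the same cohort.
#' @param patients Patient universe used for the burden denominator.
#' @param cohort Cohort label.
#' @return A one-row data.frame: `cohort`, `mean_amp_freq`, `mean_del_freq`,
#'   `pooled_mu`, `mutation_burden`, `n_bins_defined`.
#' @export
cohort_summary <- function(scores, muts, patients, cohort = "cohort") {
  def <- !is.na(scores$mu)
  if (!any(def)) stop("no bin with a defined mu score")
  coding <- muts[muts$is_coding & !(muts$chrom %in% sex_chrom_names) &
                   muts$patient %in% patients, , drop = FALSE]
  data.frame(
    cohort = cohort,
    mean_amp_freq = mean(scores$amp_freq),
    mean_del_freq = mean(scores$del_freq),
    pooled_mu = log10(mean(10^scores$mu[def])),
    mutation_burden = nrow(coding) / length(patients),
    n_bins_defined = sum(def),
    stringsAsFactors = FALSE
  )
}
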