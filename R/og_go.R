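#' Oncogene and proliferation-gene densities per bin
#'
#' The relative density of oncogenes (OGs) and proliferation-inducing
#' ("GO") genes within each segment: number of list genes in the bin over
#' the number of genes in the bin, with genes assigned to the bin containing
#' their midpoint. Bins without genes get `NA` densities and are excluded
#' downstream.
#'
#' @param genes Gene annotation table.
#' @param grid A `segment_grid`.
#' @param og_list Character vector of oncogene symbols (typically the
#'   top-250 ranked set; the ranking is consumed, not recomputed).
#' @param go_list Character vector of proliferation-inducing gene symbols.
#' @return Data.frame: `bin_id`, `og_score`, `go_score`, `n_genes`.
#' @export
density_scores <- function(genes, grid, og_list, go_list) {
  bin <- gene_bin_map(genes, grid)
  ok <- !is.na(bin)
  n_genes <- tabulate(bin[ok], nbins = nrow(grid))
  n_og <- tabulate(bin[ok][genes$gene[ok] %in% og_list], nbins = nrow(grid))
  n_go <- tabulate(bin[ok][genes$gene[ok] %in% go_list], nbins = nrow(grid))
  data.frame(
    bin_id = grid$bin_id,
    og_score = ifelse(n_genes > 0, n_og / n_genes, NA_real_),
    go_score = ifelse(n_genes > 0, n_go / n_genes, NA_real_),
    n_genes = n_genes, stringsAsFactors = FALSE
  )
}

# Min-max scale to [0, 1]; constant vectors map to 0.
minmax_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) return(ifelse(is.na(x), NA_real_, 0))
  (x - r[1]) / (r[2] - r[1])
}

# Shared predictor: OG density + GO density + min-max scaled mu, on bins
# where all terms are defined.
oggo_predictor <- function(density, scores) {
  stopifnot(identical(density$bin_id, scores$bin_id))
  mu_s <- minmax_scale(scores$mu)
  data.frame(
    bin_id = scores$bin_id,
    amp_freq = scores$amp_freq,
    oggo = density$og_score + density$go_score,
    mu_scaled = mu_s,
    full = density$og_score + density$go_score + mu_s,
    stringsAsFactors = FALSE
  )
}

#' Additive OG + GO + mu model of the amplification pattern
#'
#' Compares three predictors of per-bin amplification frequency by Spearman
#' correlation: the OG + GO density sum, the mu score alone, and their
#' unweighted sum after min-max scaling mu to [0, 1] (the densities are
#' already in [0, 1]). A combined model beating both components indicates
#' that driver density and mutation buffering explain complementary parts of
#' the amplification landscape.
#'
#' @param density Per-bin densities from [density_scores()].
#' @param scores Per-bin score table from [score_table()] on the same grid.
#' @return Data.frame with one row per model (`og_go`, `mu`, `og_go_mu`):
#'   `model`, `rho`, `p_value`, `n_bins`.
#' @export
combined_model <- function(density, scores) {
  pr <- oggo_predictor(density, scores)
  models <- c(og_go = "oggo", mu = "mu_scaled", og_go_mu = "full")
  out <- do.call(rbind, lapply(names(models), function(m) {
    r <- correlate(pr, paste0("amp_freq~", models[[m]]), stratum_label = m)
    data.frame(model = m, rho = r$rho, p_value = r$p_value, n_bins = r$n_bins,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort-swap control for the combined model
#'
#' Correlates each cohort's OG + GO + mu predictor against the other
#' cohort's amplification frequencies. Tissue-specific structure should make
#' the swapped correlations drop below the matched ones in both directions.
#'
#' @param density_a,scores_a Densities and scores of cohort A.
#' @param density_b,scores_b Densities and scores of cohort B (same grid).
#' @param labels Length-2 character vector of cohort labels.
#' @return Data.frame with rows `matched_A`, `matched_B`, `A_pred_on_B`,
#'   `B_pred_on_A`: `comparison`, `rho`, `p_value`, `n_bins`.
#' @export
swap_control <- function(density_a, scores_a, density_b, scores_b,
                         labels = c("A", "B")) {
  if (!identical(scores_a$bin_id, scores_b$bin_id)) {
    stop("the two cohorts are not scored on the same grid")
  }
  pa <- oggo_predictor(density_a, scores_a)
  pb <- oggo_predictor(density_b, scores_b)
  run <- function(pred, amp, label) {
    df <- data.frame(amp_freq = amp, full = pred)
    r <- correlate(df, "amp_freq~full", stratum_label = label)
    data.frame(comparison = label, rho = r$rho, p_value = r$p_value,
               n_bins = r$n_bins, stringsAsFactors = FALSE)
  }
  out <- rbind(
    run(pa$full, pa$amp_freq, paste0("matched_", labels[1])),
    run(pb$full, pb$amp_freq, paste0("matched_", labels[2])),
    run(pa$full, pb$amp_freq, paste0(labels[1], "_pred_on_", labels[2])),
    run(pb$full, pa$amp_freq, paste0(labels[2], "_pred_on_", labels[1]))
  )
  rownames(out) <- NULL
  out
}
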