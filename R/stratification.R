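#' Spearman correlation between two per-bin score columns
#'
#' Rank correlation (midranks for ties) between, e.g., amplification
#' frequency and the mu score across the bins of one cohort; the positive
#' association between the two is the package's proxy for mutation
#' buffering. Bins with an undefined mu are dropped. The p-value uses the
#' exact permutation distribution when there are no ties and at most 10
#' usable bins, and the standard t-approximation otherwise. No
#' multiple-testing correction is applied.
#'
#' @param scores Per-bin score table ([score_table()]).
#' @param pair Formula-like string `"x~y"` naming two columns of `scores`
#'   (default `"amp_freq~mu"`).
#' @param stratum_label Optional label carried into the output.
#' @return One-row data.frame: `variable_pair`, `stratum_label`, `rho`,
#'   `p_value`, `n_bins`. `rho` is `NA` (with reason in `note`) for fewer
#'   than 3 usable bins or a degenerate (constant) variable.
#' @export
correlate <- function(scores, pair = "amp_freq~mu", stratum_label = "control") {
  vars <- strsplit(pair, "~", fixed = TRUE)[[1]]
  if (length(vars) != 2 || !all(vars %in% names(scores))) {
    stop("pair must name two columns of the score table, e.g. 'amp_freq~mu'")
  }
  x <- scores[[vars[1]]]
  y <- scores[[vars[2]]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  res <- data.frame(
    variable_pair = pair, stratum_label = stratum_label,
    rho = NA_real_, p_value = NA_real_, n_bins = length(x),
    note = "", stringsAsFactors = FALSE
  )
  if (length(x) < 3) {
    res$note <- "fewer than 3 usable bins"
    return(res)
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    res$note <- "degenerate: constant variable"
    return(res)
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (!ties && length(x) <= 10))
  )
  res$rho <- unname(ct$estimate)
  res$p_value <- ct$p.value
  res
}

#' Sweep segmentation scales
#'
#' Recomputes the per-bin scores and the amplification-frequency / mu
#' correlation at each requested scale -- gene bodies, fixed bins over a
#' range of lengths, chromosome arms, whole chromosomes -- and reports the
#' scale with the largest rho. This is how the characteristic length of the
#' buffering signal is located.
#'
#' @param cna,muts,genes,genome Cohort inputs as in [score_table()].
#' @param js Numeric vector of fixed bin lengths (bp) to sweep.
#' @param named_scales Character subset of `c("gene", "arm", "chromosome")`
#'   to include alongside the fixed bins.
#' @param pair Correlation pair, default `"amp_freq~mu"`.
#' @param ... Passed to [score_table()].
#' @return Data.frame with one row per scale: `scale`, `j`, `rho`,
#'   `p_value`, `n_bins`; attribute `argmax` holds the row index of the
#'   maximal rho.
#' @export
sweep_scales <- function(cna, muts, genes, genome,
                         js = seq(1e6, 50e6, by = 1e6),
                         named_scales = character(0),
                         pair = "amp_freq~mu", ...) {
  rows <- list()
  for (sc in named_scales) {
    grid <- build_grid(genome, sc, genes = genes)
    st <- score_table(cna, muts, grid, genes = genes, genome = genome, ...)
    r <- correlate(st, pair, stratum_label = sc)
    rows[[length(rows) + 1L]] <- data.frame(
      scale = sc, j = NA_real_, rho = r$rho, p_value = r$p_value,
      n_bins = r$n_bins, stringsAsFactors = FALSE
    )
  }
  for (j in js) {
    grid <- build_grid(genome, "fixed", j = j)
    st <- score_table(cna, muts, grid, genes = genes, genome = genome, ...)
    r <- correlate(st, pair, stratum_label = paste0("fixed_", j))
    rows[[length(rows) + 1L]] <- data.frame(
      scale = "fixed", j = j, rho = r$rho, p_value = r$p_value,
      n_bins = r$n_bins, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "argmax") <- if (all(is.na(out$rho))) NA_integer_ else which.max(out$rho)
  out
}

#' Built-in gene- and mutation-property strata
#'
#' Each stratum assigns every mutation to the stratum (`"in"`), its
#' complement (`"out"`) or a discarded band (`"drop"`, e.g. missing scores
#' or the PolyPhen middle band), as a pure function of the mutation record
#' and the annotation of its gene. Gene-based strata also expose a
#' `gene_filter` so the coding-length denominator can optionally be
#' restricted to stratum genes.
#'
#' Built-ins: haploinsufficiency by pLI (> 0.2) and by GHIS (> 0.5),
#' expression (median TPM > 0), damaging mutations by CADD (> 3.5 vs < 3.5)
#' and PolyPhen (> 0.6 vs < 0.3, middle band dropped), non-synonymous vs
#' synonymous, aggregation-causing (score > 5000 and fold change > 1), and
#' driver removal (mutations outside OGs, outside TSGs, outside both).
#'
#' @return Named list of strata; each element has `name`, `complement_name`,
#'   `assign(muts, genes)` and optionally `gene_filter(genes)`.
#' @export
strata_registry <- function() {
  gene_col <- function(muts, genes, col) genes[[col]][match(muts$gene, genes$gene)]
  three_way <- function(v, hi, lo = hi) {
    ifelse(is.na(v), "drop", ifelse(v > hi, "in", ifelse(v < lo, "out",
           if (hi == lo) "out" else "drop")))
  }
  list(
    pli = list(
      name = "pli_haploinsufficient", complement_name = "pli_tolerant",
      assign = function(muts, genes) {
        v <- gene_col(muts, genes, "pli")
        ifelse(is.na(v), "drop", ifelse(v > 0.2, "in", "out"))
      },
      gene_filter = function(genes) !is.na(genes$pli) & genes$pli > 0.2
    ),
    ghis = list(
      name = "ghis_haploinsufficient", complement_name = "ghis_tolerant",
      assign = function(muts, genes) {
        v <- gene_col(muts, genes, "ghis")
        ifelse(is.na(v), "drop", ifelse(v > 0.5, "in", "out"))
      },
      gene_filter = function(genes) !is.na(genes$ghis) & genes$ghis > 0.5
    ),
    expressed = list(
      name = "expressed", complement_name = "non_expressed",
      assign = function(muts, genes) {
        v <- gene_col(muts, genes, "median_tpm")
        ifelse(is.na(v), "drop", ifelse(v > 0, "in", "out"))
      },
      gene_filter = function(genes) !is.na(genes$median_tpm) & genes$median_tpm > 0
    ),
    cadd = list(
      name = "cadd_damaging", complement_name = "cadd_benign",
      assign = function(muts, genes) three_way(muts$cadd, 3.5, 3.5)
    ),
    polyphen = list(
      name = "polyphen_damaging", complement_name = "polyphen_benign",
      assign = function(muts, genes) three_way(muts$polyphen, 0.6, 0.3)
    ),
    synonymy = list(
      name = "non_synonymous", complement_name = "synonymous",
      assign = function(muts, genes) ifelse(muts$is_synonymous, "out", "in")
    ),
    aggregation = list(
      name = "aggregation_causing", complement_name = "non_aggregation",
      assign = function(muts, genes) {
        s <- muts$aggregation_score
        fc <- muts$aggregation_fold_change
        ifelse(is.na(s) | is.na(fc), "drop",
               ifelse(s > 5000 & fc > 1, "in", "out"))
      }
    ),
    no_og = list(
      name = "no_og", complement_name = "og_only",
      assign = function(muts, genes) {
        v <- gene_col(muts, genes, "is_og")
        ifelse(!is.na(v) & v, "out", "in")
      }
    ),
    no_tsg = list(
      name = "no_tsg", complement_name = "tsg_only",
      assign = function(muts, genes) {
        v <- gene_col(muts, genes, "is_tsg")
        ifelse(!is.na(v) & v, "out", "in")
      }
    ),
    no_og_tsg = list(
      name = "no_og_tsg", complement_name = "og_tsg_only",
      assign = function(muts, genes) {
        og <- gene_col(muts, genes, "is_og")
        tsg <- gene_col(muts, genes, "is_tsg")
        drv <- (!is.na(og) & og) | (!is.na(tsg) & tsg)
        ifelse(drv, "out", "in")
      }
    )
  )
}

#' Load a strata registry from a YAML file
#'
#' Each entry needs `name`, `column`, `operator` (one of `>`, `>=`, `<`,
#' `<=`, `==`), `threshold` and `source` (`"gene"` or `"mutation"`); records
#' failing the predicate form the complement, records with a missing value
#' are dropped.
#'
#' @param path Path to the YAML file.
#' @return A strata registry list compatible with
#'   [stratified_correlations()].
#' @export
read_strata_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  spec <- yaml::read_yaml(path)
  out <- lapply(spec, function(s) {
    op <- match.fun(s$operator)
    thr <- s$threshold
    col <- s$column
    from_gene <- identical(s$source, "gene")
    list(
      name = s$name,
      complement_name = paste0("not_", s$name),
      assign = function(muts, genes) {
        v <- if (from_gene) genes[[col]][match(muts$gene, genes$gene)] else muts[[col]]
        ifelse(is.na(v), "drop", ifelse(op(v, thr), "in", "out"))
      }
    )
  })
  names(out) <- vapply(spec, `[[`, "", "name")
  out
}

#' Correlations stratified by gene and mutation properties
#'
#' For each stratum the mu score is recomputed using only the mutations the
#' stratum keeps (the amplification and deletion frequencies are left
#' untouched) and re-correlated against the amplification frequency; the
#' unfiltered control is always included. Used to ask which kinds of
#' mutation drive the buffering signal.
#'
#' @param states State matrix from [patient_bin_states()].
#' @param muts Mutation data.frame.
#' @param genes Gene annotation table.
#' @param grid The grid the states were computed on.
#' @param coding_bp Per-bin coding base pairs ([bin_coding_bp()]).
#' @param strata A registry as from [strata_registry()] (any subset).
#' @param include_complement Also compute each stratum's complement.
#' @param restrict_coding_bp When `TRUE`, gene-based strata also restrict
#'   the coding-length denominator to stratum genes; default keeps the
#'   all-gene denominator.
#' @param pair Correlation pair, default `"amp_freq~mu"`.
#' @return Data.frame of [correlate()] rows, one per stratum (plus
#'   complements and the control), with `n_mut` used per stratum. Strata
#'   retaining no mutations get `rho = NA` and a note.
#' @export
stratified_correlations <- function(states, muts, genes, grid, coding_bp,
                                    strata = strata_registry(),
                                    include_complement = TRUE,
                                    restrict_coding_bp = FALSE,
                                    pair = "amp_freq~mu") {
  one <- function(m, label, bp) {
    st <- score_from_states(states, m, grid, bp)
    r <- correlate(st, pair, stratum_label = label)
    r$n_mut <- nrow(m)
    if (nrow(m) == 0) r$note <- "stratum retained no mutations"
    r
  }
  rows <- list(one(muts, "control", coding_bp))
  for (s in strata) {
    grp <- s$assign(muts, genes)
    bp_in <- coding_bp
    bp_out <- coding_bp
    if (restrict_coding_bp && !is.null(s$gene_filter)) {
      keep <- s$gene_filter(genes)
      bp_in <- bin_coding_bp(genes[keep, , drop = FALSE], grid)
      bp_out <- bin_coding_bp(genes[!keep, , drop = FALSE], grid)
    }
    rows[[length(rows) + 1L]] <- one(muts[grp == "in", , drop = FALSE], s$name, bp_in)
    if (include_complement) {
      rows[[length(rows) + 1L]] <-
        one(muts[grp == "out", , drop = FALSE], s$complement_name, bp_out)
    }
  }
  do.call(rbind, rows)
}

#' Paired comparison of correlation distributions across cohorts
#'
#' Paired two-sided Wilcoxon signed-rank test on per-cohort rho values,
#' e.g. stratum vs control across the significant tumor types.
#'
#' @param rho1,rho2 Numeric vectors of correlations, named by cohort; the
#'   names must pair up.
#' @return One-row data.frame: `statistic`, `p_value`, `n_pairs`,
#'   `median_diff`.
#' @export
compare_strata <- function(rho1, rho2) {
  if (!is.null(names(rho1)) || !is.null(names(rho2))) {
    if (is.null(names(rho1)) || is.null(names(rho2)) ||
        !setequal(names(rho1), names(rho2))) {
      stop("unpaired cohorts: ",
           paste(c(setdiff(names(rho1), names(rho2)),
                   setdiff(names(rho2), names(rho1))), collapse = ", "))
    }
    rho2 <- rho2[names(rho1)]
  } else if (length(rho1) != length(rho2)) {
    stop("rho vectors differ in length and carry no cohort names")
  }
  ok <- stats::complete.cases(rho1, rho2)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  wt <- stats::wilcox.test(rho1[ok], rho2[ok], paired = TRUE)
  data.frame(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_pairs = sum(ok), median_diff = stats::median(rho1[ok] - rho2[ok])
  )
}

#' Correlation between per-cohort buffering strength and mutation burden
#'
#' Tests whether tumor types with higher mutation load show stronger
#' amplification/mu association: Spearman correlation between each cohort's
#' buffering rho and its coding mutation burden.
#'
#' @param burden Numeric vector of per-cohort mutation burdens, named by
#'   cohort.
#' @param rho Numeric vector of per-cohort buffering correlations, named by
#'   cohort.
#' @return One-row data.frame: `rho`, `p_value`, `n_cohorts` (`NA` with
#'   fewer than 3 cohorts).
#' @export
meta_correlation <- function(burden, rho) {
  if (!is.null(names(burden)) && !is.null(names(rho))) rho <- rho[names(burden)]
  ok <- stats::complete.cases(burden, rho)
  if (sum(ok) < 3) {
    return(data.frame(rho = NA_real_, p_value = NA_real_, n_cohorts = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(burden[ok], rho[ok], method = "spearman", exact = FALSE)
  )
  data.frame(rho = unname(ct$estimate), p_value = ct$p.value, n_cohorts = sum(ok))
}

#' Keep only cohorts with a significant buffering correlation
#'
#' @param results Data.frame with columns `cohort` and `p_value`.
#' @param alpha Significance cutoff (default 0.05, uncorrected).
#' @return The subset of rows with `p_value <= alpha`.
#' @export
significant_cohorts <- function(results, alpha = 0.05) {
  results[!is.na(results$p_value) & results$p_value <= alpha, , drop = FALSE]
}
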