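#' Per-gene amplification frequency and mu score
#'
#' Runs the scoring machinery on a gene-scale grid: each gene body is a bin,
#' its own coding length the denominator. Non-expressed genes (median TPM of
#' zero) are removed before scoring, and genes whose mu is undefined are
#' excluded from the output with a message.
#'
#' @param cna,muts,genes,genome Cohort inputs as in [score_table()].
#' @param ... Further arguments to [score_table()].
#' @return Data.frame: `gene`, `chrom`, `start`, `end`, `amp_freq`, `mu`,
#'   `n_A`, `n_D`, `n_N`, `coding_bp`, `n_mut_neutral`.
#' @export
gene_scores <- function(cna, muts, genes, genome, ...) {
  if ("median_tpm" %in% names(genes)) {
    genes <- genes[is.na(genes$median_tpm) | genes$median_tpm > 0, , drop = FALSE]
  }
  grid <- build_grid(genome, "gene", genes = genes)
  st <- score_table(cna, muts, grid, genes = genes, genome = genome, ...)
  drop <- is.na(st$mu)
  if (any(drop)) {
    message(sum(drop), " gene(s) with undefined mu excluded")
  }
  st <- st[!drop, , drop = FALSE]
  names(st)[names(st) == "bin_id"] <- "gene"
  rownames(st) <- NULL
  st
}

#' Permutation-based per-gene protection index
#'
#' The protection index of a gene is its amplification frequency minus its
#' mu score; genes amplified far more often than their mutation exposure
#' predicts are candidates for buffering-driven protection. Because the raw
#' mu score is a negative log10 rate while the amplification frequency lives
#' in [0, 1], both are min-max scaled to [0, 1] within the cohort before
#' subtraction (`scale = "raw"` preserves the literal difference). A null
#' distribution is built by `n_perm` random re-pairings of the
#' amplification-frequency vector against the mu vector across genes; each
#' gene's percentile within the null determines its class: above the 94th
#' percentile protected, below the 6th unprotected, otherwise neither.
#'
#' @param scores Per-gene scores from [gene_scores()] (needs `gene`,
#'   `amp_freq`, `mu`).
#' @param n_perm Number of permutations (default 10,000; fewer than 100
#'   triggers a warning).
#' @param seed Mandatory RNG seed for reproducibility.
#' @param scale `"minmax"` (default) or `"raw"`.
#' @param null_type `"pooled"` (default) ranks each observed index within
#'   the null values of all genes pooled; `"per_gene"` ranks within that
#'   gene's own null; `"empirical"` ranks within the observed cross-gene
#'   index distribution (no permutations).
#' @param perm `"shuffle"` (default) re-pairs the two vectors across genes;
#'   `"swap"` is the literal two-point null that flips the sign of each
#'   gene's index at random.
#' @param lower,upper Percentile cutoffs for unprotected/protected calls.
#' @return Data.frame: `gene`, `cohort` columns of `scores` carried through,
#'   `amp_scaled`, `mu_scaled`, `p_index`, `percentile`, `klass`.
#' @export
protection_index <- function(scores, n_perm = 10000, seed,
                             scale = c("minmax", "raw"),
                             null_type = c("pooled", "per_gene", "empirical"),
                             perm = c("shuffle", "swap"),
                             lower = 6, upper = 94) {
  scale <- match.arg(scale)
  null_type <- match.arg(null_type)
  perm <- match.arg(perm)
  if (missing(seed)) stop("a seed is mandatory for reproducible permutations")
  if (n_perm < 100 && null_type != "empirical") {
    warning("fewer than 100 permutations gives a coarse percentile granularity")
  }
  n <- nrow(scores)
  if (n < 100) warning("fewer than 100 genes; the permutation null may be unstable")
  amp_s <- if (scale == "minmax") minmax_scale(scores$amp_freq) else scores$amp_freq
  mu_s <- if (scale == "minmax") minmax_scale(scores$mu) else scores$mu
  p_obs <- amp_s - mu_s

  set.seed(seed)
  percentile_of <- function(x, null_sorted) {
    n_lt <- findInterval(x, null_sorted, left.open = TRUE)
    n_le <- findInterval(x, null_sorted)
    100 * (n_lt + (n_le - n_lt) / 2) / length(null_sorted)
  }
  if (null_type == "empirical") {
    percentile <- percentile_of(p_obs, sort(p_obs))
  } else {
    null_mat <- matrix(NA_real_, nrow = n, ncol = n_perm)
    if (perm == "shuffle") {
      # permutations are drawn in (sigma, sigma^-1) pairs so the pooled null
      # is closed under inversion; this makes the percentiles exactly
      # anti-symmetric under a global amp <-> mu swap (for even n_perm)
      k <- 1L
      while (k <= n_perm) {
        s <- sample.int(n)
        null_mat[, k] <- amp_s[s] - mu_s
        if (k + 1L <= n_perm) null_mat[, k + 1L] <- amp_s[order(s)] - mu_s
        k <- k + 2L
      }
    } else {
      for (k in seq_len(n_perm)) {
        null_mat[, k] <- sample(c(-1, 1), n, replace = TRUE) * p_obs
      }
    }
    if (null_type == "pooled") {
      percentile <- percentile_of(p_obs, sort(as.vector(null_mat)))
    } else {
      percentile <- vapply(seq_len(n), function(i) {
        percentile_of(p_obs[i], sort(null_mat[i, ]))
      }, numeric(1))
    }
  }
  out <- data.frame(
    gene = scores$gene,
    amp_scaled = amp_s, mu_scaled = mu_s,
    p_index = p_obs, percentile = percentile,
    klass = ifelse(percentile > upper, "protected",
                   ifelse(percentile < lower, "unprotected", "neither")),
    stringsAsFactors = FALSE
  )
  if ("cohort" %in% names(scores)) out$cohort <- scores$cohort
  out
}

#' Cross-cohort consensus of protection calls
#'
#' A gene is consensus-protected (or unprotected) when it is called so in at
#' least `min_cohorts` cohorts; a gene meeting both thresholds is
#' pathological and reported as `none` with a warning.
#'
#' @param records Row-bound [protection_index()] tables with a `cohort`
#'   column.
#' @param min_cohorts Minimum number of supporting cohorts (default 3).
#' @return Data.frame: `gene`, `n_protected`, `n_unprotected`, `consensus`.
#' @export
consensus_calls <- function(records, min_cohorts = 3) {
  prot <- tapply(records$klass == "protected", records$gene, sum)
  unprot <- tapply(records$klass == "unprotected", records$gene, sum)
  genes <- names(prot)
  n_p <- as.integer(prot)
  n_u <- as.integer(unprot[genes])
  consensus <- ifelse(n_p >= min_cohorts & n_u >= min_cohorts, "none",
                      ifelse(n_p >= min_cohorts, "protected",
                             ifelse(n_u >= min_cohorts, "unprotected", "none")))
  if (any(n_p >= min_cohorts & n_u >= min_cohorts)) {
    warning("gene(s) meeting both consensus thresholds set to 'none'")
  }
  data.frame(
    gene = genes, n_protected = n_p, n_unprotected = n_u,
    consensus = consensus, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Essentiality and expression contrasts of protected vs unprotected genes
#'
#' Three read-outs on the consensus sets: (i) a two-sided Wilcoxon rank-sum
#' test on the CRISPR gene-effect score (more negative = more essential),
#' (ii) a Fisher exact test of the overlap between the protection classes
#' and the common-essential / non-essential flags, and (iii) a two-sided
#' rank-sum test on median expression.
#'
#' @param consensus Output of [consensus_calls()].
#' @param genes Gene annotation table with `crispr_effect` and the
#'   essentiality flags.
#' @return List with `crispr` (one-row data.frame: `p_value`,
#'   `median_protected`, `median_unprotected`, `n_protected`,
#'   `n_unprotected`), `essential_overlap` (one-row: `odds_ratio`,
#'   `p_value`, plus the 2x2 counts) and `expression` (one-row rank-sum
#'   summary); elements are `NULL` with a message when a set is empty.
#' @export
essentiality_comparison <- function(consensus, genes) {
  gp <- consensus$gene[consensus$consensus == "protected"]
  gu <- consensus$gene[consensus$consensus == "unprotected"]
  out <- list(crispr = NULL, essential_overlap = NULL, expression = NULL)
  if (length(gp) == 0 || length(gu) == 0) {
    message("empty protected or unprotected set; comparisons skipped")
    return(out)
  }
  ann <- function(g, col) genes[[col]][match(g, genes$gene)]

  ep <- ann(gp, "crispr_effect"); eu <- ann(gu, "crispr_effect")
  ep <- ep[!is.na(ep)]; eu <- eu[!is.na(eu)]
  if (length(ep) && length(eu)) {
    wt <- stats::wilcox.test(ep, eu)
    out$crispr <- data.frame(
      p_value = wt$p.value, median_protected = stats::median(ep),
      median_unprotected = stats::median(eu),
      n_protected = length(ep), n_unprotected = length(eu)
    )
  }
  if (all(c("is_common_essential", "is_nonessential") %in% names(genes))) {
    ce_p <- sum(ann(gp, "is_common_essential"), na.rm = TRUE)
    ne_p <- sum(ann(gp, "is_nonessential"), na.rm = TRUE)
    ce_u <- sum(ann(gu, "is_common_essential"), na.rm = TRUE)
    ne_u <- sum(ann(gu, "is_nonessential"), na.rm = TRUE)
    tab <- matrix(c(ce_p, ne_p, ce_u, ne_u), nrow = 2, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ft <- stats::fisher.test(tab)
      out$essential_overlap <- data.frame(
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        protected_essential = ce_p, protected_nonessential = ne_p,
        unprotected_essential = ce_u, unprotected_nonessential = ne_u
      )
    }
  }
  if ("median_tpm" %in% names(genes)) {
    tp <- ann(gp, "median_tpm"); tu <- ann(gu, "median_tpm")
    tp <- tp[!is.na(tp)]; tu <- tu[!is.na(tu)]
    if (length(tp) && length(tu)) {
      wt <- stats::wilcox.test(tp, tu)
      out$expression <- data.frame(
        p_value = wt$p.value, median_protected = stats::median(tp),
        median_unprotected = stats::median(tu)
      )
    }
  }
  out
}
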