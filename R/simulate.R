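#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults chosen to mimic a
#' mid-size solid-tumor cohort profiled by SNP arrays and exome sequencing:
#' a block-constant log-normal regional mutation-rate field, a mixture of
#' focal, arm-level and chromosomal CNA events, gene-property covariates and
#' allele-specific copy number with known mutation multiplicities. The
#' `coupling_beta` parameter tilts where amplifications land toward
#' mutation-rich blocks, planting the buffering signal the pipeline is built
#' to detect; `coupling_beta = 0` gives the null.
#'
#' @param seed RNG seed; fully determines the cohort.
#' @param n_patients Number of patients.
#' @param genome A `genome_build` (default [default_genome()], 5 autosomes
#'   of 200 Mbp).
#' @param n_genes Number of genes, spread proportionally to chromosome
#'   length.
#' @param gene_length Gene body length in bp.
#' @param l_block Block length of the regional rate field in bp; the
#'   expected optimum of a segment-length sweep sits near this value.
#' @param rate_sdlog Log-normal sd of the block rates (mean fixed at 1).
#' @param gene_rate_sdlog Log-normal sd of an iid per-gene mutability
#'   multiplier layered on top of the regional field; models gene-to-gene
#'   variation in mutability (replication timing, chromatin, sequence
#'   composition) that is uncoupled from amplification placement.
#' @param coupling_beta Focal amplification placement is proportional to
#'   `rate^coupling_beta`. Arm-level and chromosomal events are placed
#'   uniformly: their breakpoints are fixed by centromeres and telomeres
#'   (missegregation-like), so only focal events can fine-tune their
#'   position to the local mutation load.
#' @param event_mix Named proportions for `focal`, `arm`, `chromosomal`
#'   events.
#' @param mean_events Poisson mean of CNA events per patient.
#' @param amp_prob Probability an event is an amplification (else deletion).
#' @param focal_length_range Uniform range of focal event lengths in bp.
#'   Focal events are contained within a single rate-field block (lengths
#'   truncated to the block), modeling breakpoints that respect the
#'   megabase-scale domain structure shaping the mutation-rate field.
#' @param base_mut_rate Coding mutations per coding Mbp per patient at
#'   relative rate 1.
#' @param noncoding_rate Non-coding mutations per Mbp per patient.
#' @param amp_mut_boost Scale mutation intensity on amplified genes by total
#'   copy number over 2 (the confounder the mu score is designed to dodge).
#' @param depth Sequencing depth for binomial VAF sampling.
#' @param purity_range Uniform range of per-patient tumor purity.
#' @param early_fraction Probability a mutation on an amplified segment
#'   predates the amplification (multiplicity = major allele count).
#' @param stratum_coupling Optional predicate `function(genes)` returning a
#'   logical; when set, only mutations in predicate-true genes follow the
#'   amplification-coupled rate field, the rest follow an independent field.
#' @param synonymous_frac Fraction of coding mutations that are synonymous.
#' @param tpm_zero_frac Fraction of genes simulated as non-expressed.
#' @param truth_bin_j Bin length of the grid on which true per-patient bin
#'   states are recorded.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_patients = 100, genome = default_genome(),
                       n_genes = 500, gene_length = 20e3, l_block = 10e6,
                       rate_sdlog = 1.25, gene_rate_sdlog = 1.25,
                       coupling_beta = 0,
                       event_mix = c(focal = 0.6, arm = 0.3, chromosomal = 0.1),
                       mean_events = 10, amp_prob = 0.5,
                       focal_length_range = c(10e6, 40e6),
                       base_mut_rate = 2, noncoding_rate = 0.02,
                       amp_mut_boost = TRUE, depth = 100,
                       purity_range = c(0.6, 0.95), early_fraction = 0.5,
                       stratum_coupling = NULL, synonymous_frac = 0.25,
                       tpm_zero_frac = 0.15, truth_bin_j = 10e6) {
  stopifnot(
    n_patients > 0, n_genes > 0, l_block > 0, coupling_beta >= 0,
    abs(sum(event_mix) - 1) < 1e-8, base_mut_rate >= 0,
    early_fraction >= 0, early_fraction <= 1
  )
  if (sum(genome$length) < n_genes * gene_length) {
    stop("infeasible config: gene bodies exceed the genome")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Independent recount of per-(patient, bin) states, used only to fill the
# truth record: plain base-R interval arithmetic, no shared code with
# patient_bin_states(). Same semantics: union coverage of same-sign events
# >= 0.5 of the bin, larger coverage wins, ties -> A.
truth_states <- function(cna, grid, patients, amp_cut = 0.2) {
  st <- matrix("N", nrow(grid), length(patients),
               dimnames = list(grid$bin_id, patients))
  # merge sorted intervals, then per-bin coverage via a cumulative-length map
  bin_coverage <- function(s, e, bins) {
    o <- order(s)
    s <- s[o]; e <- cummax(e[o])
    grp <- cumsum(c(TRUE, s[-1] > e[-length(e)] + 1))
    ms <- tapply(s, grp, min)
    me <- tapply(e, grp, max)
    cum <- cumsum(me - ms + 1)
    cov_upto <- function(x) {  # covered length in (-inf, x]
      i <- findInterval(x, ms)
      out <- numeric(length(x))
      pos <- i > 0
      out[pos] <- c(0, cum)[i[pos]] +
        pmax(0, pmin(x[pos], me[i[pos]]) - ms[i[pos]] + 1)
      out
    }
    cov_upto(bins$end) - cov_upto(bins$start - 1)
  }
  for (p in seq_along(patients)) {
    cc <- cna[cna$patient == patients[p], , drop = FALSE]
    if (nrow(cc) == 0) next
    a_cov <- numeric(nrow(grid))
    d_cov <- numeric(nrow(grid))
    for (ch in unique(cc$chrom)) {
      bix <- which(grid$chrom == ch)
      if (!length(bix)) next
      amp <- cc$segment_mean > amp_cut & cc$chrom == ch
      del <- cc$segment_mean < -amp_cut & cc$chrom == ch
      if (any(amp)) a_cov[bix] <- bin_coverage(cc$start[amp], cc$end[amp], grid[bix, ])
      if (any(del)) d_cov[bix] <- bin_coverage(cc$start[del], cc$end[del], grid[bix, ])
    }
    len <- grid$end - grid$start + 1
    a_in <- a_cov >= 0.5 * len
    d_in <- d_cov >= 0.5 * len
    st[a_in & (!d_in | a_cov >= d_cov), p] <- "A"
    st[d_in & !(a_in & a_cov >= d_cov), p] <- "D"
  }
  st
}

#' Simulate a tumor cohort with known ground truth
#'
#' Generates per-patient CNA calls, somatic mutations, gene annotations and
#' allele-specific copy-number segments under the model described in
#' [sim_config()], together with a truth record holding the regional rate
#' field, the true per-(patient, bin) copy-number states, and each
#' mutation's true multiplicity and timing. The same seed always yields a
#' byte-identical cohort.
#'
#' @param cfg A `sim_config`.
#' @return List with elements `cna`, `muts`, `genes`, `ascn`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- cfg$genome
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))

  # regional rate field: block-constant log-normal, mean 1
  blocks <- build_grid(genome, "fixed", j = cfg$l_block)
  meanlog <- -cfg$rate_sdlog^2 / 2
  lambda <- stats::rlnorm(nrow(blocks), meanlog, cfg$rate_sdlog)
  lambda_alt <- stats::rlnorm(nrow(blocks), meanlog, cfg$rate_sdlog)

  # genes spread proportionally to chromosome length
  n_per <- round(cfg$n_genes * genome$length / sum(genome$length))
  n_per[length(n_per)] <- cfg$n_genes - sum(n_per[-length(n_per)])
  glist <- lapply(seq_len(nrow(genome)), function(k) {
    spacing <- genome$length[k] / n_per[k]
    start <- pmax(1, round((seq_len(n_per[k]) - 0.5) * spacing - cfg$gene_length / 2))
    data.frame(
      chrom = genome$chrom[k], start = start,
      end = pmin(start + cfg$gene_length - 1, genome$length[k]),
      stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, glist)
  genes <- data.frame(gene = sprintf("G%04d", seq_len(nrow(genes))), genes,
                      stringsAsFactors = FALSE)
  genes$coding_bp <- sample(5e3:15e3, nrow(genes), replace = TRUE)
  genes$pli <- stats::runif(nrow(genes))
  genes$ghis <- stats::runif(nrow(genes))
  genes$median_tpm <- ifelse(stats::runif(nrow(genes)) < cfg$tpm_zero_frac, 0,
                             stats::rlnorm(nrow(genes), 2, 1))
  genes$is_og <- stats::runif(nrow(genes)) < 0.05
  genes$is_tsg <- stats::runif(nrow(genes)) < 0.05
  genes$is_go <- stats::runif(nrow(genes)) < 0.10
  genes$crispr_effect <- stats::rnorm(nrow(genes), -0.3, 0.5)
  genes$is_common_essential <- genes$crispr_effect < -1
  genes$is_nonessential <- genes$crispr_effect > -0.1

  gene_block <- gene_bin_map(genes, blocks)
  coupled <- if (is.null(cfg$stratum_coupling)) rep(TRUE, nrow(genes)) else
    cfg$stratum_coupling(genes)
  gene_mult <- stats::rlnorm(nrow(genes), -cfg$gene_rate_sdlog^2 / 2,
                             cfg$gene_rate_sdlog)
  gene_rate <- ifelse(coupled, lambda[gene_block], lambda_alt[gene_block]) * gene_mult

  # CNA events -------------------------------------------------------------
  n_ev <- stats::rpois(cfg$n_patients, cfg$mean_events)
  ev_patient <- rep(patients, n_ev)
  E <- length(ev_patient)
  ev_class <- sample(names(cfg$event_mix), E, replace = TRUE, prob = cfg$event_mix)
  ev_amp <- stats::runif(E) < cfg$amp_prob

  block_w <- lambda^cfg$coupling_beta
  arms <- build_grid(genome, "arm")

  ev_chrom <- character(E)
  ev_start <- numeric(E)
  ev_end <- numeric(E)
  for (i in seq_len(E)) {
    if (ev_class[i] == "chromosomal") {
      k <- sample.int(nrow(genome), 1, prob = genome$length)
      ev_chrom[i] <- genome$chrom[k]; ev_start[i] <- 1; ev_end[i] <- genome$length[k]
    } else if (ev_class[i] == "arm") {
      k <- sample.int(nrow(arms), 1, prob = arms$end - arms$start + 1)
      ev_chrom[i] <- arms$chrom[k]; ev_start[i] <- arms$start[k]; ev_end[i] <- arms$end[k]
    } else {
      # focal events are contained in a single rate-field block: the same
      # megabase-scale domains (replication timing, TAD-like units) that
      # shape regional mutation rate also constrain rearrangement
      # breakpoints, so a focal event does not straddle domain boundaries
      blen <- blocks$end - blocks$start + 1
      b <- if (ev_amp[i]) sample.int(nrow(blocks), 1, prob = block_w * blen)
           else sample.int(nrow(blocks), 1, prob = blen)
      len <- min(stats::runif(1, cfg$focal_length_range[1],
                              cfg$focal_length_range[2]), blen[b])
      ev_chrom[i] <- blocks$chrom[b]
      ev_start[i] <- round(stats::runif(1, blocks$start[b], blocks$end[b] - len + 1))
      ev_end[i] <- min(blocks$end[b], ev_start[i] + round(len) - 1)
    }
  }
  cna <- data.frame(
    patient = ev_patient, chrom = ev_chrom, start = ev_start, end = ev_end,
    segment_mean = ifelse(ev_amp, stats::runif(E, 0.3, 1),
                          -stats::runif(E, 0.3, 1)),
    stringsAsFactors = FALSE
  )

  # allele-specific CN for the amplified events
  purity <- stats::runif(cfg$n_patients, cfg$purity_range[1], cfg$purity_range[2])
  names(purity) <- patients
  amp_idx <- which(ev_amp)
  ascn <- data.frame(
    patient = ev_patient[amp_idx], chrom = ev_chrom[amp_idx],
    start = ev_start[amp_idx], end = ev_end[amp_idx],
    major = sample(2:4, length(amp_idx), replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    minor = sample(0:1, length(amp_idx), replace = TRUE),
    stringsAsFactors = FALSE
  )
  ascn$purity <- purity[ascn$patient]

  # per-(patient, gene) amplification boost from covering amp events
  boost <- matrix(1, cfg$n_patients, nrow(genes),
                  dimnames = list(patients, genes$gene))
  if (nrow(ascn) > 0 && cfg$amp_mut_boost) {
    mid <- floor((genes$start + genes$end) / 2)
    ggr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(mid, mid))
    agr <- GenomicRanges::GRanges(ascn$chrom, IRanges::IRanges(ascn$start, ascn$end))
    hits <- GenomicRanges::findOverlaps(agr, ggr)
    if (length(hits)) {
      ai <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
      cn_half <- (ascn$major[ai] + ascn$minor[ai]) / 2
      pi <- match(ascn$patient[ai], patients)
      # max boost when several amp events cover the same gene
      o <- order(cn_half)
      boost[cbind(pi[o], gi[o])] <- cn_half[o]
    }
  }

  # coding mutations --------------------------------------------------------
  lam_mat <- boost * rep(gene_rate * cfg$base_mut_rate * genes$coding_bp / 1e6,
                         each = cfg$n_patients)
  counts <- stats::rpois(length(lam_mat), lam_mat)
  nz <- which(counts > 0)
  gi <- ((nz - 1) %/% cfg$n_patients) + 1
  pi <- ((nz - 1) %% cfg$n_patients) + 1
  gi <- rep(gi, counts[nz])
  pi <- rep(pi, counts[nz])
  n_cod <- length(gi)
  muts <- data.frame(
    patient = patients[pi], chrom = genes$chrom[gi],
    pos = round(stats::runif(n_cod, genes$start[gi], genes$end[gi])),
    gene = genes$gene[gi], is_coding = TRUE,
    is_synonymous = stats::runif(n_cod) < cfg$synonymous_frac,
    stringsAsFactors = FALSE
  )

  # non-coding mutations (intergenic, used by the timing analysis)
  if (cfg$noncoding_rate > 0) {
    blen <- blocks$end - blocks$start + 1
    lam_nc <- outer(rep(1, cfg$n_patients), lambda * cfg$noncoding_rate * blen / 1e6)
    nc_counts <- stats::rpois(length(lam_nc), lam_nc)
    nz <- which(nc_counts > 0)
    bi <- ((nz - 1) %/% cfg$n_patients) + 1
    pj <- ((nz - 1) %% cfg$n_patients) + 1
    bi <- rep(bi, nc_counts[nz])
    pj <- rep(pj, nc_counts[nz])
    if (length(bi)) {
      nc <- data.frame(
        patient = patients[pj], chrom = blocks$chrom[bi],
        pos = round(stats::runif(length(bi), blocks$start[bi], blocks$end[bi])),
        gene = NA_character_, is_coding = FALSE, is_synonymous = FALSE,
        stringsAsFactors = FALSE
      )
      muts <- rbind(muts, nc)
    }
  }

  # mutation-level annotations
  n_mut <- nrow(muts)
  muts$cadd <- round(stats::rexp(n_mut, 1 / 4), 3)
  muts$polyphen <- round(stats::runif(n_mut), 3)
  muts$aggregation_score <- round(stats::runif(n_mut, 0, 10000), 1)
  muts$aggregation_fold_change <- round(stats::rlnorm(n_mut, 0, 0.3), 3)

  # true multiplicity, timing and VAF ---------------------------------------
  muts$major <- 1L; muts$minor <- 1L
  if (nrow(ascn) > 0 && n_mut > 0) {
    mgr <- GenomicRanges::GRanges(
      paste(muts$patient, muts$chrom, sep = "|"),
      IRanges::IRanges(muts$pos, muts$pos)
    )
    agr <- GenomicRanges::GRanges(
      paste(ascn$patient, ascn$chrom, sep = "|"),
      IRanges::IRanges(ascn$start, ascn$end)
    )
    suppressWarnings(hit <- GenomicRanges::findOverlaps(mgr, agr, select = "first"))
    cov <- !is.na(hit)
    muts$major[cov] <- ascn$major[hit[cov]]
    muts$minor[cov] <- ascn$minor[hit[cov]]
  }
  early <- stats::runif(n_mut) < cfg$early_fraction
  muts$true_m <- ifelse(muts$major >= 2 & early, muts$major, 1L)
  muts$true_timing <- ifelse(muts$true_m == muts$major, "early", "late")
  pur <- purity[muts$patient]
  evaf <- muts$true_m * pur / (pur * (muts$major + muts$minor) + 2 * (1 - pur))
  muts$depth <- cfg$depth
  muts$vaf <- stats::rbinom(n_mut, cfg$depth, evaf) / cfg$depth

  truth_grid <- build_grid(genome, "fixed", j = cfg$truth_bin_j)
  truth <- list(
    lambda = data.frame(blocks, lambda = lambda, lambda_alt = lambda_alt),
    coupled_genes = genes$gene[coupled],
    states = truth_states(cna, truth_grid, patients),
    mutations = muts[, c("patient", "chrom", "pos", "major", "minor",
                         "true_m", "true_timing")],
    purity = purity
  )
  mut_cols <- c("patient", "chrom", "pos", "gene", "is_coding", "is_synonymous",
                "cadd", "polyphen", "aggregation_score",
                "aggregation_fold_change", "vaf", "depth")
  list(
    cna = cna, muts = muts[, mut_cols], genes = genes, ascn = ascn,
    truth = truth, config = cfg, patients = patients
  )
}

#' Simulate per-gene scores with a planted protected set
#'
#' Generates a per-gene (amplification frequency, mu) table where a
#' designated fraction of genes receives both a top-decile amplification
#' frequency and a bottom-decile mu score -- the signature the protection
#' index should flag. Used to measure the sensitivity of the
#' permutation-percentile rule.
#'
#' @param n_genes Number of genes.
#' @param planted_frac Fraction of genes planted as protected.
#' @param seed RNG seed.
#' @return Data.frame: `gene`, `amp_freq`, `mu` (raw log10 scale),
#'   `planted`.
#' @export
simulate_gene_scores <- function(n_genes = 600, planted_frac = 0.05, seed = 1) {
  set.seed(seed)
  amp <- stats::rbeta(n_genes, 1.5, 6)
  mu <- stats::runif(n_genes, -7, -4)
  planted <- seq_len(n_genes) <= round(planted_frac * n_genes)
  q_amp <- stats::quantile(amp, 0.9)
  q_mu <- stats::quantile(mu, 0.1)
  amp[planted] <- stats::runif(sum(planted), q_amp, max(amp))
  mu[planted] <- stats::runif(sum(planted), min(mu), q_mu)
  o <- sample.int(n_genes)  # shuffle so planted genes are not a prefix
  data.frame(
    gene = sprintf("G%04d", seq_len(n_genes)),
    amp_freq = amp[o], mu = mu[o], planted = planted[o],
    stringsAsFactors = FALSE
  )
}

#' Simulate per-bin tables with additive OG + GO + mu structure
#'
#' Generates one cohort's per-bin driver densities and scores where the
#' amplification frequency is, by construction, a noisy monotone function of
#' `og_score + go_score + minmax(mu)` -- the generating model that
#' [combined_model()] assumes. Different seeds give independent cohorts, so a
#' pair of them exercises [swap_control()].
#'
#' @param seed RNG seed.
#' @param n_bins Number of bins.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   additive predictor before ranking.
#' @return List with `density` (as [density_scores()]) and `scores` (the
#'   columns [combined_model()] needs).
#' @export
simulate_oggo_bins <- function(seed = 1, n_bins = 80, noise_sd = 0.15) {
  set.seed(seed)
  og <- stats::rbeta(n_bins, 1, 8)
  go <- stats::rbeta(n_bins, 1, 8)
  mu <- stats::runif(n_bins, -7, -4)
  mu_s <- minmax_scale(mu)
  amp <- minmax_scale(og + go + mu_s + stats::rnorm(n_bins, 0, noise_sd))
  bin_id <- sprintf("bin%03d", seq_len(n_bins))
  list(
    density = data.frame(bin_id = bin_id, og_score = og, go_score = go,
                         n_genes = 10L, stringsAsFactors = FALSE),
    scores = data.frame(bin_id = bin_id, amp_freq = amp, mu = mu,
                        stringsAsFactors = FALSE)
  )
}

#' Tiny hand-checkable cohorts
#'
#' A registry of minimal worked examples whose every score is computed by
#' hand in the documentation and asserted in the test suite.
#'
#' * `mini-eq3`: one 1 Mbp chromosome, 5 patients (2 amplified over the
#'   whole bin, 3 copy-neutral), 6 coding mutations all in copy-neutral
#'   patients, coding length 2e5 bp; so amplification frequency = 2/5 and
#'   mu = log10(6 / (2e5 * 3)) = -5.
#' * `mini-timing`: one amplified 3:0 segment at purity 1 carrying one
#'   mutation at VAF 1 (multiplicity 3: early, zero wild-type copies left,
#'   non-buffered) and one at VAF 1/3 (multiplicity 1: late, two wild-type
#'   copies left, buffered).
#' * `mini-null`: the mini-eq3 layout with no mutations at all; every mu is
#'   undefined while the frequencies stay defined.
#'
#' @param name One of `"mini-eq3"`, `"mini-timing"`, `"mini-null"`.
#' @return A list with the tables the fixture needs plus an `expected` list
#'   of hand-computed values.
#' @export
make_fixture <- function(name = c("mini-eq3", "mini-timing", "mini-null")) {
  name <- match.arg(name)
  genome <- genome_build("chr1", 1e6, 5e5)
  patients <- paste0("P", 1:5)
  genes <- data.frame(
    gene = "G1", chrom = "chr1", start = 1e5, end = 4e5, coding_bp = 2e5,
    median_tpm = 10, stringsAsFactors = FALSE
  )
  cna <- data.frame(
    patient = c("P1", "P2"), chrom = "chr1", start = 1, end = 1e6,
    segment_mean = c(0.5, 0.8), stringsAsFactors = FALSE
  )
  if (name == "mini-eq3") {
    muts <- data.frame(
      patient = c("P3", "P3", "P4", "P4", "P5", "P5"), chrom = "chr1",
      pos = c(11e4, 12e4, 13e4, 14e4, 15e4, 16e4), gene = "G1",
      is_coding = TRUE, is_synonymous = FALSE, stringsAsFactors = FALSE
    )
    expected <- list(amp_freq = 2 / 5, del_freq = 0, mu = -5, n_N = 3,
                     n_mut_neutral = 6)
  } else if (name == "mini-null") {
    muts <- data.frame(
      patient = character(0), chrom = character(0), pos = numeric(0),
      gene = character(0), is_coding = logical(0), is_synonymous = logical(0),
      stringsAsFactors = FALSE
    )
    expected <- list(amp_freq = 2 / 5, del_freq = 0, mu = NA_real_)
  } else {
    ascn <- data.frame(
      patient = "P1", chrom = "chr1", start = 1, end = 1e6,
      major = 3, minor = 0, purity = 1, stringsAsFactors = FALSE
    )
    muts <- data.frame(
      patient = "P1", chrom = "chr1", pos = c(2e5, 3e5), gene = "G1",
      is_coding = TRUE, is_synonymous = FALSE,
      vaf = c(1, 1 / 3), depth = 100, stringsAsFactors = FALSE
    )
    return(list(
      genome = genome, patients = patients, ascn = ascn, muts = muts,
      expected = list(m = c(3L, 1L), timing = c("early", "late"),
                      buffered = c(FALSE, TRUE))
    ))
  }
  list(genome = genome, patients = patients, cna = cna, muts = muts,
       genes = genes, expected = expected)
}

#' Write a simulated cohort to disk in the external file dialects
#'
#' Emits the SEG, mutation TSV, gene table, allele-specific CN table and a
#' truth JSON into a directory, exactly the formats the readers in this
#' package consume.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_seg(cohort$cna, file.path(dir, "cohort.seg"))
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  m <- cohort$muts
  m$consequence <- ifelse(!m$is_coding, "Intron",
                          ifelse(m$is_synonymous, "Silent", "Missense_Mutation"))
  tsv(m[, setdiff(names(m), c("is_coding", "is_synonymous"))], "mutations.tsv")
  tsv(cohort$genes, "genes.tsv")
  tsv(cohort$ascn, "ascn.tsv")
  truth <- cohort$truth
  truth$states <- list(
    bin_id = rownames(truth$states), patient = colnames(truth$states),
    state = unname(apply(truth$states, 2, paste0, collapse = ""))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
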