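# Brute-force, loop-based recount of per-bin scores, kept deliberately
# independent of the vectorized implementation: per patient and bin, the
# copy-number state is derived by direct interval clipping; the mu numerator
# is recounted mutation by mutation.
brute_force_scores <- function(cna, muts, grid, coding_bp, patients,
                               amp_cut = 0.2, overlap_frac = 0.5) {
  n_bin <- nrow(grid)
  state <- matrix("N", n_bin, length(patients))
  union_len <- function(s, e) {
    if (length(s) == 0) return(0)
    o <- order(s)
    s <- s[o]; e <- e[o]
    tot <- 0; cs <- s[1]; ce <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] > ce + 1) {
        tot <- tot + ce - cs + 1; cs <- s[k]; ce <- e[k]
      } else ce <- max(ce, e[k])
    }
    tot + ce - cs + 1
  }
  for (p in seq_along(patients)) {
    cc <- cna[cna$patient == patients[p], , drop = FALSE]
    for (b in seq_len(n_bin)) {
      len <- grid$end[b] - grid$start[b] + 1
      cov_of <- function(rows) {
        s <- pmax(cc$start[rows], grid$start[b])
        e <- pmin(cc$end[rows], grid$end[b])
        keep <- s <= e
        union_len(s[keep], e[keep])
      }
      a <- cov_of(cc$chrom == grid$chrom[b] & cc$segment_mean > amp_cut)
      d <- cov_of(cc$chrom == grid$chrom[b] & cc$segment_mean < -amp_cut)
      a_in <- a >= overlap_frac * len
      d_in <- d >= overlap_frac * len
      if (a_in && d_in) {
        state[b, p] <- if (a >= d) "A" else "D"
      } else if (a_in) state[b, p] <- "A" else if (d_in) state[b, p] <- "D"
    }
  }
  n_A <- rowSums(state == "A")
  n_D <- rowSums(state == "D")
  n_N <- length(patients) - n_A - n_D
  n_mut <- numeric(n_bin)
  sex <- c("X", "Y", "chrX", "chrY", "23", "24")
  for (i in seq_len(nrow(muts))) {
    if (!muts$is_coding[i] || muts$chrom[i] %in% sex) next
    p <- match(muts$patient[i], patients)
    if (is.na(p)) next
    for (b in seq_len(n_bin)) {
      if (muts$chrom[i] == grid$chrom[b] &&
          muts$pos[i] >= grid$start[b] && muts$pos[i] <= grid$end[b]) {
        if (state[b, p] == "N") n_mut[b] <- n_mut[b] + 1
        break
      }
    }
  }
  data.frame(
    amp_freq = n_A / length(patients), del_freq = n_D / length(patients),
    mu = ifelse(n_mut > 0 & n_N > 0 & coding_bp > 0,
                log10(n_mut / (coding_bp * n_N)), NA_real_),
    n_A = n_A, n_D = n_D, n_N = n_N, n_mut_neutral = n_mut
  )
}

# Small randomized cohort on a 2-chromosome genome for oracle equivalence.
random_toy_cohort <- function(seed, n_patients = NULL, n_mut = NULL) {
  set.seed(seed)
  genome <- genome_build(c("c1", "c2"), c(50e6, 30e6), c(20e6, 12e6))
  if (is.null(n_patients)) n_patients <- sample(3:20, 1)
  patients <- paste0("T", seq_len(n_patients))
  n_calls <- sample(5:40, 1)
  ci <- sample(1:2, n_calls, replace = TRUE)
  s <- round(runif(n_calls, 1, genome$length[ci] * 0.9))
  e <- pmin(round(s + runif(n_calls, 1e5, 30e6)), genome$length[ci])
  cna <- data.frame(
    patient = sample(patients, n_calls, replace = TRUE),
    chrom = genome$chrom[ci], start = s, end = e,
    segment_mean = round(runif(n_calls, -1, 1), 3),
    stringsAsFactors = FALSE
  )
  if (is.null(n_mut)) n_mut <- sample(50:500, 1)
  mi <- sample(1:2, n_mut, replace = TRUE)
  muts <- data.frame(
    patient = sample(patients, n_mut, replace = TRUE),
    chrom = genome$chrom[mi],
    pos = round(runif(n_mut, 1, genome$length[mi])),
    gene = NA_character_,
    is_coding = runif(n_mut) < 0.8,
    is_synonymous = runif(n_mut) < 0.25,
    stringsAsFactors = FALSE
  )
  grid <- build_grid(genome, "fixed", j = 10e6)
  coding_bp <- round(runif(nrow(grid), 1e4, 1e6))
  list(genome = genome, patients = patients, cna = cna, muts = muts,
       grid = grid, coding_bp = coding_bp)
}
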