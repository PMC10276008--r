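test_that("mu_score computes the documented quantity and NA cases", {
  expect_equal(mu_score(10, 5, 1e6), log10(10 / 5e6))
  expect_equal(mu_score(c(0, 3), c(5, 0), c(1e6, 1e6)), c(NA_real_, NA_real_))
  expect_equal(mu_score(3, 5, 0), NA_real_)
})

test_that("the mini-eq3 fixture reproduces its hand-computed scores", {
  fx <- make_fixture("mini-eq3")
  grid <- build_grid(fx$genome, "fixed", j = 1e6)
  st <- score_table(fx$cna, fx$muts, grid, genes = fx$genes,
                    genome = fx$genome, patients = fx$patients)
  expect_equal(st$amp_freq, fx$expected$amp_freq)
  expect_equal(st$del_freq, fx$expected$del_freq)
  expect_equal(st$mu, fx$expected$mu)  # exactly -5
  expect_identical(st$mu, -5)
  expect_equal(st$n_N, fx$expected$n_N)
  expect_equal(st$n_mut_neutral, fx$expected$n_mut_neutral)
})

test_that("mini-null keeps frequencies defined while mu is NA", {
  fx <- make_fixture("mini-null")
  grid <- build_grid(fx$genome, "fixed", j = 1e6)
  st <- score_table(fx$cna, fx$muts, grid, genes = fx$genes,
                    genome = fx$genome, patients = fx$patients)
  expect_equal(st$amp_freq, 2 / 5)
  expect_true(is.na(st$mu))
  ps <- score_table(fx$cna, fx$muts, grid, genes = fx$genes,
                    genome = fx$genome, patients = fx$patients,
                    mu_zero_policy = "pseudocount")
  expect_equal(ps$mu, log10(0.5 / (2e5 * 3)))
})

test_that("score_table matches the brute-force oracle on random toys", {
  for (sd in c(11, 29, 57)) {
    toy <- random_toy_cohort(sd)
    bf <- brute_force_scores(toy$cna, toy$muts, toy$grid, toy$coding_bp,
                             toy$patients)
    st <- suppressWarnings(
      score_table(toy$cna, toy$muts, toy$grid, genome = toy$genome,
                  patients = toy$patients, coding_bp = toy$coding_bp)
    )
    expect_identical(st$n_A, bf$n_A)
    expect_identical(st$n_D, bf$n_D)
    expect_identical(st$n_N, bf$n_N)
    expect_identical(st$n_mut_neutral, bf$n_mut_neutral)
    expect_equal(st$mu, bf$mu, tolerance = 1e-12)
  }
})

test_that("mutations in amplified patients never move mu", {
  toy <- random_toy_cohort(83)
  st0 <- suppressWarnings(
    score_table(toy$cna, toy$muts, toy$grid, genome = toy$genome,
                patients = toy$patients, coding_bp = toy$coding_bp)
  )
  states <- suppressWarnings(
    patient_bin_states(toy$cna, toy$grid, toy$patients, toy$genome)
  )
  amp_cells <- which(states == "A", arr.ind = TRUE)
  expect_gt(nrow(amp_cells), 0)
  extra <- data.frame(
    patient = toy$patients[amp_cells[, 2]],
    chrom = toy$grid$chrom[amp_cells[, 1]],
    pos = toy$grid$start[amp_cells[, 1]],
    gene = NA_character_, is_coding = TRUE, is_synonymous = FALSE,
    stringsAsFactors = FALSE
  )
  extra <- extra[rep(seq_len(nrow(extra)), 25), ]  # arbitrary injection count
  st1 <- suppressWarnings(
    score_table(toy$cna, rbind(toy$muts, extra), toy$grid, genome = toy$genome,
                patients = toy$patients, coding_bp = toy$coding_bp)
  )
  expect_identical(st1$mu, st0$mu)
  expect_identical(st1$n_mut_neutral, st0$n_mut_neutral)
})

test_that("bin_coding_bp apportions genes by midpoint", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 5e6)
  genes <- data.frame(
    gene = c("A", "B", "C"), chrom = "chr1",
    start = c(1e6, 2e6, 8e6), end = c(1.5e6, 2.5e6, 9e6),
    coding_bp = c(1000, 2000, 4000), stringsAsFactors = FALSE
  )
  expect_equal(bin_coding_bp(genes, grid), c(3000, 4000))
  gg <- build_grid(g, "gene", genes = genes)
  expect_equal(bin_coding_bp(genes, gg), c(1000, 2000, 4000))
})

test_that("cohort_summary pools mu in rate space", {
  scores <- data.frame(
    amp_freq = c(0.1, 0.3), del_freq = c(0, 0.1), mu = c(-5, -6)
  )
  muts <- data.frame(patient = c("T1", "T1", "T2"), chrom = "chr1",
                     pos = 1:3, gene = "G", is_coding = c(TRUE, TRUE, FALSE),
                     is_synonymous = FALSE, stringsAsFactors = FALSE)
  cs <- cohort_summary(scores, muts, patients = c("T1", "T2"), cohort = "X")
  expect_equal(cs$pooled_mu, log10(mean(c(1e-5, 1e-6))))
  expect_equal(cs$mutation_burden, 1)  # 2 coding over 2 patients
  expect_equal(cs$n_bins_defined, 2)
  expect_error(cohort_summary(data.frame(amp_freq = 1, del_freq = 0, mu = NA),
                              muts, "T1"), "no bin")
})

test_that("score_table intersects the patient universes with a message", {
  fx <- make_fixture("mini-eq3")
  grid <- build_grid(fx$genome, "fixed", j = 1e6)
  cna <- rbind(fx$cna, data.frame(patient = "ONLY_CNA", chrom = "chr1",
                                  start = 1, end = 1e6, segment_mean = 0.5))
  muts <- rbind(fx$muts, data.frame(patient = "P1", chrom = "chr1", pos = 17e4,
                                    gene = "G1", is_coding = TRUE,
                                    is_synonymous = FALSE))
  # shared universe is {P1}: ONLY_CNA, P2 and the mutation-only P3..P5 drop
  expect_message(
    st <- score_table(cna, muts, grid, genes = fx$genes, genome = fx$genome),
    "5 patient\\(s\\).*dropped"
  )
  expect_equal(st$n_A + st$n_D + st$n_N, 1)
  expect_equal(st$amp_freq, 1)
  # P1 is amplified, so its mutation must not enter the mu numerator
  expect_equal(st$n_mut_neutral, 0)
  expect_error(
    score_table(fx$cna, fx$muts, grid, genes = fx$genes, genome = fx$genome),
    "no patients shared"
  )
})
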