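test_that("correlate reports rho, exact small-sample p and edge notes", {
  sc <- data.frame(amp_freq = 1:6 / 10, mu = -6 + 1:6 / 10)
  r <- correlate(sc)
  expect_equal(r$rho, 1)
  # exact permutation p for perfect rank agreement at n = 6: only the two
  # extreme orderings reach |rho| = 1, so two-sided p = 2/6!
  expect_equal(r$p_value, 2 / factorial(6))
  expect_equal(r$n_bins, 6)

  r_na <- correlate(data.frame(amp_freq = c(0.1, 0.2), mu = c(-5, -6)))
  expect_true(is.na(r_na$rho))
  expect_match(r_na$note, "fewer than 3")

  r_const <- correlate(data.frame(amp_freq = c(1, 1, 1), mu = c(-5, -6, -7)))
  expect_true(is.na(r_const$rho))
  expect_match(r_const$note, "degenerate")

  sc$mu[2] <- NA
  expect_equal(correlate(sc)$n_bins, 5)
  expect_error(correlate(sc, pair = "amp_freq~nope"), "two columns")
})

test_that("sweep_scales covers named and fixed scales and flags the argmax", {
  fx <- make_fixture("mini-eq3")
  sw <- sweep_scales(fx$cna, fx$muts, fx$genes, fx$genome,
                     js = c(5e5, 1e6), named_scales = c("gene", "chromosome"),
                     patients = fx$patients)
  expect_equal(sw$scale, c("gene", "chromosome", "fixed", "fixed"))
  expect_equal(sw$j, c(NA, NA, 5e5, 1e6))
  expect_true(is.na(attr(sw, "argmax")) || attr(sw, "argmax") <= nrow(sw))
})

test_that("the built-in strata apply their documented cutoffs", {
  reg <- strata_registry()
  genes <- data.frame(
    gene = c("G1", "G2", "G3"),
    pli = c(0.2, 0.21, NA), ghis = c(0.5, 0.51, 0.4),
    median_tpm = c(0, 5, NA),
    is_og = c(TRUE, FALSE, NA), is_tsg = c(FALSE, TRUE, NA),
    stringsAsFactors = FALSE
  )
  muts <- data.frame(
    gene = c("G1", "G2", "G3"),
    cadd = c(3.5, 3.6, 3.4), polyphen = c(0.45, 0.7, 0.2),
    is_synonymous = c(TRUE, FALSE, FALSE),
    aggregation_score = c(5001, 5001, 4000),
    aggregation_fold_change = c(1.2, 0.9, 2),
    stringsAsFactors = FALSE
  )
  expect_equal(reg$pli$assign(muts, genes), c("out", "in", "drop"))  # strict >
  expect_equal(reg$ghis$assign(muts, genes), c("out", "in", "out"))
  expect_equal(reg$expressed$assign(muts, genes), c("out", "in", "drop"))
  expect_equal(reg$cadd$assign(muts, genes), c("out", "in", "out"))
  # polyphen middle band [0.3, 0.6] is dropped
  expect_equal(reg$polyphen$assign(muts, genes), c("drop", "in", "out"))
  expect_equal(reg$synonymy$assign(muts, genes), c("out", "in", "in"))
  expect_equal(reg$aggregation$assign(muts, genes), c("in", "out", "out"))
  expect_equal(reg$no_og$assign(muts, genes), c("out", "in", "in"))
  expect_equal(reg$no_tsg$assign(muts, genes), c("in", "out", "in"))
  expect_equal(reg$no_og_tsg$assign(muts, genes), c("out", "out", "in"))
})

test_that("stratified_correlations recompute mu per stratum only", {
  toy <- random_toy_cohort(5, n_patients = 12, n_mut = 400)
  toy$muts$cadd <- round(runif(nrow(toy$muts), 0, 10), 2)
  genes <- data.frame(gene = character(0), pli = numeric(0))
  states <- suppressWarnings(
    patient_bin_states(toy$cna, toy$grid, toy$patients, toy$genome)
  )
  out <- stratified_correlations(
    states, toy$muts, genes, toy$grid, toy$coding_bp,
    strata = strata_registry()["cadd"]
  )
  expect_equal(out$stratum_label, c("control", "cadd_damaging", "cadd_benign"))
  # the stratum splits the control's mutations (none dropped at cadd != 3.5)
  expect_equal(sum(out$n_mut[-1]), out$n_mut[1])
  ctrl <- correlate(
    score_from_states(states, toy$muts, toy$grid, toy$coding_bp)
  )
  expect_equal(out$rho[1], ctrl$rho)
})

test_that("compare_strata pairs by cohort name and rejects mismatches", {
  rho1 <- c(a = 0.5, b = 0.6, c = 0.7)
  rho2 <- c(b = 0.45, c = 0.65, a = 0.38)
  cs <- compare_strata(rho1, rho2)
  expect_equal(cs$n_pairs, 3)
  expect_equal(cs$median_diff, median(c(0.5 - 0.38, 0.6 - 0.45, 0.7 - 0.65)))
  expect_error(compare_strata(rho1, c(a = 1, b = 2, z = 3)), "unpaired")
  expect_error(compare_strata(unname(rho1), c(0.1, 0.2)), "differ in length")
  expect_error(compare_strata(c(a = 1), c(a = 2)), "fewer than 2")
})

test_that("meta_correlation and significant_cohorts behave as documented", {
  burden <- c(a = 1, b = 2, c = 3, d = 4)
  rho <- c(d = 0.8, c = 0.6, b = 0.4, a = 0.2)
  mc <- meta_correlation(burden, rho)
  expect_equal(mc$rho, 1)
  expect_equal(meta_correlation(c(a = 1, b = 2), c(a = 1, b = 2))$n_cohorts, 2)
  res <- data.frame(cohort = c("a", "b", "c"), p_value = c(0.01, 0.5, NA))
  expect_equal(significant_cohorts(res)$cohort, "a")
})

test_that("read_strata_yaml builds working strata from a YAML spec", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- name: highly_expressed",
    "  column: median_tpm",
    "  operator: '>'",
    "  threshold: 10",
    "  source: gene",
    "- name: high_vaf",
    "  column: vaf",
    "  operator: '>='",
    "  threshold: 0.25",
    "  source: mutation"
  ), path)
  reg <- read_strata_yaml(path)
  expect_equal(names(reg), c("highly_expressed", "high_vaf"))
  genes <- data.frame(gene = c("G1", "G2"), median_tpm = c(50, 1))
  muts <- data.frame(gene = c("G1", "G2", "G1"), vaf = c(0.5, 0.25, NA))
  expect_equal(reg$highly_expressed$assign(muts, genes), c("in", "out", "in"))
  expect_equal(reg$high_vaf$assign(muts, genes), c("in", "in", "drop"))
  expect_equal(reg$highly_expressed$complement_name, "not_highly_expressed")
})
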