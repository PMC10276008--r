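test_that("gene_scores removes non-expressed genes and undefined mu", {
  fx <- make_fixture("mini-eq3")
  genes <- rbind(
    fx$genes,
    data.frame(gene = c("G2", "G3"), chrom = "chr1",
               start = c(5e5, 6e5), end = c(5.5e5, 6.5e5),
               coding_bp = 1e4, median_tpm = c(0, 10))
  )
  # G2 is non-expressed, G3 is expressed but mutation-free (mu undefined)
  expect_message(
    gs <- gene_scores(fx$cna, fx$muts, genes, fx$genome,
                      patients = fx$patients),
    "undefined mu"
  )
  expect_equal(gs$gene, "G1")
  expect_equal(gs$mu, log10(6 / (2e5 * 3)))
  expect_equal(gs$amp_freq, 2 / 5)
})

test_that("protection_index is deterministic and classifies extremes", {
  scores <- simulate_gene_scores(n_genes = 200, planted_frac = 0.1, seed = 4)
  p1 <- protection_index(scores, n_perm = 500, seed = 11)
  p2 <- protection_index(scores, n_perm = 500, seed = 11)
  expect_identical(p1, p2)
  p3 <- protection_index(scores, n_perm = 500, seed = 12)
  expect_false(identical(p1$percentile, p3$percentile))
  expect_true(all(p1$klass %in% c("protected", "unprotected", "neither")))
  expect_true(all(p1$percentile[p1$klass == "protected"] > 94))
  expect_true(all(p1$percentile[p1$klass == "unprotected"] < 6))
  expect_equal(p1$p_index, p1$amp_scaled - p1$mu_scaled)
  expect_true(all(p1$amp_scaled >= 0 & p1$amp_scaled <= 1))
  expect_error(protection_index(scores), "seed is mandatory")
  expect_warning(protection_index(scores, n_perm = 50, seed = 1),
                 "coarse percentile")
})

test_that("null_type and perm variants run and broadly agree on extremes", {
  scores <- simulate_gene_scores(n_genes = 150, planted_frac = 0.1, seed = 9)
  pooled <- protection_index(scores, n_perm = 200, seed = 3)
  emp <- protection_index(scores, n_perm = 200, seed = 3,
                          null_type = "empirical")
  per_gene <- protection_index(scores, n_perm = 200, seed = 3,
                               null_type = "per_gene")
  swap <- protection_index(scores, n_perm = 200, seed = 3, perm = "swap")
  raw <- protection_index(scores, n_perm = 200, seed = 3, scale = "raw")
  # the gene with the single largest index is at the top under every null
  top <- which.max(pooled$p_index)
  for (v in list(emp, per_gene, swap)) {
    expect_equal(which.max(v$p_index), top)
    expect_gt(v$percentile[top], 94)
  }
  expect_equal(raw$p_index, scores$amp_freq - scores$mu)
})

test_that("consensus_calls applies the >= min_cohorts rule", {
  rec <- data.frame(
    gene = rep(c("A", "B", "C"), each = 4),
    klass = c(rep("protected", 3), "neither",
              rep("unprotected", 3), "protected",
              "protected", "protected", "neither", "neither"),
    cohort = rep(paste0("c", 1:4), 3),
    stringsAsFactors = FALSE
  )
  cc <- consensus_calls(rec, min_cohorts = 3)
  expect_equal(cc$consensus[cc$gene == "A"], "protected")
  expect_equal(cc$consensus[cc$gene == "B"], "unprotected")
  expect_equal(cc$consensus[cc$gene == "C"], "none")
  expect_equal(cc$n_protected[cc$gene == "A"], 3L)
  # a gene meeting both thresholds degrades to none with a warning
  both <- data.frame(
    gene = "D", klass = rep(c("protected", "unprotected"), each = 3),
    cohort = paste0("c", 1:6), stringsAsFactors = FALSE
  )
  expect_warning(cb <- consensus_calls(both), "both consensus")
  expect_equal(cb$consensus, "none")
})

test_that("essentiality_comparison contrasts the consensus sets", {
  consensus <- data.frame(
    gene = paste0("G", 1:8),
    consensus = rep(c("protected", "unprotected"), each = 4),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene = paste0("G", 1:8),
    crispr_effect = c(-1.5, -1.2, -1.4, -1.1, -0.1, 0, -0.05, 0.1),
    is_common_essential = c(rep(TRUE, 4), rep(FALSE, 4)),
    is_nonessential = c(rep(FALSE, 4), rep(TRUE, 4)),
    median_tpm = c(10, 12, 9, 11, 1, 2, 1.5, 3),
    stringsAsFactors = FALSE
  )
  out <- essentiality_comparison(consensus, genes)
  expect_lt(out$crispr$median_protected, out$crispr$median_unprotected)
  expect_equal(out$essential_overlap$protected_essential, 4)
  expect_equal(out$essential_overlap$unprotected_nonessential, 4)
  expect_gt(out$expression$median_protected, out$expression$median_unprotected)
  empty <- data.frame(gene = "G1", consensus = "protected",
                      stringsAsFactors = FALSE)
  expect_message(res <- essentiality_comparison(empty, genes), "skipped")
  expect_null(res$crispr)
})
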