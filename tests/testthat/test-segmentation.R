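test_that("build_grid produces the documented partitions", {
  g <- genome_build(c("chr1", "chr2"), c(100e6, 80e6), c(60e6, 40e6))
  grid <- build_grid(g, "fixed", j = 36e6)
  expect_equal(grid$start[grid$chrom == "chr1"], c(1, 36e6 + 1, 72e6 + 1))
  expect_equal(grid$end[grid$chrom == "chr1"], c(36e6, 72e6, 100e6))
  expect_equal(grid$bin_id[1], "chr1:1-36000000")
  expect_equal(attr(grid, "scale"), "fixed")

  arms <- build_grid(g, "arm")
  expect_equal(nrow(arms), 4)
  expect_equal(arms$end[arms$chrom == "chr1"], c(60e6, 100e6))

  chroms <- build_grid(g, "chromosome")
  expect_equal(chroms$end, g$length)

  genes <- data.frame(gene = c("B", "A"), chrom = "chr2",
                      start = c(5e6, 1e6), end = c(6e6, 2e6), coding_bp = 1e3)
  gg <- build_grid(g, "gene", genes = genes)
  expect_equal(gg$bin_id, c("A", "B"))  # sorted by position
  expect_error(build_grid(g, "gene"), "gene annotation")
  expect_error(build_grid(g, "fixed"), "j > 0")
})

test_that("classify_call uses strict cutoffs", {
  expect_equal(
    classify_call(c(0.2, 0.2000001, -0.2, -0.2000001, 0)),
    c("neutral", "amplified", "neutral", "deleted", "neutral")
  )
  expect_error(classify_call(0.5, amp_cut = 0), "amp_cut > 0")
})

test_that("classify_event applies the 90%/50% rules", {
  g <- genome_build("chr1", 100e6, 60e6)  # p arm 60 Mb, q arm 40 Mb
  calls <- data.frame(
    chrom = "chr1",
    start = c(1,    1,    1,    1,    55e6),
    end   = c(90e6, 89e6, 30e6, 29e6, 80e6),
    stringsAsFactors = FALSE
  )
  # 90e6/100e6 = 90% exactly -> chromosomal; 89% covers >50% of p -> arm;
  # 30e6/60e6 = 50% of p exactly -> arm; 29 Mb < 50% -> focal;
  # centromere-spanning: 5 Mb on p, 20 Mb on q -> uses q (20/40 = 50%) -> arm
  expect_equal(classify_event(calls, g),
               c("chromosomal", "arm", "arm", "focal", "arm"))
  expect_error(classify_event(data.frame(chrom = "chrZ", start = 1, end = 2), g),
               "absent")
})

test_that("patient_bin_states applies the union-coverage majority rule", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 10e6)  # a single 10 Mb bin
  pats <- c("T1", "T2", "T3", "T4")
  cna <- data.frame(
    patient = c("T1", "T1",          # two disjoint amps, 3 Mb each: 60% -> A
                "T2", "T2",          # two overlapping amps, union 4 Mb: 40% -> N
                "T3"),               # deletion covering 80% -> D
    chrom = "chr1",
    start = c(1, 4e6, 1, 2e6, 1),
    end   = c(3e6, 7e6 - 1, 3e6, 4e6, 8e6),
    segment_mean = c(0.5, 0.5, 0.5, 0.5, -0.5),
    stringsAsFactors = FALSE
  )
  st <- patient_bin_states(cna, grid, pats, g)
  expect_equal(unname(st[1, ]), c("A", "N", "D", "N"))
  expect_equal(dimnames(st), list(grid$bin_id, pats))
})

test_that("A/D conflicts resolve by coverage, ties to A with a warning", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 10e6)
  # amp covers 70%, del covers 60%: both qualify, amp wins
  cna <- data.frame(
    patient = "T1", chrom = "chr1", start = c(1, 4e6 + 1),
    end = c(7e6, 10e6), segment_mean = c(0.5, -0.5), stringsAsFactors = FALSE
  )
  st <- patient_bin_states(cna, grid, "T1", g)
  expect_equal(unname(st[1, 1]), "A")
  cna$segment_mean <- c(-0.5, 0.5)  # now del covers 70%
  st <- patient_bin_states(cna, grid, "T1", g)
  expect_equal(unname(st[1, 1]), "D")
  # exact tie: amp and del each cover the full bin
  cna2 <- data.frame(
    patient = "T1", chrom = "chr1", start = 1, end = 10e6,
    segment_mean = c(0.5, -0.5), stringsAsFactors = FALSE
  )
  expect_warning(st <- patient_bin_states(cna2, grid, "T1", g), "tie")
  expect_equal(unname(st[1, 1]), "A")
})

test_that("patient_bin_states respects the event-class filter", {
  g <- genome_build("chr1", 100e6, 60e6)
  grid <- build_grid(g, "fixed", j = 50e6)
  cna <- data.frame(
    patient = c("T1", "T2"), chrom = "chr1", start = c(1, 1),
    end = c(100e6, 20e6), segment_mean = 0.5, stringsAsFactors = FALSE
  )
  st_all <- patient_bin_states(cna, grid, c("T1", "T2"), g)
  expect_equal(unname(st_all[, "T1"]), c("A", "A"))
  st_focal <- patient_bin_states(cna, grid, c("T1", "T2"), g,
                                 event_filter = "focal")
  expect_equal(unname(st_focal[, "T1"]), c("N", "N"))  # chromosomal removed
  expect_equal(unname(st_focal[, "T2"]), c("N", "N"))  # 20/50 Mb < overlap_frac
  st_any <- patient_bin_states(cna, grid, c("T1", "T2"), g,
                               event_filter = "focal", overlap_frac = 0.2)
  expect_equal(unname(st_any[, "T2"]), c("A", "N"))
  expect_error(
    patient_bin_states(cna, grid, "T1", g),
    "outside the supplied patient universe"
  )
})

test_that("empty or all-neutral calls give all-N states", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 5e6)
  cna <- data.frame(patient = "T1", chrom = "chr1", start = 1, end = 10e6,
                    segment_mean = 0.1, stringsAsFactors = FALSE)
  st <- patient_bin_states(cna, grid, c("T1", "T2"), g)
  expect_true(all(st == "N"))
  st0 <- patient_bin_states(cna[0, ], grid, c("T1", "T2"), g)
  expect_true(all(st0 == "N"))
})

test_that("gene_bin_map assigns genes by midpoint", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 5e6)
  genes <- data.frame(
    gene = c("A", "B", "C"), chrom = c("chr1", "chr1", "chr9"),
    start = c(4e6, 4e6 + 2, 1), end = c(6e6 - 2, 6e6, 100),
    coding_bp = 1e3, stringsAsFactors = FALSE
  )
  # A midpoint just below 5e6 -> bin 1; B midpoint just above -> bin 2;
  # C on an unknown chromosome -> NA
  expect_equal(gene_bin_map(genes, grid), c(1L, 2L, NA))
})

test_that("write_grid_bed emits 0-based half-open records", {
  g <- genome_build("chr1", 10e6, 5e6)
  grid <- build_grid(g, "fixed", j = 5e6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_grid_bed(grid, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, c(0, 5e6))
  expect_equal(bed$V3, c(5e6, 10e6))
  expect_equal(bed$V4, grid$bin_id)
})
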