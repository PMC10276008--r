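#' Variant_Classification vocabulary
#'
#' Fixed mapping from MAF `Variant_Classification` terms to coding /
#' synonymous status. Unknown terms are treated as non-coding with a warning.
#'
#' @return A data.frame with columns `consequence`, `is_coding`,
#'   `is_synonymous`.
#' @export
consequence_table <- function() {
  data.frame(
    consequence = c(
      "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
      "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
      "Translation_Start_Site", "Splice_Site", "Silent",
      "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA",
      "Targeted_Region", "lincRNA", "Intergenic"
    ),
    is_coding = c(rep(TRUE, 10), rep(FALSE, 10)),
    is_synonymous = c(rep(FALSE, 9), TRUE, rep(FALSE, 10)),
    stringsAsFactors = FALSE
  )
}

#' Read a SEG file of somatic copy-number calls
#'
#' Expects the tab-separated SEG dialect with 1-based inclusive coordinates
#' and a header containing at least Sample, Chromosome, Start, End and
#' Segment_Mean (case-insensitive; `Num_Probes` is ignored if present).
#' Coordinates are kept 1-based inclusive internally, the convention shared
#' by SEG, MAF and the GenomicRanges machinery used for all interval
#' arithmetic.
#'
#' @param path Path to a SEG file.
#' @param genome A `genome_build` used to validate coordinates; `NULL` skips
#'   validation.
#' @return A data.frame of CNA calls with columns `patient`, `chrom`,
#'   `start`, `end`, `segment_mean`.
#' @export
read_seg <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  want <- c(
    patient = "sample", chrom = "chromosome", start = "start",
    end = "end", segment_mean = "segment_mean"
  )
  idx <- match(want, nm)
  if (anyNA(idx)) {
    stop("SEG file missing column(s): ", paste(want[is.na(idx)], collapse = ", "))
  }
  out <- df[, idx]
  names(out) <- names(want)
  out$patient <- as.character(out$patient)
  out$chrom <- as.character(out$chrom)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out$segment_mean <- as.numeric(out$segment_mean)
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  if (length(bad)) {
    stop(
      "malformed SEG row(s) (end < start or unparseable) at line(s): ",
      paste(bad + 1L, collapse = ", ")
    )
  }
  if (!is.null(genome)) validate_coordinates(out, genome)
  out
}

#' Write CNA calls as a SEG file
#'
#' Round-trips [read_seg()] output bit-identically on valid input.
#'
#' @param calls Data.frame of CNA calls (`patient`, `chrom`, `start`, `end`,
#'   `segment_mean`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(calls, path) {
  out <- data.frame(
    Sample = calls$patient, Chromosome = calls$chrom,
    Start = format(calls$start, scientific = FALSE, trim = TRUE),
    End = format(calls$end, scientific = FALSE, trim = TRUE),
    Segment_Mean = calls$segment_mean,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAF-like mutation table
#'
#' Requires columns (case-insensitive) patient/Tumor_Sample_Barcode, chrom,
#' pos (or Start_Position), gene (or Hugo_Symbol) and consequence (or
#' Variant_Classification). Optional columns `cadd`, `polyphen`,
#' `aggregation_score`, `aggregation_fold_change`, `vaf`, `depth` are carried
#' through when present. `is_coding` / `is_synonymous` are derived from the
#' consequence vocabulary ([consequence_table()]); unknown terms map to
#' non-coding with a warning. Sex-chromosome records are kept here and
#' removed by downstream filters. Exact duplicate (patient, chrom, pos)
#' records are collapsed and the count reported via a message.
#'
#' @param path Path to a tab-separated mutation file.
#' @param genome Optional `genome_build` for coordinate validation.
#' @param dedup Collapse exact duplicate (patient, chrom, pos) rows.
#' @return A data.frame of mutation records.
#' @export
read_mutations <- function(path, genome = NULL, dedup = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(df[[i]])
    }
    NULL
  }
  patient <- pick("patient", "tumor_sample_barcode", "sample")
  chrom <- pick("chrom", "chromosome")
  pos <- pick("pos", "start_position", "position")
  gene <- pick("gene", "hugo_symbol")
  consequence <- pick("consequence", "variant_classification")
  if (is.null(patient) || is.null(chrom) || is.null(pos) ||
      is.null(gene) || is.null(consequence)) {
    stop("mutation file missing one of patient/chrom/pos/gene/consequence")
  }
  pos <- suppressWarnings(as.numeric(pos))
  if (anyNA(pos)) {
    stop(
      "unparseable position at line(s): ",
      paste(which(is.na(pos)) + 1L, collapse = ", ")
    )
  }
  voc <- consequence_table()
  hit <- match(consequence, voc$consequence)
  if (anyNA(hit)) {
    warning(
      sum(is.na(hit)), " mutation(s) with unknown consequence term(s) ",
      "treated as non-coding: ",
      paste(unique(consequence[is.na(hit)]), collapse = ", ")
    )
  }
  out <- data.frame(
    patient = as.character(patient), chrom = as.character(chrom),
    pos = pos, gene = as.character(gene),
    is_coding = ifelse(is.na(hit), FALSE, voc$is_coding[hit]),
    is_synonymous = ifelse(is.na(hit), FALSE, voc$is_synonymous[hit]),
    stringsAsFactors = FALSE
  )
  for (opt in c("cadd", "polyphen", "aggregation_score",
                "aggregation_fold_change", "vaf", "depth")) {
    v <- pick(opt)
    if (!is.null(v)) out[[opt]] <- as.numeric(v)
  }
  if (dedup) {
    key <- paste(out$patient, out$chrom, out$pos)
    dup <- duplicated(key)
    if (any(dup)) {
      message("collapsed ", sum(dup), " duplicate mutation record(s)")
      out <- out[!dup, , drop = FALSE]
    }
  }
  if (!is.null(genome)) {
    known <- intersect(unique(out$chrom), genome$chrom)
    len <- genome$length[match(out$chrom, genome$chrom)]
    bad <- which(out$chrom %in% known & (out$pos < 1 | out$pos > len))
    if (length(bad)) {
      stop("position outside chromosome at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  out
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene`, `chrom`, `start`, `end`, `coding_bp`
#' and any of the optional property columns `pli`, `ghis`, `median_tpm`,
#' `is_og`, `is_tsg`, `is_go`, `crispr_effect`, `is_common_essential`,
#' `is_nonessential`.
#'
#' @param path Path to the table.
#' @param genome Optional `genome_build` for validation.
#' @return A data.frame of gene annotations.
#' @export
read_gene_table <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end", "coding_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$coding_bp > df$end - df$start + 1)) {
    stop("coding_bp exceeds gene length for some genes")
  }
  for (fl in c("is_og", "is_tsg", "is_go", "is_common_essential", "is_nonessential")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  if (!is.null(genome)) validate_coordinates(df, genome)
  df
}

#' Read an allele-specific copy-number table
#'
#' Tab-separated with columns `patient`, `chrom`, `start`, `end`, `major`,
#' `minor`, `purity`.
#'
#' @param path Path to the table.
#' @return A data.frame of allele-specific segments.
#' @export
read_ascn_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "chrom", "start", "end", "major", "minor", "purity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele-specific CN table missing: ", paste(miss, collapse = ", "))
  if (any(df$minor > df$major)) stop("minor allele count exceeds major")
  if (any(df$purity <= 0 | df$purity > 1)) stop("purity must be in (0, 1]")
  df
}

#' Read a BED coverage mask
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention and normalized (sorted, overlaps merged).
#'
#' @param path Path to a BED file (chrom, start, end; no header).
#' @return A normalized data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$start <- df$start + 1L
  normalize_mask(df)
}

# Sort and merge overlapping/adjacent mask intervals (1-based inclusive).
normalize_mask <- function(mask) {
  if (nrow(mask) == 0) return(mask)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(mask$start, mask$end)
  ))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Remove mutations falling inside a coverage mask
#'
#' Mutations inside regions not covered by the CNA assay are discarded so
#' that the copy-neutral mutation rate is only estimated where copy-number
#' state is known. Idempotent; the mask interval order is irrelevant.
#'
#' @param muts Mutation data.frame (needs `chrom`, `pos`).
#' @param mask Data.frame of masked intervals (`chrom`, `start`, `end`,
#'   1-based inclusive). May be empty or `NULL`.
#' @return `muts` restricted to positions outside every mask interval, with
#'   the removed count reported via a message.
#' @export
apply_coverage_mask <- function(muts, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(muts)
  mask <- normalize_mask(mask)
  mgr <- GenomicRanges::GRanges(muts$chrom, IRanges::IRanges(muts$pos, muts$pos))
  kgr <- GenomicRanges::GRanges(mask$chrom, IRanges::IRanges(mask$start, mask$end))
  hit <- GenomicRanges::countOverlaps(mgr, kgr) > 0
  if (any(hit)) message("coverage mask removed ", sum(hit), " mutation(s)")
  muts[!hit, , drop = FALSE]
}
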