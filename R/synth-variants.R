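## Multi-sample variant tables: in-memory container, VCF 4.2 / BED
## serialization, and a simulator planting shared parental variants plus
## per-sample de novo SNVs with a chosen base-change spectrum.

#' Multi-sample variant table
#'
#' In-memory container for called variants across samples. `records`
#' carries per-variant fields (`chrom`, `pos` 1-based, `ref`, `alt`, `mq`
#' mapping quality, `dp` read depth); per-sample state is carried in three
#' parallel matrices (variants x samples): `called` (a non-reference
#' genotype is asserted), `af` (variant-caller allele frequency, `NA`
#' unless called) and `gt_known` (the genotype is known at all, i.e. not
#' `./.`).
#'
#' @param records data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `mq`, `dp`.
#' @param called,af,gt_known matrices, one column per sample.
#' @param samples sample names (columns of the matrices).
#' @return object of class `variant_table`.
#' @export
variant_table <- function(records, called, af, gt_known, samples) {
  records <- as.data.frame(records)
  need <- c("chrom", "pos", "ref", "alt", "mq", "dp")
  stopifnot(all(need %in% names(records)))
  n <- nrow(records)
  called <- matrix(as.logical(called), n, length(samples),
                   dimnames = list(NULL, samples))
  af <- matrix(as.numeric(af), n, length(samples),
               dimnames = list(NULL, samples))
  gt_known <- matrix(as.logical(gt_known), n, length(samples),
                     dimnames = list(NULL, samples))
  if (any(records$ref == records$alt)) stop("ref must differ from alt")
  if (any(records$dp < 0)) stop("dp must be non-negative")
  if (any(!is.na(af) & !called))
    stop("allele frequency defined only when called")
  structure(list(records = records, called = called, af = af,
                 gt_known = gt_known, samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants x %d samples (%s)\n",
              nrow(x$records), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$records), length(x$samples))

## subset rows of a variant table
vt_slice <- function(vt, idx) {
  variant_table(vt$records[idx, , drop = FALSE],
                vt$called[idx, , drop = FALSE],
                vt$af[idx, , drop = FALSE],
                vt$gt_known[idx, , drop = FALSE], vt$samples)
}

#' Write a variant table as VCF 4.2
#'
#' `MQ` and `DP` go to INFO; per-sample columns carry `GT:AF` (genotype
#' `0/1` when called, `0/0` when known reference, `./.` when unknown).
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  r <- vt$records
  ord <- order(r$chrom, r$pos)
  fmt_sample <- function(i, s) {
    gt <- if (vt$called[i, s]) "0/1"
          else if (vt$gt_known[i, s]) "0/0" else "./."
    af <- if (!is.na(vt$af[i, s])) sprintf("%.4g", vt$af[i, s]) else "."
    paste0(gt, ":", af)
  }
  body <- vapply(ord, function(i) {
    paste(c(r$chrom[i], r$pos[i], ".", r$ref[i], r$alt[i], ".", "PASS",
            sprintf("MQ=%g;DP=%d", r$mq[i], as.integer(r$dp[i])), "GT:AF",
            vapply(vt$samples, function(s) fmt_sample(i, s),
                   character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses with \pkg{vcfR}; `MQ` and `DP` are taken from INFO (configurable
#' to per-sample FORMAT fields via `mq_field`/`dp_field` = `"FORMAT"`, in
#' which case the maximum across samples is recorded per variant).
#' Genotypes containing a non-reference allele count as called; `./.`
#' genotypes count as unknown. Per-sample `AF` is read from FORMAT when
#' present.
#'
#' @param path VCF path.
#' @param mq_field,dp_field `"INFO"` (default) or `"FORMAT"`.
#' @return a [variant_table()].
#' @export
read_vcf_table <- function(path, mq_field = "INFO", dp_field = "INFO") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    val <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(val)) rep(NA_real_, nrow(fix)) else val
  }
  grab <- function(which, key) {
    if (which == "INFO") return(info_num(key))
    m <- vcfR::extract.gt(v, element = key, as.numeric = TRUE)
    apply(m, 1, function(x) if (all(is.na(x))) NA_real_
          else max(x, na.rm = TRUE))
  }
  mq <- grab(mq_field, "MQ")
  dp <- grab(dp_field, "DP")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  called <- !is.na(gt) & grepl("[1-9]", gt)
  gt_known <- !is.na(gt) & !grepl("^\\.([/|]\\.)?$", gt)
  af <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if ("AF" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    af_raw <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
    af[called] <- af_raw[called]
  }
  variant_table(
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
               alt = fix$ALT, mq = mq, dp = dp),
    called, af, gt_known, samples)
}

#' Write / read low-complexity regions as BED
#'
#' 0-based half-open intervals, serialized through \pkg{rtracklayer}.
#'
#' @param intervals data frame with `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @param path BED path.
#' @return `read_bed`: a data frame of 0-based half-open intervals.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

MUTATION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

## draw (ref, alt) for a strand-collapsed class, randomly picking a strand
draw_ref_alt <- function(class) {
  parts <- strsplit(class, ">", fixed = TRUE)[[1]]
  if (runif(1) < 0.5) parts else unname(c(COMP[parts[1]], COMP[parts[2]]))
}

#' Simulate a multi-sample variant table with planted de novo SNVs
#'
#' Emulates the input of a WGS de novo off-target analysis: one control
#' (non-targeting gRNA) sample plus edited clones, sharing `n_shared`
#' parental variants (called in every sample) and carrying per-clone
#' private de novo SNVs with a chosen base-change spectrum (e.g. an
#' APOBEC-like C>T/G>A-enriched one). A fraction of each clone's de novos
#' can be placed inside generated low-complexity regions, and a number of
#' private variants can be given an unknown control genotype; both classes
#' are removed by [filter_denovo()] and are labelled in the returned
#' truth.
#'
#' @param n_samples total samples (>= 2; the first is the control).
#' @param n_shared shared parental variants.
#' @param denovo_spec named counts by class (subset of
#'   `r paste(MUTATION_CLASSES, collapse = ", ")`) applied to each edited
#'   sample, or a list of such vectors (one per edited sample).
#' @param mq_range,dp_range inclusive integer ranges for MQ and DP (the
#'   defaults pass the de novo filter thresholds).
#' @param lcr_fraction fraction of each clone's de novos placed inside
#'   low-complexity regions.
#' @param seed integer seed.
#' @param n_control_unknown per-clone count of private variants whose
#'   control genotype is unknown.
#' @param chrom,chrom_len contig name and length for placement.
#' @return list with `variants` (a [variant_table()]), `lcr` (data frame
#'   of 0-based half-open intervals) and `truth` (per-variant data frame:
#'   `pos`, `ref`, `alt`, `class`, `kind` in
#'   {shared, denovo, control_unknown}, `sample`, `in_lcr`).
#' @export
simulate_variant_tables <- function(n_samples = 4, n_shared = 50,
                                    denovo_spec = c("C>T" = 8, "C>A" = 1,
                                                    "T>C" = 1),
                                    mq_range = c(40, 60),
                                    dp_range = c(11, 80),
                                    lcr_fraction = 0, seed = 1,
                                    n_control_unknown = 0,
                                    chrom = "chr1", chrom_len = 1e6) {
  if (n_samples < 2) stop("need at least two samples (one control)")
  check_fraction(lcr_fraction, "lcr_fraction")
  samples <- c("nt-ctrl", paste0("clone", seq_len(n_samples - 1)))
  if (!is.list(denovo_spec))
    denovo_spec <- rep(list(denovo_spec), n_samples - 1)
  stopifnot(length(denovo_spec) == n_samples - 1)
  for (sp in denovo_spec)
    if (!all(names(sp) %in% MUTATION_CLASSES))
      stop("unknown mutation class in denovo_spec")
  with_seed(seed, {
    ## low-complexity intervals: 10 blocks of 200 bp in the left half
    lcr <- data.frame(
      chrom = chrom,
      start = sort(sample.int(as.integer(chrom_len / 2), 10)) )
    lcr$end <- lcr$start + 200L
    in_lcr <- function(p) any(p > lcr$start & p <= lcr$end)
    used <- integer(0)
    draw_pos <- function(inside_lcr) {
      for (i in 1:10000) {
        p <- if (inside_lcr) {
          row <- lcr[sample.int(nrow(lcr), 1), ]
          row$start + sample.int(200L, 1)
        } else sample.int(as.integer(chrom_len), 1)
        if (p %in% used) next
        if (!inside_lcr && in_lcr(p)) next
        used <<- c(used, p)
        return(p)
      }
      stop("could not place variant after bounded retries")
    }
    rows <- list()
    add_row <- function(kind, sample, class, inside_lcr) {
      ra <- draw_ref_alt(class)
      rows[[length(rows) + 1]] <<- data.frame(
        pos = draw_pos(inside_lcr), ref = ra[1], alt = ra[2],
        class = class, kind = kind, sample = sample, in_lcr = inside_lcr)
    }
    for (i in seq_len(n_shared))
      add_row("shared", NA_character_,
              sample(MUTATION_CLASSES, 1), FALSE)
    for (s in seq_len(n_samples - 1)) {
      spec <- denovo_spec[[s]]
      classes <- rep(names(spec), spec)
      n_in <- as.integer(round(lcr_fraction * length(classes)))
      inside <- rep(FALSE, length(classes))
      if (n_in > 0) inside[sample.int(length(classes), n_in)] <- TRUE
      for (j in seq_along(classes))
        add_row("denovo", samples[s + 1], classes[j], inside[j])
      for (j in seq_len(n_control_unknown))
        add_row("control_unknown", samples[s + 1],
                sample(MUTATION_CLASSES, 1), FALSE)
    }
    if (length(rows) == 0)
      rows <- list(data.frame(pos = integer(0), ref = character(0),
                              alt = character(0), class = character(0),
                              kind = character(0), sample = character(0),
                              in_lcr = logical(0)))
    truth <- do.call(rbind, rows)
    n <- nrow(truth)
    called <- matrix(FALSE, n, n_samples, dimnames = list(NULL, samples))
    gt_known <- matrix(TRUE, n, n_samples, dimnames = list(NULL, samples))
    af <- matrix(NA_real_, n, n_samples, dimnames = list(NULL, samples))
    for (i in seq_len(n)) {
      if (truth$kind[i] == "shared") {
        called[i, ] <- TRUE
        af[i, ] <- round(runif(n_samples, 0.3, 0.7), 2)
      } else {
        called[i, truth$sample[i]] <- TRUE
        af[i, truth$sample[i]] <- sample(c(0.25, 0.5, 0.75, 1), 1)
        if (truth$kind[i] == "control_unknown")
          gt_known[i, "nt-ctrl"] <- FALSE
      }
    }
    recs <- data.frame(
      chrom = chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
      mq = sample(mq_range[1]:mq_range[2], n, replace = TRUE),
      dp = sample(dp_range[1]:dp_range[2], n, replace = TRUE))
    ord <- order(recs$pos)
    list(variants = variant_table(recs[ord, ],
                                  called[ord, , drop = FALSE],
                                  af[ord, , drop = FALSE],
                                  gt_known[ord, , drop = FALSE], samples),
         lcr = lcr, truth = truth[ord, ])
  })
}
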