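## On-target allele-outcome extraction from alignments, VCF-based on-target
## frequencies, multi-sample de novo variant filtering, mutation spectra
## and per-clone summaries.

## normalise a "site" argument (sim_site, find_sites row, or plain list)
## to list(chrom, window = c(start0, end0), strand)
site_fields <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    return(list(chrom = site$chrom, strand = site$strand,
                window = c(site$window_start, site$window_end)))
  }
  stopifnot(!is.null(site$chrom), !is.null(site$window),
            !is.null(site$strand))
  list(chrom = site$chrom, strand = site$strand,
       window = as.integer(site$window))
}

## windows of a site list / data frame as GRanges
sites_granges <- function(sites) {
  if (is.data.frame(sites)) {
    GenomicRanges::GRanges(sites$chrom,
      IRanges::IRanges(start = sites$window_start + 1L,
                       end = sites$window_end))
  } else {
    f <- lapply(sites, site_fields)
    GenomicRanges::GRanges(
      vapply(f, `[[`, character(1), "chrom"),
      IRanges::IRanges(
        start = vapply(f, function(x) x$window[1] + 1L, integer(1)),
        end = vapply(f, function(x) x$window[2], integer(1))))
  }
}

#' On-target allele frequencies from a variant table
#'
#' Returns the variant-caller allele frequency for every called record
#' whose position lies inside any target-site window and which passes the
#' quality cutoffs (both bounds inclusive: records with mapping quality
#' `>= mq_min` and read depth `>= dp_min` are kept).
#'
#' @param vt a [variant_table()].
#' @param sites site list or data frame carrying 20-nt windows.
#' @param mq_min minimum mapping quality (default 35, inclusive).
#' @param dp_min minimum read depth (default 10, inclusive).
#' @return data frame with `chrom`, `pos`, `ref`, `alt`, `sample`, `af`;
#'   empty (zero rows) when nothing passes.
#' @export
ontarget_vcf_frequencies <- function(vt, sites, mq_min = 35, dp_min = 10) {
  stopifnot(inherits(vt, "variant_table"))
  r <- vt$records
  gr_var <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$pos, width = 1L))
  hit <- GenomicRanges::countOverlaps(gr_var, sites_granges(sites)) > 0
  pass <- hit & !is.na(r$mq) & !is.na(r$dp) & r$mq >= mq_min &
    r$dp >= dp_min
  idx <- which(pass)
  rows <- lapply(idx, function(i) {
    s <- vt$samples[vt$called[i, ]]
    if (length(s) == 0) return(NULL)
    data.frame(chrom = r$chrom[i], pos = r$pos[i], ref = r$ref[i],
               alt = r$alt[i], sample = s, af = vt$af[i, s])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), af = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Walk a CIGAR string and return the read bases over a 1-based reference
## window: a character vector of length window width (NA where the window
## position is not aligned), plus any insertion strings keyed by the
## window offset after which they occur.
read_window_bases <- function(pos, cigar, seq, ws, we) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  kinds <- sub("^[0-9]+", "", toks)
  wlen <- we - ws + 1L
  bases <- rep(NA_character_, wlen)
  ins <- list()
  rpos <- pos      # next reference position
  qpos <- 1L       # next query position
  sq <- seq_chars(seq)
  for (k in seq_along(kinds)) {
    len <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      lo <- max(rpos, ws)
      hi <- min(rpos + len - 1L, we)
      if (lo <= hi)
        bases[(lo - ws + 1L):(hi - ws + 1L)] <-
          sq[(qpos + lo - rpos):(qpos + hi - rpos)]
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (kind == "I") {
      ## insertion between rpos-1 and rpos
      if (rpos - 1L >= ws && rpos <= we)
        ins[[as.character(rpos - 1L - ws + 1L)]] <-
          chars_to_seq(sq[qpos:(qpos + len - 1L)])
      qpos <- qpos + len
    } else if (kind %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (kind == "S") {
      qpos <- qpos + len
    } # H, P consume nothing
  }
  list(bases = bases, ins = ins)
}

#' Extract allele outcomes across a target-site window
#'
#' Implements the spanning-read allele extraction rule: only reads whose
#' alignment covers the entirety of the 20-nt window (every window
#' position aligned; reads with deletions or clips inside the window are
#' excluded) and whose mapping quality is `>= mq_min` are counted.
#' Duplicate-marked, secondary, supplementary and unmapped records are
#' excluded. Distinct window sequences are alleles; alleles supported by
#' fewer than `min_support` reads are removed, but the frequency
#' denominator remains the total number of spanning, MQ-passing reads.
#' Reads with insertions inside the window yield length-mismatched alleles
#' that are reported but flagged `indel` and not classified by edited Cs.
#'
#' @param alignments SAM record data frame (see [read_sam()]).
#' @param site site with `chrom`, 0-based half-open `window`, `strand`
#'   (e.g. a `sim_site` or one row of [find_sites()]).
#' @param mq_min minimum mapping quality (default 35, inclusive).
#' @param min_support minimum reads per retained allele (default 4;
#'   alleles with support `< 4` are removed).
#' @param reference_window reference window sequence in spacer
#'   orientation; defaults to the site's `spacer` when present. Needed for
#'   edited-C classification.
#' @param target_c_positions preferred target C positions (1-based,
#'   PAM-proximal = 1) for bystander classification.
#' @return data frame of class `allele_outcomes`: `window_seq` (spacer
#'   orientation), `support`, `frequency`, `indel`, `n_edited_c`,
#'   `edited_positions` (comma-separated), `other_diff`, `bystander`;
#'   attributes `total_spanning` (denominator), `removed` (below-support
#'   alleles) and `zero_spanning` flag.
#' @export
window_allele_outcomes <- function(alignments, site, mq_min = 35,
                                   min_support = 4,
                                   reference_window = NULL,
                                   target_c_positions = NULL) {
  sf <- site_fields(site)
  if (is.null(reference_window) && !is.null(site$spacer))
    reference_window <- site$spacer
  if (is.null(target_c_positions) &&
      !is.null(site$target_c_positions))
    target_c_positions <- site$target_c_positions
  ws <- sf$window[1] + 1L   # 1-based inclusive
  we <- sf$window[2]
  a <- alignments
  drop_flag <- bitwAnd(a$flag, 0x4L) > 0 |    # unmapped
    bitwAnd(a$flag, 0x100L) > 0 |             # secondary
    bitwAnd(a$flag, 0x400L) > 0 |             # duplicate
    bitwAnd(a$flag, 0x800L) > 0               # supplementary
  a <- a[!drop_flag & a$rname == sf$chrom & a$mapq >= mq_min, ,
         drop = FALSE]
  alleles <- character(0)
  for (i in seq_len(nrow(a))) {
    wb <- read_window_bases(a$pos[i], a$cigar[i], a$seq[i], ws, we)
    if (is.null(wb) || anyNA(wb$bases)) next  # entirety rule
    parts <- wb$bases
    if (length(wb$ins) > 0) {
      for (off in rev(sort(as.integer(names(wb$ins)))))
        parts <- append(parts, seq_chars(wb$ins[[as.character(off)]]),
                        after = off)
    }
    alleles <- c(alleles, chars_to_seq(parts))
  }
  total <- length(alleles)
  empty <- data.frame(window_seq = character(0), support = integer(0),
                      frequency = numeric(0), indel = logical(0),
                      n_edited_c = integer(0),
                      edited_positions = character(0),
                      other_diff = logical(0), bystander = logical(0))
  if (total == 0) {
    out <- empty
    attr(out, "total_spanning") <- 0L
    attr(out, "removed") <- empty
    attr(out, "zero_spanning") <- TRUE
    class(out) <- c("allele_outcomes", "data.frame")
    return(out)
  }
  if (sf$strand == "-") alleles <- revcomp(alleles)
  counts <- sort(table(alleles), decreasing = TRUE)
  build <- function(seqs, supports) {
    rows <- lapply(seq_along(seqs), function(i) {
      cl <- if (is.null(reference_window)) NULL
            else classify_outcome(seqs[i], reference_window,
                                  target_c_positions)
      data.frame(
        window_seq = seqs[i], support = supports[i],
        frequency = supports[i] / total,
        indel = if (is.null(cl)) nchar(seqs[i]) !=
          (we - ws + 1L) else cl$indel,
        n_edited_c = if (is.null(cl) || cl$indel) NA_integer_
          else cl$n_edited_c,
        edited_positions = if (is.null(cl) || cl$indel) NA_character_
          else paste(cl$edited_positions, collapse = ","),
        other_diff = if (is.null(cl) || cl$indel) NA
          else length(cl$other_positions) > 0,
        bystander = if (is.null(cl) || cl$indel) NA else cl$bystander)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  keep <- counts >= min_support
  out <- if (any(keep)) build(names(counts)[keep],
                              as.integer(counts[keep])) else empty
  removed <- if (any(!keep)) build(names(counts)[!keep],
                                   as.integer(counts[!keep])) else empty
  attr(out, "total_spanning") <- total
  attr(out, "removed") <- removed
  attr(out, "zero_spanning") <- FALSE
  class(out) <- c("allele_outcomes", "data.frame")
  out
}

#' Classify an allele by its edited Cs
#'
#' Compares an allele to the reference window (both in spacer
#' orientation; pass `strand = "-"` if both are given in plus-strand
#' orientation instead, in which case they are reverse-complemented
#' first, turning G>A differences into C>T). Counts positions where a
#' reference C became a T; any other difference is reported separately.
#' `bystander` is `TRUE` when any edited position is not a preferred
#' target C. Length-mismatched alleles are flagged `indel` and not
#' classified.
#'
#' @param allele allele window sequence.
#' @param reference_window reference window sequence.
#' @param target_c_positions preferred target C positions (1-based,
#'   PAM-proximal = 1); `NULL` treats every edited C as a bystander
#'   candidate check with no preferred set (bystander `FALSE` only for
#'   unedited alleles).
#' @param strand orientation of the supplied sequences (see above).
#' @return list with `n_edited_c`, `edited_positions`, `other_positions`,
#'   `bystander`, `indel`.
#' @export
classify_outcome <- function(allele, reference_window,
                             target_c_positions = NULL, strand = "+") {
  if (strand == "-") {
    allele <- revcomp(allele)
    reference_window <- revcomp(reference_window)
  }
  a <- seq_chars(allele)
  r <- seq_chars(reference_window)
  if (length(a) != length(r))
    return(list(n_edited_c = NA_integer_, edited_positions = integer(0),
                other_positions = integer(0), bystander = NA,
                indel = TRUE))
  diff <- which(a != r)
  edited <- diff[r[diff] == "C" & a[diff] == "T"]
  other <- setdiff(diff, edited)
  bystander <- if (is.null(target_c_positions))
    length(edited) > 0 else length(setdiff(edited,
                                           target_c_positions)) > 0
  list(n_edited_c = length(edited), edited_positions = edited,
       other_positions = other, bystander = bystander, indel = FALSE)
}

#' Filter a multi-sample table down to de novo variants
#'
#' Applies, in order: (a) remove variants called in every sample (a
#' non-reference genotype asserted in all samples marks a parental
#' variant); (b) remove variants with an unknown control genotype; (c)
#' keep mapping quality `>= mq_min` (inclusive); (d) keep read depth
#' `> dp_strict_min` (strict); (e) remove variants inside low-complexity
#' regions. Per-step removal counts are logged and conserve the total.
#'
#' @param vt a [variant_table()].
#' @param control_sample name of the control column (default
#'   `"nt-ctrl"`).
#' @param mq_min minimum mapping quality (default 40, inclusive).
#' @param dp_strict_min read-depth bound (default 10, strict: DP must
#'   exceed it).
#' @param lcr low-complexity regions: data frame of 0-based half-open
#'   `chrom`/`start`/`end` intervals, a BED path, or `NULL` to skip.
#' @return list with `variants` (filtered [variant_table()]) and `log`
#'   (data frame: `step`, `removed`, `remaining`).
#' @export
filter_denovo <- function(vt, control_sample = "nt-ctrl", mq_min = 40,
                          dp_strict_min = 10, lcr = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (!control_sample %in% vt$samples)
    stop("control sample not in table: ", control_sample)
  if (is.character(lcr) && length(lcr) == 1) lcr <- read_bed(lcr)
  steps <- character(0); removed <- integer(0); remaining <- integer(0)
  note <- function(name, keep, cur) {
    steps <<- c(steps, name)
    removed <<- c(removed, sum(!keep))
    cur <- vt_slice(cur, which(keep))
    remaining <<- c(remaining, nrow(cur$records))
    cur
  }
  cur <- vt
  cur <- note("not_called_in_all_samples",
              rowSums(cur$called) < length(cur$samples), cur)
  cur <- note("control_genotype_known",
              cur$gt_known[, control_sample], cur)
  cur <- note("mq_at_least_min",
              !is.na(cur$records$mq) & cur$records$mq >= mq_min, cur)
  cur <- note("dp_strictly_above_min",
              !is.na(cur$records$dp) & cur$records$dp > dp_strict_min,
              cur)
  if (!is.null(lcr) && nrow(lcr) > 0) {
    gr_l <- GenomicRanges::GRanges(lcr$chrom,
      IRanges::IRanges(start = lcr$start + 1L, end = lcr$end))
    gr_v <- GenomicRanges::GRanges(cur$records$chrom,
      IRanges::IRanges(cur$records$pos, width = 1L))
    keep <- GenomicRanges::countOverlaps(gr_v, gr_l) == 0
  } else keep <- rep(TRUE, nrow(cur$records))
  cur <- note("outside_low_complexity", keep, cur)
  list(variants = cur,
       log = data.frame(step = steps, removed = removed,
                        remaining = remaining))
}

#' Mutation spectrum of a variant set
#'
#' Partitions variants into SNVs and non-SNVs and bins SNVs into the six
#' strand-collapsed base-change classes (C>A, C>G, C>T, T>A, T>C, T>G; a
#' G>A call counts as C>T, and so on). An APOBEC-mediated CBE leaves a
#' C>T/G>A-dominated spectrum.
#'
#' @param variants a [variant_table()] or a data frame with `ref` and
#'   `alt` columns.
#' @return list with `counts` (named integer vector over the six
#'   classes), `fractions` (over SNVs; zero vector when no SNVs),
#'   `n_snv`, `n_non_snv`.
#' @export
mutation_spectrum <- function(variants) {
  if (inherits(variants, "variant_table")) variants <- variants$records
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% BASES &
    alt %in% BASES & ref != alt
  counts <- setNames(integer(length(MUTATION_CLASSES)), MUTATION_CLASSES)
  if (any(is_snv)) {
    r <- ref[is_snv]
    a <- alt[is_snv]
    flip <- r %in% c("A", "G")
    r[flip] <- COMP[r[flip]]
    a[flip] <- COMP[a[flip]]
    tab <- table(paste0(r, ">", a))
    counts[names(tab)] <- as.integer(tab)
  }
  n_snv <- sum(counts)
  fractions <- if (n_snv > 0) counts / n_snv else counts * 0
  list(counts = counts, fractions = fractions, n_snv = n_snv,
       n_non_snv = sum(!is_snv))
}

#' Summarize editing across a clone's target sites
#'
#' A site counts as edited when the summed frequency of its retained
#' non-reference C>T-bearing alleles (`n_edited_c >= 1`, indel alleles
#' excluded) reaches `reporting_threshold`.
#'
#' @param outcomes named list of [window_allele_outcomes()] results, one
#'   per targeted site.
#' @param clone_id label.
#' @param reporting_threshold minimum summed edited-allele frequency for
#'   a site to count as edited (default 0.1).
#' @return object of class `clone_summary`: `clone_id`,
#'   `n_sites_edited`, `per_site` (data frame: `site`,
#'   `edited_frequency`, `edited`).
#' @export
summarize_clone <- function(outcomes, clone_id = "clone",
                            reporting_threshold = 0.1) {
  check_fraction(reporting_threshold, "reporting_threshold")
  per_site <- do.call(rbind, lapply(seq_along(outcomes), function(i) {
    o <- outcomes[[i]]
    ed <- !is.na(o$n_edited_c) & o$n_edited_c >= 1 & !o$indel
    f <- sum(o$frequency[ed])
    data.frame(site = if (!is.null(names(outcomes)))
      names(outcomes)[i] else as.character(i),
      edited_frequency = f, edited = f >= reporting_threshold)
  }))
  structure(list(clone_id = clone_id,
                 n_sites_edited = sum(per_site$edited),
                 per_site = per_site),
            class = "clone_summary")
}

#' @export
print.clone_summary <- function(x, ...) {
  cat(sprintf("<clone_summary> %s: %d of %d target sites edited\n",
              x$clone_id, x$n_sites_edited, nrow(x$per_site)))
  invisible(x)
}
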