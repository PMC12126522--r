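## Minimal SAM text I/O (mandatory columns + MAPQ) and simulation of
## aligned reads over a target-site window with planted allele mixtures.
## SAM records are held as a plain data frame with the mandatory columns;
## no installed R package parses SAM text directly (Rsamtools reads BAM),
## so the (trivial) tab-separated record layout is handled here.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Write alignment records as SAM
#'
#' Writes a minimal coordinate-sorted SAM file (`@HD`, one `@SQ` line per
#' contig, mandatory columns only).
#'
#' @param records data frame with the eleven mandatory SAM columns
#'   (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`,
#'   `tlen`, `seq`, `qual`).
#' @param path output path.
#' @param contigs named integer vector of contig lengths for `@SQ` lines.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, path, contigs) {
  stopifnot(all(SAM_COLS %in% names(records)), !is.null(names(contigs)))
  records <- records[order(records$rname, records$pos), SAM_COLS]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  body <- do.call(paste, c(records, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into a record data frame
#'
#' @param path SAM file path.
#' @return list with `contigs` (named lengths from `@SQ`) and `records`
#'   (data frame of the mandatory columns; `flag`, `pos`, `mapq` integer).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- integer(0)
  if (length(sq) > 0) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    contigs <- setNames(ln, sn)
  }
  if (length(body) == 0) {
    rec <- as.data.frame(setNames(rep(list(character(0)), 11), SAM_COLS))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 11)
    if (length(bad) > 0)
      stop("malformed SAM record at line ", bad[1], " of body")
    rec <- as.data.frame(do.call(rbind,
                                 lapply(parts, function(x) x[1:11])),
                         stringsAsFactors = FALSE)
    names(rec) <- SAM_COLS
  }
  rec$flag <- as.integer(rec$flag)
  rec$pos <- as.integer(rec$pos)
  rec$mapq <- as.integer(rec$mapq)
  rec$pnext <- as.integer(rec$pnext)
  rec$tlen <- as.integer(rec$tlen)
  list(contigs = contigs, records = rec)
}

#' Simulate aligned reads over a target-site window
#'
#' Plants an allele mixture (the site's `truth_alleles`) into reads
#' spanning the site's 20-nt window. Allele counts are assigned exactly by
#' largest-remainder rounding of `frequency * n_reads` so that recovery
#' tests are exact; set `sampling = "binomial"` for multinomially sampled
#' counts instead. A stated fraction of reads is trimmed to cover the
#' window only partially (such reads are excluded by the spanning-read
#' rule downstream).
#'
#' @param genome named character vector with the site's contig.
#' @param site a `sim_site` (see [simulate_genome()],
#'   [plant_allele_mixture()]); its `truth_alleles` frequencies must sum
#'   to 1.
#' @param n_reads total reads to generate.
#' @param read_len read length; must exceed the window by `margin` so
#'   reads can span it.
#' @param mq_values mapping qualities to draw from (with replacement).
#' @param seed integer seed.
#' @param partial_fraction fraction of reads trimmed to partial window
#'   coverage.
#' @param sampling `"exact"` (largest remainder) or `"binomial"`.
#' @param margin minimum read overhang beyond the window.
#' @return data frame of SAM records with attributes `truth_counts`
#'   (named allele counts, spacer orientation) and `site`.
#' @export
simulate_edited_reads <- function(genome, site, n_reads, read_len = 60,
                                  mq_values = 60L, seed = 1,
                                  partial_fraction = 0,
                                  sampling = c("exact", "binomial"),
                                  margin = 2) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(site, "sim_site"), n_reads >= 1)
  check_fraction(partial_fraction, "partial_fraction")
  freqs <- site$truth_alleles
  if (abs(sum(freqs) - 1) > 1e-9) stop("truth frequencies must sum to 1")
  wlen <- site$window[2] - site$window[1]
  if (read_len < wlen + margin)
    stop("read_len must be >= window length + margin")
  g <- seq_chars(genome[[site$chrom]])
  n <- length(g)
  ws <- site$window[1] + 1L  # 1-based window start
  we <- site$window[2]       # 1-based window end (inclusive)
  with_seed(seed, {
    counts <- if (sampling == "exact") largest_remainder(freqs, n_reads)
              else as.integer(stats::rmultinom(1, n_reads, freqs))
    names(counts) <- names(freqs)
    allele_of_read <- rep(names(freqs), counts)
    n_partial <- as.integer(round(partial_fraction * n_reads))
    is_partial <- rep(FALSE, n_reads)
    if (n_partial > 0)
      is_partial[sample.int(n_reads, n_partial)] <- TRUE
    recs <- vector("list", n_reads)
    for (r in seq_len(n_reads)) {
      gm <- g
      ## place the allele in plus-strand orientation over the window
      win <- seq_chars(allele_of_read[r])
      if (site$strand == "-") win <- seq_chars(revcomp(allele_of_read[r]))
      gm[ws:we] <- win
      if (is_partial[r]) {
        ## read ends inside the window, covering 1..wlen-1 positions
        k <- sample.int(wlen - 1L, 1)
        start <- max(1L, we - wlen + k - read_len + 1L)
        end <- we - wlen + k
      } else {
        lo <- max(1L, we - read_len + 1L)
        hi <- min(ws, n - read_len + 1L)
        start <- if (hi > lo) sample(lo:hi, 1) else lo
        end <- min(n, start + read_len - 1L)
      }
      recs[[r]] <- data.frame(
        qname = sprintf("read_%04d", r), flag = 0L, rname = site$chrom,
        pos = start,
        mapq = as.integer(sample(rep(mq_values, 2), 1)),
        cigar = paste0(end - start + 1L, "M"),
        rnext = "*", pnext = 0L, tlen = 0L,
        seq = chars_to_seq(gm[start:end]), qual = "*")
    }
    out <- do.call(rbind, recs)
    attr(out, "truth_counts") <- counts
    attr(out, "site") <- site
    out
  })
}
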