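## Sanger chromatogram handling: TraceData container, readers (four-channel
## TSV dialect and AB1/ABIF), noise-based end trimming, per-position base
## proportion quantification, spacer window location and control
## normalization.

#' TraceData: per-position basecalls and channel peak intensities
#'
#' Container for a Sanger chromatogram reduced to one intensity 4-tuple per
#' called base (A, C, G, T channel order). This per-basecall grid is the
#' signal layer that editing quantification operates on; the raw
#' oversampled electropherogram is not retained.
#'
#' @param basecalls character vector of single letters over A,C,G,T,N.
#' @param intensities numeric matrix, one row per basecall, four columns of
#'   non-negative channel peak values in A,C,G,T order.
#' @param source_id label identifying the trace.
#' @return object of class `trace_data`.
#' @export
trace_data <- function(basecalls, intensities, source_id = "trace") {
  basecalls <- toupper(as.character(basecalls))
  intensities <- as.matrix(intensities)
  if (length(basecalls) != nrow(intensities))
    stop("basecalls and intensity rows differ in length")
  if (ncol(intensities) != 4)
    stop("intensities must have four channels (A,C,G,T)")
  if (any(intensities < 0) || any(!is.finite(intensities)))
    stop("intensities must be finite and non-negative")
  if (nrow(intensities) > 0 && any(rowSums(intensities) == 0))
    stop("trace has positions with all-zero channel signal")
  if (!all(basecalls %in% c(BASES, "N")))
    stop("basecalls must be over {A,C,G,T,N}")
  colnames(intensities) <- BASES
  structure(
    list(basecalls = basecalls, intensities = intensities,
         source_id = source_id),
    class = "trace_data"
  )
}

#' @export
print.trace_data <- function(x, ...) {
  cat(sprintf("<trace_data> %s: %d positions\n", x$source_id,
              length(x$basecalls)))
  if (length(x$basecalls) > 0)
    cat("  calls: ", paste(head(x$basecalls, 30), collapse = ""),
        if (length(x$basecalls) > 30) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.trace_data <- function(x) length(x$basecalls)

## subset a trace to a contiguous index range, preserving attributes
trace_slice <- function(trace, idx) {
  trace_data(trace$basecalls[idx], trace$intensities[idx, , drop = FALSE],
             trace$source_id)
}

#' Read a Sanger trace
#'
#' Two dialects are supported. `"tsv"` is a plain-text table with columns
#' `pos`, `basecall`, `A`, `C`, `G`, `T` (non-negative intensities).
#' `"ab1"` is the binary ABIF chromatogram format: basecalls are taken from
#' the `PBAS` tag and channel intensities from the analyzed traces
#' (`DATA9`-`DATA12`, channel order per `FWO_`) sampled at the called-base
#' peak locations (`PLOC`).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"ab1"`.
#' @return a [trace_data()] object.
#' @export
read_trace <- function(path, dialect = c("tsv", "ab1")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (dialect == "tsv") read_trace_tsv(path) else read_trace_ab1(path)
}

read_trace_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pos", "basecall", "A", "C", "G", "T")
  if (!all(need %in% names(tab)))
    stop("trace TSV must have columns: ", paste(need, collapse = ", "))
  zero <- which(rowSums(as.matrix(tab[, BASES])) == 0)
  if (length(zero) > 0)
    stop("all-zero channel signal at record pos=", tab$pos[zero[1]])
  trace_data(tab$basecall, as.matrix(tab[, BASES]),
             source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a trace in the four-channel TSV dialect
#'
#' @param trace a [trace_data()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trace_tsv <- function(trace, path) {
  tab <- data.frame(pos = seq_along(trace$basecalls),
                    basecall = trace$basecalls, trace$intensities,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- minimal ABIF reader -------------------------------------------------
## ABIF: 4-byte "ABIF" magic, big-endian; a directory of 28-byte entries
## (name, tag number, element type, element size, count, data size, data
## offset). Entries with data size <= 4 store the value in the offset field.

abif_read_entry <- function(con) {
  name <- rawToChar(readBin(con, "raw", 4))
  number <- readBin(con, "integer", 1, 4, endian = "big")
  etype <- readBin(con, "integer", 1, 2, endian = "big")
  esize <- readBin(con, "integer", 1, 2, endian = "big")
  count <- readBin(con, "integer", 1, 4, endian = "big")
  dsize <- readBin(con, "integer", 1, 4, endian = "big")
  doff_raw <- readBin(con, "raw", 4)
  readBin(con, "raw", 4) # handle, unused
  list(name = name, number = number, etype = etype, esize = esize,
       count = count, dsize = dsize, doff_raw = doff_raw)
}

abif_entry_data <- function(raw, entry) {
  if (entry$dsize <= 4) {
    bytes <- entry$doff_raw[seq_len(entry$dsize)]
  } else {
    off <- readBin(entry$doff_raw, "integer", 1, 4, endian = "big")
    bytes <- raw[(off + 1):(off + entry$dsize)]
  }
  switch(as.character(entry$etype),
    "2" = rawToChar(bytes),                                   # char
    "18" = rawToChar(bytes[-1]),                              # pString
    "4" = readBin(bytes, "integer", entry$count, 2, endian = "big"),
    "5" = readBin(bytes, "integer", entry$count, 4, endian = "big"),
    "1" = as.integer(bytes),                                  # byte
    stop("unsupported ABIF element type: ", entry$etype)
  )
}

read_trace_ab1 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128 || rawToChar(raw[1:4]) != "ABIF")
    stop("not an ABIF file: ", path)
  con <- rawConnection(raw)
  on.exit(close(con))
  seek(con, 6)
  dir_entry <- abif_read_entry(con)  # tdir entry at fixed offset 6
  dir_off <- readBin(dir_entry$doff_raw, "integer", 1, 4, endian = "big")
  entries <- vector("list", dir_entry$count)
  seek(con, dir_off)
  for (i in seq_len(dir_entry$count)) entries[[i]] <- abif_read_entry(con)
  get_tag <- function(name, number) {
    for (e in entries)
      if (e$name == name && e$number == number) return(abif_entry_data(raw, e))
    NULL
  }
  basecalls <- get_tag("PBAS", 2)
  if (is.null(basecalls)) basecalls <- get_tag("PBAS", 1)
  ploc <- get_tag("PLOC", 2)
  if (is.null(ploc)) ploc <- get_tag("PLOC", 1)
  fwo <- get_tag("FWO_", 1)
  if (is.null(basecalls) || is.null(ploc) || is.null(fwo))
    stop("ABIF file lacks PBAS/PLOC/FWO_ records: ", path)
  channel_order <- seq_chars(fwo)
  traces <- lapply(9:12, function(i) get_tag("DATA", i))
  if (any(vapply(traces, is.null, logical(1))))
    stop("ABIF file lacks analyzed traces DATA9-12: ", path)
  calls <- seq_chars(basecalls)
  if (length(calls) != length(ploc))
    stop("ABIF PBAS and PLOC lengths differ: ", path)
  intens <- matrix(0, nrow = length(calls), ncol = 4,
                   dimnames = list(NULL, BASES))
  for (ch in seq_len(4)) {
    base <- channel_order[ch]
    intens[, base] <- traces[[ch]][ploc + 1L]  # PLOC is 0-based
  }
  trace_data(calls, intens, source_id = sub("\\.[^.]*$", "", basename(path)))
}

## --- noise, trimming, quantification -------------------------------------

#' Per-position noise fraction of a trace
#'
#' Noise at a position is the summed signal in the three channels that do
#' not correspond to the basecall, divided by the total signal across all
#' four channels (scale-invariant). An `N` call has no basecall channel and
#' returns 1 by convention.
#'
#' @param trace a [trace_data()] object.
#' @param i position index (1-based); defaults to all positions.
#' @return numeric vector of noise fractions in \[0,1\].
#' @export
position_noise <- function(trace, i = seq_along(trace$basecalls)) {
  if (length(i) == 0) return(numeric(0))
  if (any(i < 1 | i > length(trace$basecalls)))
    stop("position out of range")
  tot <- rowSums(trace$intensities[i, , drop = FALSE])
  call <- trace$basecalls[i]
  own <- numeric(length(i))
  known <- call %in% BASES
  if (any(known)) {
    idx <- cbind(seq_along(i)[known], match(call[known], BASES))
    own[known] <- trace$intensities[i, , drop = FALSE][idx]
  }
  noise <- (tot - own) / tot
  noise[!known] <- 1
  noise
}

#' Trim noisy trace ends
#'
#' Scans inward from each end and removes positions until the rolling mean
#' of [position_noise()] over `window` consecutive positions first falls
#' below `threshold`; the retained trace is the contiguous stretch between
#' the two qualifying windows. Trimming is idempotent. If no window on
#' either side qualifies the result is an empty trace flagged with
#' `attr(, "trimmed_out") = TRUE`.
#'
#' @param trace a [trace_data()] object.
#' @param threshold noise fraction in (0,1) below which a window qualifies
#'   (default 0.2).
#' @param window rolling-window width in positions (default 5).
#' @return trimmed [trace_data()] with attribute `trim` recording the
#'   number of positions removed at each end.
#' @export
trim_trace <- function(trace, threshold = 0.2, window = 5) {
  check_fraction(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  stopifnot(window >= 1)
  n <- length(trace$basecalls)
  noise <- position_noise(trace)
  if (n < window) {
    out <- trace_slice(trace, integer(0))
    attr(out, "trimmed_out") <- TRUE
    attr(out, "trim") <- c(left = n, right = 0L)
    return(out)
  }
  ## rolling means of `window` consecutive noise values, anchored at start i
  roll <- as.numeric(stats::filter(noise, rep(1 / window, window),
                                   sides = 1))
  roll <- roll[window:n]  # roll[i] = mean(noise[i:(i+window-1)])
  ok <- roll < threshold
  if (!any(ok)) {
    out <- trace_slice(trace, integer(0))
    attr(out, "trimmed_out") <- TRUE
    attr(out, "trim") <- c(left = n, right = 0L)
    return(out)
  }
  left <- which(ok)[1]                      # first qualifying window start
  right <- rev(which(ok))[1] + window - 1L  # end of last qualifying window
  out <- trace_slice(trace, left:right)
  attr(out, "trimmed_out") <- FALSE
  attr(out, "trim") <- c(left = left - 1L, right = n - right)
  out
}

#' Quantify per-position base proportions
#'
#' For each retained position, the percentage of each base is 100 times its
#' channel signal over the total channel signal, so the four percentages sum
#' to 100 at every position. The percent-T column at a reference C is the
#' standard readout of C-to-T base editing.
#'
#' @param trace a non-empty [trace_data()] object.
#' @return a `quant_table` data frame with columns `pos`, `basecall`,
#'   `pct_A`, `pct_C`, `pct_G`, `pct_T`.
#' @export
quantify_bases <- function(trace) {
  if (length(trace$basecalls) == 0) stop("empty trace")
  tot <- rowSums(trace$intensities)
  pct <- 100 * trace$intensities / tot
  out <- data.frame(pos = seq_along(trace$basecalls),
                    basecall = trace$basecalls, pct,
                    check.names = FALSE)
  names(out)[3:6] <- paste0("pct_", BASES)
  class(out) <- c("quant_table", "data.frame")
  out
}

#' Locate a spacer window in a trace
#'
#' Finds the unique best match of the spacer, or its reverse complement, in
#' the trace basecalls allowing up to `k` mismatches (edited positions in
#' the trace count as mismatches, hence the default slack of 3). Spacer
#' positions are numbered from the PAM-proximal end (position 1 = 5' end of
#' the spacer).
#'
#' @param trace a [trace_data()] object.
#' @param spacer spacer sequence, 15-23 nt.
#' @param k maximum number of mismatches tolerated (default 3).
#' @return list with `window_map` (integer vector mapping spacer position
#'   to trace index), `orientation` (`"forward"` or `"revcomp"`),
#'   `mismatches`, and `start` (trace index of the match's left end).
#' @export
align_spacer_to_trace <- function(trace, spacer, k = 3) {
  sp <- seq_chars(spacer)
  L <- length(sp)
  if (L < 15 || L > 23) stop("spacer length must be 15-23 nt")
  calls <- trace$basecalls
  n <- length(calls)
  if (n < L) stop("no spacer match within ", k, " mismatches (trace too short)")
  score_all <- function(pat) {
    m <- n - L + 1L
    mm <- integer(m)
    for (j in seq_len(L))
      mm <- mm + as.integer(calls[j:(m + j - 1L)] != pat[j])
    mm
  }
  fwd <- score_all(sp)
  rev <- score_all(seq_chars(revcomp(chars_to_seq(sp))))
  best <- min(c(fwd, rev))
  if (best > k)
    stop("no spacer match within ", k, " mismatches")
  hits_f <- which(fwd == best)
  hits_r <- which(rev == best)
  if (length(hits_f) + length(hits_r) > 1)
    stop("ambiguous spacer window: ", length(hits_f) + length(hits_r),
         " equal-score placements")
  if (length(hits_f) == 1) {
    start <- hits_f
    map <- start:(start + L - 1L)
    orientation <- "forward"
  } else {
    start <- hits_r
    map <- (start + L - 1L):start  # spacer position 1 = rightmost trace index
    orientation <- "revcomp"
  }
  list(window_map = setNames(map, seq_len(L)), orientation = orientation,
       mismatches = best, start = start)
}

#' Normalize an editing percentage against a non-targeting control
#'
#' Subtracts the control mean percent (e.g. mean %T of the non-targeting
#' gRNA condition) from the experimental mean percent. The result is not
#' clamped at zero; negative values are preserved.
#'
#' @param experimental_mean experimental mean percentage in \[0,100\].
#' @param control_mean control mean percentage in \[0,100\].
#' @return normalized percentage (may be negative).
#' @export
#' @examples
#' normalize_percent(40, 5)  # 35
normalize_percent <- function(experimental_mean, control_mean) {
  stopifnot(all(experimental_mean >= 0 & experimental_mean <= 100),
            all(control_mean >= 0 & control_mean <= 100))
  experimental_mean - control_mean
}

## --- batch processing -----------------------------------------------------

#' Quantify a batch of traces against their spacers
#'
#' Processes a batch manifest (columns `sample_id`, `path`, `condition` in
#' {`experimental`, `nt-ctrl`}, `spacer_id`): each trace is read, trimmed,
#' quantified, and its spacer window located; per-spacer-position base
#' percentages are returned in long form.
#'
#' @param manifest data frame or path to a manifest TSV.
#' @param spacers named character vector mapping spacer_id to sequence.
#' @param dialect trace file dialect (see [read_trace()]).
#' @param threshold,window trimming parameters (see [trim_trace()]).
#' @param k spacer-alignment mismatch tolerance.
#' @return data frame with columns `sample_id`, `condition`, `spacer_id`,
#'   `spacer_pos`, `trace_pos`, `basecall`, `pct_A`..`pct_T`.
#' @export
quantify_batch <- function(manifest, spacers, dialect = "tsv",
                           threshold = 0.2, window = 5, k = 3) {
  if (is.character(manifest)) manifest <- read.delim(manifest)
  need <- c("sample_id", "path", "condition", "spacer_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(manifest$condition, c("experimental", "nt-ctrl"))
  if (length(bad) > 0)
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    tr <- trim_trace(read_trace(m$path, dialect), threshold, window)
    if (isTRUE(attr(tr, "trimmed_out")))
      stop("trace entirely below quality: ", m$sample_id)
    sp <- spacers[[m$spacer_id]]
    if (is.null(sp)) stop("unknown spacer_id: ", m$spacer_id)
    q <- quantify_bases(tr)
    al <- align_spacer_to_trace(tr, sp, k)
    idx <- al$window_map
    cbind(
      data.frame(sample_id = m$sample_id, condition = m$condition,
                 spacer_id = m$spacer_id,
                 spacer_pos = as.integer(names(idx)), trace_pos = idx),
      q[idx, c("basecall", paste0("pct_", BASES))]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize batch editing percentages against the non-targeting control
#'
#' For each spacer and spacer position, the mean percentage of `base`
#' across experimental replicates and across `nt-ctrl` replicates is
#' computed; the normalized value is their difference (replicate means are
#' arithmetic means; negative values preserved).
#'
#' @param batch output of [quantify_batch()].
#' @param base channel to report (default `"T"`, the C-to-T readout).
#' @return data frame with columns `spacer_id`, `spacer_pos`,
#'   `raw_percent`, `control_percent`, `normalized_percent`.
#' @export
normalize_batch <- function(batch, base = "T") {
  stopifnot(base %in% BASES)
  col <- paste0("pct_", base)
  agg <- function(cond) {
    sub <- batch[batch$condition == cond, ]
    stats::aggregate(sub[[col]],
                     by = list(spacer_id = sub$spacer_id,
                               spacer_pos = sub$spacer_pos), FUN = mean)
  }
  if (!any(batch$condition == "nt-ctrl"))
    stop("batch contains no nt-ctrl samples")
  ex <- agg("experimental")
  ct <- agg("nt-ctrl")
  names(ex)[3] <- "raw_percent"
  names(ct)[3] <- "control_percent"
  out <- merge(ex, ct, by = c("spacer_id", "spacer_pos"))
  out$normalized_percent <- normalize_percent(out$raw_percent,
                                              out$control_percent)
  out[order(out$spacer_id, out$spacer_pos), ]
}
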