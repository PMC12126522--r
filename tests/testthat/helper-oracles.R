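## Independent oracles and fixture builders shared across tests.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc_chars <- function(chars) {
  unname(rev(c(A = "T", C = "G", G = "C", T = "A")[chars]))
}

## Exhaustive off-target enumeration by plain loops, written independently
## of the package's vectorized prefix-sum search. oracle_enumerate() lists,
## for every PAM match on either strand, the minimal mismatch count of
## every bulge class (none, DNA 1-2, RNA 1-2) over every bulge placement;
## oracle_select() then applies a (max_mm, max_bulge) budget and the
## lexicographic (bulge_size, n_mismatches, type) choice. Splitting the
## two lets one exhaustive enumeration serve the whole parameter grid.
oracle_enumerate <- function(genome, sp, pam = "TVVV", enum_b = 2,
                             seed_adj = FALSE) {
  L <- 20L
  plen <- nchar(pam)
  spc <- strsplit(sp, "")[[1]]
  iup <- list(A = "A", C = "C", G = "G", T = "T",
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  res <- list()
  for (strand in c("+", "-")) {
    s_ch <- strsplit(genome, "")[[1]]
    if (strand == "-") s_ch <- rc_chars(s_ch)
    n <- length(s_ch)
    for (p in seq_len(n - plen + 1)) {
      ok <- TRUE
      for (j in seq_len(plen))
        if (!s_ch[p + j - 1] %in% iup[[substr(pam, j, j)]]) {
          ok <- FALSE
          break
        }
      if (!ok) next
      s0 <- p + plen
      tmin <- if (seed_adj) 1L else 2L
      cands <- list()
      if (s0 + L - 1 <= n)
        cands[[length(cands) + 1]] <-
          c(0, 0, sum(s_ch[s0:(s0 + L - 1)] != spc))
      for (b in seq_len(enum_b)) {
        if (enum_b == 0) break
        if (s0 + L + b - 1 <= n) {       # DNA bulge: b extra genome nt
          best <- Inf
          for (t in tmin:(L - 1)) {
            mm <- sum(s_ch[s0:(s0 + t - 1)] != spc[1:t]) +
              sum(s_ch[(s0 + t + b):(s0 + L + b - 1)] != spc[(t + 1):L])
            best <- min(best, mm)
          }
          cands[[length(cands) + 1]] <- c(1, b, best)
        }
        if (s0 + L - b - 1 <= n && tmin <= L - 1 - b) {  # RNA bulge
          best <- Inf
          for (t in tmin:(L - 1 - b)) {
            mm <- sum(s_ch[s0:(s0 + t - 1)] != spc[1:t]) +
              sum(s_ch[(s0 + t):(s0 + L - b - 1)] != spc[(t + b + 1):L])
            best <- min(best, mm)
          }
          cands[[length(cands) + 1]] <- c(2, b, best)
        }
      }
      if (length(cands) == 0) next
      pam_start <- if (strand == "+") p - 1L else n - p - plen + 1L
      cm <- do.call(rbind, cands)
      res[[length(res) + 1]] <- data.frame(
        strand = strand, pam_start = pam_start, type = cm[, 1],
        size = cm[, 2], mm = cm[, 3])
    }
  }
  if (length(res) == 0)
    return(data.frame(strand = character(0), pam_start = integer(0),
                      type = integer(0), size = integer(0),
                      mm = integer(0)))
  do.call(rbind, res)
}

oracle_select <- function(enum, max_mm = 5, max_b = 2) {
  keep <- enum[enum$mm <= max_mm & enum$size <= max_b, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(strand = character(0), pam_start = integer(0),
                      bulge_type = character(0), bulge_size = integer(0),
                      n_mismatches = integer(0)))
  keep$key <- keep$size * 1e6 + keep$mm * 100 + keep$type
  parts <- split(keep, list(keep$strand, keep$pam_start), drop = TRUE)
  res <- do.call(rbind, lapply(parts, function(d) {
    bc <- d[which.min(d$key), ]
    data.frame(strand = bc$strand, pam_start = as.integer(bc$pam_start),
               bulge_type = c("none", "DNA", "RNA")[bc$type + 1],
               bulge_size = as.integer(bc$size),
               n_mismatches = as.integer(bc$mm))
  }))
  res <- res[order(res$pam_start, res$strand), ]
  rownames(res) <- NULL
  res
}

offtarget_oracle <- function(genome, sp, pam = "TVVV", max_mm = 5,
                             max_b = 2, seed_adj = FALSE) {
  oracle_select(oracle_enumerate(genome, sp, pam, enum_b = max_b,
                                 seed_adj = seed_adj),
                max_mm = max_mm, max_b = max_b)
}

## comparable view of find_sites output
site_key_cols <- function(f) {
  f <- f[order(f$pam_start, f$strand),
         c("strand", "pam_start", "bulge_type", "bulge_size",
           "n_mismatches")]
  rownames(f) <- NULL
  f
}

## --- minimal ABIF (.ab1) writer ------------------------------------------
## Builds a tiny valid ABIF file: PBAS2 basecalls, PLOC2 peak positions,
## FWO_1 channel order and DATA9-12 analyzed traces (one sample per call,
## so PLOC is the identity). Big-endian throughout.
write_minimal_ab1 <- function(path, basecalls, intensities,
                              channel_order = "GATC") {
  n <- length(basecalls)
  stopifnot(nrow(intensities) == n, ncol(intensities) == 4)
  intensities <- round(intensities)
  stopifnot(all(intensities >= 0), all(intensities < 32767))
  ord <- strsplit(channel_order, "")[[1]]
  entries <- list()
  blocks <- raw(0)
  data_start <- 128L
  add_entry <- function(name, number, etype, esize, count, payload) {
    dsize <- length(payload)
    if (dsize <= 4) {
      doff <- c(payload, raw(4 - dsize))
    } else {
      doff <- writeBin(as.integer(data_start + length(blocks)), raw(),
                       size = 4, endian = "big")
      blocks <<- c(blocks, payload)
    }
    entries[[length(entries) + 1]] <<- list(
      name = name, number = number, etype = etype, esize = esize,
      count = count, dsize = dsize, doff = doff)
  }
  int16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "big")
  add_entry("PBAS", 2L, 2L, 1L, n, charToRaw(paste(basecalls,
                                                   collapse = "")))
  add_entry("PLOC", 2L, 4L, 2L, n, int16_raw(seq_len(n) - 1L))
  add_entry("FWO_", 1L, 2L, 1L, 4L, charToRaw(channel_order))
  for (ch in 1:4)
    add_entry("DATA", 8L + ch, 4L, 2L, n,
              int16_raw(intensities[, ord[ch]]))
  dir_off <- data_start + length(blocks)
  ser_entry <- function(e) {
    c(charToRaw(e$name),
      writeBin(e$number, raw(), size = 4, endian = "big"),
      writeBin(e$etype, raw(), size = 2, endian = "big"),
      writeBin(e$esize, raw(), size = 2, endian = "big"),
      writeBin(as.integer(e$count), raw(), size = 4, endian = "big"),
      writeBin(as.integer(e$dsize), raw(), size = 4, endian = "big"),
      e$doff, raw(4))
  }
  tdir <- list(name = "tdir", number = 1L, etype = 1023L, esize = 28L,
               count = length(entries),
               dsize = 28L * length(entries),
               doff = writeBin(as.integer(dir_off), raw(), size = 4,
                               endian = "big"))
  out <- c(charToRaw("ABIF"),
           writeBin(101L, raw(), size = 2, endian = "big"),
           ser_entry(tdir))
  out <- c(out, raw(data_start - length(out)))
  out <- c(out, blocks)
  for (e in entries) out <- c(out, ser_entry(e))
  writeBin(out, path)
  invisible(path)
}
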