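## Off-target site search: every PAM match on either strand is tested for
## an alignment of the spacer to the downstream genome with at most one
## bulge event (DNA bulge = extra genome nt, RNA bulge = unmatched spacer
## nt) and a bounded number of substitutions. The per-PAM enumeration is
## vectorized over PAM positions via cumulative prefix-mismatch sums.

#' Find off-target sites of a spacer
#'
#' Scans both strands of a genome for PAM matches (IUPAC pattern, default
#' TVVV as used for relaxed Cas12a off-target prediction) and reports each
#' PAM whose downstream sequence aligns to the spacer with at most
#' `max_mismatches` substitutions and at most one bulge event of size
#' `<= max_bulge` (a DNA bulge inserts extra genome nucleotides between
#' two spacer positions; an RNA bulge skips spacer positions). Mixing
#' bulge types within one alignment is not allowed. For each qualifying
#' PAM the alignment minimizing `(bulge_size, n_mismatches)`
#' lexicographically (ties: no bulge < DNA < RNA) is reported.
#'
#' By default a bulge event may not involve or abut the PAM-proximal
#' first spacer position (alignment at the PAM junction is ambiguous);
#' set `allow_seed_adjacent_bulge = TRUE` to relax this by one position.
#'
#' @param genome character vector / named vector / DNAStringSet.
#' @param spacer 20-nt spacer over A,C,G,T.
#' @param pam IUPAC PAM pattern (default `"TVVV"`).
#' @param max_mismatches maximum substitutions (default 5).
#' @param max_bulge maximum bulge size, 0-2 (default 2).
#' @param allow_seed_adjacent_bulge allow a bulge event directly after
#'   spacer position 1.
#' @return data frame of sites ordered by (chrom, pam_start, strand):
#'   `chrom`, `strand`, `pam_start` (0-based leftmost plus-strand PAM
#'   coordinate), `pam`, `aligned_protospacer` (genome slice in spacer
#'   orientation; length 20 + bulge for DNA, 20 - bulge for RNA),
#'   `n_mismatches`, `bulge_type` in {none, DNA, RNA}, `bulge_size`,
#'   `window_start`, `window_end` (0-based half-open fixed 20-nt window 3'
#'   of the PAM).
#' @export
find_sites <- function(genome, spacer, pam = "TVVV", max_mismatches = 5,
                       max_bulge = 2, allow_seed_adjacent_bulge = FALSE) {
  genome <- as_named_seqs(genome)
  sp <- seq_chars(spacer)
  if (length(sp) != 20 || !all(sp %in% BASES))
    stop("spacer must be 20 nt over {A,C,G,T}")
  stopifnot(max_mismatches >= 0, max_bulge >= 0, max_bulge <= 2)
  plen <- nchar(pam)
  L <- 20L
  out <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      S <- if (strand == "+") seq_chars(genome[[chrom]])
           else revcomp_chars(seq_chars(genome[[chrom]]))
      pam_pos <- iupac_match_starts(S, pam)
      if (length(pam_pos) == 0) next
      starts <- pam_pos + plen  # spacer start, strand coordinates, 1-based
      best <- best_alignments(S, sp, starts, max_mismatches, max_bulge,
                              allow_seed_adjacent_bulge)
      keep <- which(!is.na(best$mm))
      for (ii in keep) {
        p <- pam_pos[ii]
        s <- starts[ii]
        proto_len <- L + best$shift[ii]
        proto <- chars_to_seq(S[s:(s + proto_len - 1)])
        if (strand == "+") {
          pam_start <- p - 1L
          w <- c(pam_start + plen, pam_start + plen + L)
        } else {
          pam_start <- n - p - plen + 1L
          w <- c(pam_start - L, pam_start)
        }
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom, strand = strand, pam_start = pam_start,
          pam = chars_to_seq(S[p:(p + plen - 1)]),
          aligned_protospacer = proto,
          n_mismatches = best$mm[ii], bulge_type = best$type[ii],
          bulge_size = best$size[ii],
          window_start = w[1], window_end = w[2])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), strand = character(0),
                      pam_start = integer(0), pam = character(0),
                      aligned_protospacer = character(0),
                      n_mismatches = integer(0), bulge_type = character(0),
                      bulge_size = integer(0), window_start = integer(0),
                      window_end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pam_start, res$strand), ]
  rownames(res) <- NULL
  res
}

## For each candidate spacer start, find the minimal-mismatch alignment per
## bulge class and pick the lexicographic minimum under the budgets.
## Returns per-start vectors: mm, type, size, shift (protospacer length
## change: +size for DNA, -size for RNA, 0 for none); mm is NA when no
## alignment satisfies the budgets.
best_alignments <- function(S, sp, starts, max_mm, max_bulge,
                            allow_seed_adjacent) {
  n <- length(S)
  L <- 20L
  m <- length(starts)
  t_min <- if (allow_seed_adjacent) 1L else 2L
  ## A_d[i, j]: mismatch of spacer pos j vs genome at starts[i] + d + j - 1
  mm_matrix <- function(d) {
    A <- matrix(TRUE, m, L)
    for (j in seq_len(L)) {
      idx <- starts + d + j - 1L
      okr <- idx <= n
      A[okr, j] <- S[idx[okr]] != sp[j]
    }
    A
  }
  prefix <- function(A) {
    P <- A * 1L
    for (j in 2:ncol(P)) P[, j] <- P[, j - 1L] + P[, j]
    P
  }
  valid_len <- function(extra) starts + L + extra - 1L <= n
  A0 <- mm_matrix(0L)
  P0 <- prefix(A0)
  mm0 <- P0[, L]
  mm0[!valid_len(0L)] <- NA_integer_
  cand_mm <- list(); cand_type <- character(0); cand_size <- integer(0)
  add <- function(mm, type, size) {
    cand_mm[[length(cand_mm) + 1]] <<- mm
    cand_type <<- c(cand_type, type)
    cand_size <<- c(cand_size, size)
  }
  add(mm0, "none", 0L)
  for (b in seq_len(max_bulge)) {
    ## DNA bulge: b extra genome nt between spacer positions t and t+1
    Ab <- mm_matrix(b)
    Pb <- prefix(Ab)
    ts <- t_min:(L - 1L)
    mmD <- rep(NA_integer_, m)
    okD <- valid_len(b)
    if (length(ts) > 0 && any(okD)) {
      scores <- sapply(ts, function(t) P0[, t] + (Pb[, L] - Pb[, t]))
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = m)
      mmD[okD] <- apply(scores[okD, , drop = FALSE], 1, min)
    }
    add(mmD, "DNA", b)
    ## RNA bulge: spacer positions t+1..t+b unmatched; genome is 20-b nt
    ## B[i, j] (j > b): spacer pos j vs genome at starts[i] + (j - b) - 1
    B <- matrix(0L, m, L)
    for (j in (b + 1L):L) {
      idx <- starts + (j - b) - 1L
      okr <- idx <= n
      col <- rep(TRUE, m)
      col[okr] <- S[idx[okr]] != sp[j]
      B[, j] <- col * 1L
    }
    PB <- prefix(B)
    ts <- t_min:(L - 1L - b)
    mmR <- rep(NA_integer_, m)
    okR <- valid_len(-b)
    if (length(ts) > 0 && any(okR)) {
      scores <- sapply(ts, function(t) P0[, t] + (PB[, L] - PB[, t + b]))
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = m)
      mmR[okR] <- apply(scores[okR, , drop = FALSE], 1, min)
    }
    add(mmR, "RNA", b)
  }
  ## lexicographic best: bulge size, then mismatches, then type order
  type_rank <- c(none = 0L, DNA = 1L, RNA = 2L)
  best <- list(mm = rep(NA_integer_, m), type = rep(NA_character_, m),
               size = rep(NA_integer_, m), shift = rep(NA_integer_, m))
  key_best <- rep(Inf, m)
  for (k in seq_along(cand_mm)) {
    mm <- cand_mm[[k]]
    ok <- !is.na(mm) & mm <= max_mm
    key <- cand_size[k] * 1e6 + mm * 1e2 + type_rank[[cand_type[k]]]
    upd <- ok & (key < key_best)
    if (any(upd)) {
      key_best[upd] <- key[upd]
      best$mm[upd] <- as.integer(mm[upd])
      best$type[upd] <- cand_type[k]
      best$size[upd] <- cand_size[k]
      best$shift[upd] <- switch(cand_type[k], none = 0L,
                                DNA = cand_size[k], RNA = -cand_size[k])
    }
  }
  best
}

#' Genomic window of an off-target site
#'
#' Returns the 0-based half-open interval covering exactly the 20 nt 3' of
#' the PAM on the site's strand, in plus-strand coordinates (ignoring any
#' bulge-induced protospacer length change). Windows running past a contig
#' end are clipped and flagged.
#'
#' @param pam_start 0-based leftmost plus-strand coordinate of the PAM (or
#'   a data frame of sites from [find_sites()], in which case the other
#'   arguments except `contig_len` are taken from it).
#' @param strand `"+"` or `"-"`.
#' @param pam_len PAM length in nt (default 4).
#' @param contig_len optional contig length for clipping.
#' @return data frame with `start`, `end` (0-based half-open) and
#'   `clipped`.
#' @export
site_window <- function(pam_start, strand = "+", pam_len = 4,
                        contig_len = NULL) {
  if (is.data.frame(pam_start)) {
    strand <- pam_start$strand
    pam_len <- nchar(pam_start$pam)
    pam_start <- pam_start$pam_start
  }
  L <- 20L
  start <- ifelse(strand == "+", pam_start + pam_len, pam_start - L)
  end <- start + L
  clipped <- rep(FALSE, length(start))
  under <- start < 0
  start[under] <- 0L
  clipped <- clipped | under
  if (!is.null(contig_len)) {
    over <- end > contig_len
    end[over] <- contig_len
    clipped <- clipped | over
  }
  data.frame(start = as.integer(start), end = as.integer(end),
             clipped = clipped)
}

#' Overlap predicted off-target sites with observed SNVs
#'
#' A variant matches a site when its (1-based) position, converted to
#' 0-based, lies inside the site's half-open 20-nt window; the comparison
#' is strand-agnostic. Used to ask how many de novo SNVs fall inside
#' predicted off-target windows.
#'
#' @param sites data frame from [find_sites()] (needs `chrom`,
#'   `window_start`, `window_end`).
#' @param variants data frame with `chrom` and `pos` (1-based), or a
#'   [variant_table()].
#' @return list with `pairs` (data frame of variant index/position and
#'   site index/window), `n_matched` and `n_unmatched` (variant counts).
#' @export
overlap_offtargets <- function(sites, variants) {
  if (inherits(variants, "variant_table")) variants <- variants$records
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (nrow(variants) > 0 && nrow(sites) > 0) {
    shared <- intersect(unique(sites$chrom), unique(variants$chrom))
    if (length(shared) == 0)
      stop("no shared chromosome names; sites: ",
           paste(unique(sites$chrom), collapse = ","), " variants: ",
           paste(unique(variants$chrom), collapse = ","))
  }
  if (nrow(sites) == 0 || nrow(variants) == 0) {
    return(list(pairs = data.frame(variant = integer(0), pos = integer(0),
                                   site = integer(0),
                                   window_start = integer(0),
                                   window_end = integer(0)),
                n_matched = 0L, n_unmatched = nrow(variants)))
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$window_start + 1L,
                                  end = sites$window_end))
  gr_var <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(start = variants$pos,
                                     width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_sites)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(variant = qi, pos = variants$pos[qi], site = si,
                      window_start = sites$window_start[si],
                      window_end = sites$window_end[si])
  list(pairs = pairs, n_matched = length(unique(qi)),
       n_unmatched = nrow(variants) - length(unique(qi)))
}
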