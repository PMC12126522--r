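## Cas12a spacer and crRNA array design: PAM scanning, guide truncation and
## intentional mismatches, cassette assembly in three separator
## architectures, and restriction-site validation for Golden Gate cloning.

#' Mature LbCas12a direct repeat
#'
#' The 21-nt mature LbCas12a direct repeat (DR), the default repeat placed
#' before each spacer when assembling crRNA arrays. Configurable because
#' constructs may use the full-length repeat instead.
#'
#' @return character scalar, the DR sequence (DNA alphabet).
#' @export
lb_dr <- function() "TAATTTCTACTAAGTGTAGAT"

#' Construct a Cas12a spacer
#'
#' @param sequence spacer sequence, 15-23 nt over A,C,G,T, written 5'->3'
#'   in protospacer orientation (position 1 = PAM-proximal).
#' @param id label.
#' @param chrom,strand,pam_start optional genomic anchor: sequence name,
#'   `"+"`/`"-"`, and the 0-based offset of the leftmost PAM base on the
#'   plus strand.
#' @param target_c_positions integer spacer positions (1-based,
#'   PAM-proximal = 1) of the preferred target Cs; every position must hold
#'   a C in the protospacer.
#' @return object of class `spacer`.
#' @export
spacer <- function(sequence, id = "spacer", chrom = NA_character_,
                   strand = NA_character_, pam_start = NA_integer_,
                   target_c_positions = integer(0)) {
  sequence <- toupper(sequence)
  ch <- seq_chars(sequence)
  if (length(ch) < 15 || length(ch) > 23)
    stop("spacer length must be within [15,23]")
  if (!all(ch %in% BASES)) stop("spacer must be over {A,C,G,T}")
  target_c_positions <- as.integer(sort(unique(target_c_positions)))
  if (length(target_c_positions) > 0) {
    if (any(target_c_positions < 1 | target_c_positions > length(ch)))
      stop("target_c_positions outside spacer")
    if (any(ch[target_c_positions] != "C"))
      stop("target_c_positions must reference Cs in the protospacer")
  }
  structure(
    list(id = id, sequence = sequence, chrom = chrom, strand = strand,
         pam_start = pam_start, target_c_positions = target_c_positions,
         mismatches = data.frame(position = integer(0),
                                 from = character(0), to = character(0))),
    class = "spacer"
  )
}

#' @export
print.spacer <- function(x, ...) {
  cat(sprintf("<spacer> %s %s (%d nt)", x$id, x$sequence,
              nchar(x$sequence)))
  if (!is.na(x$chrom))
    cat(sprintf(" @ %s:%d(%s)", x$chrom, x$pam_start, x$strand))
  if (length(x$target_c_positions) > 0)
    cat(" target C:", paste(x$target_c_positions, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Scan a genome for Cas12a spacer candidates
#'
#' Reports every position on both strands where the PAM pattern (IUPAC,
#' default TTTV; V = A/C/G) matches and `spacer_len` nucleotides exist 3'
#' of the PAM on that strand. Spacers are reported 5'->3' in protospacer
#' orientation. For minus-strand candidates `pam_start` is the 0-based
#' leftmost plus-strand coordinate of the PAM.
#'
#' @param genome character scalar, named character vector, or
#'   [Biostrings::DNAStringSet] of contig sequences.
#' @param pam IUPAC PAM pattern 5' of the protospacer (default `"TTTV"`).
#' @param spacer_len spacer length in nt (default 20).
#' @return data frame with columns `id`, `chrom`, `strand`, `pam_start`,
#'   `pam`, `sequence`.
#' @export
scan_candidates <- function(genome, pam = "TTTV", spacer_len = 20) {
  genome <- as_named_seqs(genome)
  stopifnot(spacer_len >= 1)
  plen <- nchar(pam)
  out <- list()
  for (chrom in names(genome)) {
    g <- seq_chars(genome[[chrom]])
    n <- length(g)
    ## plus strand: PAM at p (1-based), spacer = [p+plen, p+plen+L-1]
    for (p in iupac_match_starts(g, pam)) {
      if (p + plen + spacer_len - 1 > n) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, strand = "+", pam_start = p - 1L,
        pam = chars_to_seq(g[p:(p + plen - 1)]),
        sequence = chars_to_seq(g[(p + plen):(p + plen + spacer_len - 1)]))
    }
    ## minus strand: scan the reverse complement, map back to + coordinates
    rc <- revcomp_chars(g)
    for (p in iupac_match_starts(rc, pam)) {
      if (p + plen + spacer_len - 1 > n) next
      ## rc position q <-> + position n - q + 1; leftmost + base of PAM:
      pam_left <- n - (p + plen - 1) + 1L
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, strand = "-", pam_start = pam_left - 1L,
        pam = chars_to_seq(rc[p:(p + plen - 1)]),
        sequence = chars_to_seq(rc[(p + plen):(p + plen + spacer_len - 1)]))
    }
  }
  if (length(out) == 0)
    return(data.frame(id = character(0), chrom = character(0),
                      strand = character(0), pam_start = integer(0),
                      pam = character(0), sequence = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pam_start, res$strand), ]
  res <- cbind(id = sprintf("cand_%03d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Truncate a spacer to its PAM-proximal prefix
#'
#' Removes PAM-distal (3') nucleotides, keeping the PAM-proximal `length`
#' nt; this preserves the seed region and is the standard construction of
#' truncated Cas12a guides (default 15 nt), whose heightened mismatch
#' sensitivity suppresses bystander edits. Target-C annotations beyond the
#' new length are dropped.
#'
#' @param s a [spacer()].
#' @param length new spacer length; must be shorter than the current
#'   length and at least 14.
#' @return truncated [spacer()].
#' @export
truncate_spacer <- function(s, length = 15) {
  stopifnot(inherits(s, "spacer"))
  cur <- nchar(s$sequence)
  if (length >= cur) stop("truncation length must be < current length")
  if (length < 14) stop("truncation length must be >= 14")
  out <- spacer(substr(s$sequence, 1, length), id = s$id, chrom = s$chrom,
                strand = s$strand, pam_start = s$pam_start,
                target_c_positions =
                  s$target_c_positions[s$target_c_positions <= length])
  out$mismatches <- s$mismatches[s$mismatches$position <= length, ]
  out
}

#' Introduce an intentional mismatch into a spacer
#'
#' Substitutes a single base (e.g. replacing the main target C with a T or
#' a G) and records the introduced mismatch. A no-op substitution is
#' rejected.
#'
#' @param s a [spacer()].
#' @param position spacer position (1-based, PAM-proximal = 1).
#' @param base replacement base, one of A,C,G,T; must differ from the
#'   current base.
#' @return modified [spacer()] with the mismatch recorded in
#'   `$mismatches`.
#' @export
mismatch_variant <- function(s, position, base) {
  stopifnot(inherits(s, "spacer"))
  base <- toupper(base)
  if (!base %in% BASES) stop("base must be one of A,C,G,T")
  ch <- seq_chars(s$sequence)
  if (position < 1 || position > length(ch)) stop("position outside spacer")
  if (ch[position] == base)
    stop("replacement equals existing base (no-op forbidden)")
  from <- ch[position]
  ch[position] <- base
  out <- s
  out$sequence <- chars_to_seq(ch)
  out$target_c_positions <-
    s$target_c_positions[s$target_c_positions != position | base == "C"]
  out$mismatches <- rbind(s$mismatches,
                          data.frame(position = position, from = from,
                                     to = base))
  out
}

#' GC content of a sequence
#'
#' @param seq non-empty DNA sequence.
#' @return percent G+C, 0-100.
#' @export
#' @examples
#' gc_content("ATGC")  # 50
gc_content <- function(seq) {
  ch <- seq_chars(seq)
  if (length(ch) == 0) stop("empty sequence")
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

#' Assemble a crRNA array expression cassette
#'
#' Concatenates, for each guide in order, an optional 4-nt separator, the
#' direct repeat, and the spacer. Three architectures: `standard` (no
#' separators), `synsep_AAAT` (fixed AAAT separator upstream of each DR),
#' and `varsep` (user-supplied variable 4-nt separators, one per guide;
#' structure-guided separator design is out of scope, sequences are
#' accepted as input).
#'
#' @param spacers list of [spacer()] objects, in cassette order.
#' @param architecture `"standard"`, `"synsep_AAAT"` or `"varsep"`.
#' @param separators for `varsep` only: character vector of 4-nt A/C/G/T
#'   sequences, one per spacer.
#' @param dr direct repeat sequence (default [lb_dr()]).
#' @return object of class `guide_array` with elements `units` (per-guide
#'   list of separator/DR/spacer), `architecture`, `dr`, `cassette`
#'   (sequence) and `annotation` (1-based element intervals).
#' @export
assemble_array <- function(spacers, architecture = c("standard",
                           "synsep_AAAT", "varsep"), separators = NULL,
                           dr = lb_dr()) {
  architecture <- match.arg(architecture)
  if (inherits(spacers, "spacer")) spacers <- list(spacers)
  stopifnot(length(spacers) >= 1,
            all(vapply(spacers, inherits, logical(1), "spacer")))
  n <- length(spacers)
  if (architecture == "varsep") {
    if (is.null(separators) || length(separators) != n)
      stop("varsep requires one separator per spacer")
    separators <- toupper(separators)
    if (any(nchar(separators) != 4) ||
        !all(seq_chars(paste(separators, collapse = "")) %in% BASES))
      stop("separators must be 4-nt sequences over {A,C,G,T}")
  } else {
    if (!is.null(separators))
      stop("separators are only accepted for the varsep architecture")
    separators <- rep(switch(architecture, standard = "",
                             synsep_AAAT = "AAAT"), n)
  }
  units <- lapply(seq_len(n), function(i) {
    list(separator = separators[i], direct_repeat = dr,
         spacer = spacers[[i]])
  })
  parts <- character(0)
  ann <- list()
  pos <- 0L
  for (i in seq_len(n)) {
    for (el in c("separator", "direct_repeat", "spacer")) {
      s <- if (el == "spacer") units[[i]]$spacer$sequence else units[[i]][[el]]
      if (nchar(s) == 0) next
      ann[[length(ann) + 1]] <- data.frame(
        unit = i, element = el,
        label = if (el == "spacer") units[[i]]$spacer$id else el,
        start = pos + 1L, end = pos + nchar(s))
      parts <- c(parts, s)
      pos <- pos + nchar(s)
    }
  }
  structure(
    list(units = units, architecture = architecture, dr = dr,
         cassette = paste(parts, collapse = ""),
         annotation = do.call(rbind, ann)),
    class = "guide_array"
  )
}

#' @export
print.guide_array <- function(x, ...) {
  cat(sprintf("<guide_array> %s, %d guides, cassette %d nt\n",
              x$architecture, length(x$units), nchar(x$cassette)))
  for (u in x$units)
    cat(sprintf("  %s%s + %s\n",
                if (nchar(u$separator)) paste0(u$separator, " + ") else "",
                "DR", u$spacer$id))
  invisible(x)
}

#' Reverse the guide order of an array
#'
#' Re-assembles the cassette with the spacers in reverse order (and, for
#' `varsep`, the separators reversed in step), as used when testing whether
#' a guide's position in the array affects its editing frequency.
#'
#' @param array a [assemble_array()] result.
#' @return a new `guide_array`.
#' @export
reverse_array <- function(array) {
  stopifnot(inherits(array, "guide_array"))
  sp <- rev(lapply(array$units, `[[`, "spacer"))
  sep <- rev(vapply(array$units, `[[`, character(1), "separator"))
  if (array$architecture == "varsep")
    assemble_array(sp, "varsep", separators = sep, dr = array$dr)
  else
    assemble_array(sp, array$architecture, dr = array$dr)
}

#' Parse a cassette back into spacer sequences
#'
#' Inverse of [assemble_array()] given the known DR and architecture:
#' splits the cassette at each (separator +) DR and returns the spacer
#' sequences in order. Used to verify that assembly is lossless.
#'
#' @param cassette cassette sequence.
#' @param architecture architecture the cassette was built with.
#' @param dr direct repeat used.
#' @param sep_len separator length for `varsep` (fixed at 4).
#' @return character vector of spacer sequences in cassette order.
#' @export
parse_cassette <- function(cassette, architecture = c("standard",
                           "synsep_AAAT", "varsep"), dr = lb_dr(),
                           sep_len = 4) {
  architecture <- match.arg(architecture)
  sep_len <- switch(architecture, standard = 0L, synsep_AAAT = 4L,
                    varsep = as.integer(sep_len))
  drlen <- nchar(dr)
  starts <- c()
  p <- 1L
  while (p + drlen - 1 <= nchar(cassette)) {
    hit <- regexpr(dr, substr(cassette, p, nchar(cassette)), fixed = TRUE)
    if (hit == -1) break
    starts <- c(starts, p + as.integer(hit) - 1L)
    p <- p + as.integer(hit) + drlen - 1L
  }
  if (length(starts) == 0) stop("no DR copies found in cassette")
  ends <- c(starts[-1] - sep_len - 1L, nchar(cassette))
  vapply(seq_along(starts), function(i)
    substr(cassette, starts[i] + drlen, ends[i]), character(1))
}

#' Check a cassette for forbidden recognition sites
#'
#' Scans both strands for restriction recognition sequences that would
#' interfere with Golden Gate assembly (default BsmBI and BbsI), and
#' verifies that every DR copy in the cassette is intact.
#'
#' @param cassette cassette sequence (or a `guide_array`).
#' @param forbidden_sites named character vector of recognition sequences.
#' @param dr direct repeat expected in the cassette (set `NULL` to skip
#'   the DR integrity check).
#' @return list with `hits` (data frame: site, strand, start, end on the
#'   plus strand, 1-based) and `dr_ok` (logical; `NA` if not checked).
#' @export
validate_cassette <- function(cassette,
                              forbidden_sites = c(BsmBI = "CGTCTC",
                                                  BbsI = "GAAGAC"),
                              dr = lb_dr()) {
  arr <- NULL
  if (inherits(cassette, "guide_array")) {
    arr <- cassette
    dr <- arr$dr
    cassette <- arr$cassette
  }
  cassette <- toupper(cassette)
  hits <- list()
  scan_one <- function(site, pattern, strand) {
    m <- gregexpr(pattern, cassette, fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(site = site, strand = strand, start = as.integer(m),
               end = as.integer(m) + nchar(pattern) - 1L)
  }
  for (i in seq_along(forbidden_sites)) {
    nm <- names(forbidden_sites)[i]
    pat <- toupper(forbidden_sites[[i]])
    hits[[length(hits) + 1]] <- scan_one(nm, pat, "+")
    rc <- revcomp(pat)
    if (rc != pat)
      hits[[length(hits) + 1]] <- scan_one(nm, rc, "-")
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else NULL
  if (is.null(hits))
    hits <- data.frame(site = character(0), strand = character(0),
                       start = integer(0), end = integer(0))
  hits <- hits[order(hits$start, hits$site), ]
  rownames(hits) <- NULL
  dr_ok <- NA
  if (!is.null(dr) && !is.null(arr)) {
    drs <- arr$annotation[arr$annotation$element == "direct_repeat", ]
    dr_ok <- all(substring(cassette, drs$start, drs$end) == toupper(dr))
  } else if (!is.null(dr)) {
    dr_ok <- grepl(toupper(dr), cassette, fixed = TRUE)
  }
  list(hits = hits, dr_ok = dr_ok)
}

#' Read / write spacer tables
#'
#' Tab-separated spacer tables with columns `id`, `sequence`, `chrom`,
#' `strand`, `pam_start`, `target_c_positions` (comma-separated 1-based
#' positions, empty allowed).
#'
#' @param path TSV path.
#' @return `read_spacer_tsv`: a list of [spacer()] objects.
#' @export
read_spacer_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(target_c_positions = "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    tc <- tab$target_c_positions[i]
    tc <- if (is.na(tc) || tc == "") integer(0)
          else as.integer(strsplit(tc, ",")[[1]])
    spacer(tab$sequence[i], id = tab$id[i], chrom = tab$chrom[i],
           strand = tab$strand[i], pam_start = tab$pam_start[i],
           target_c_positions = tc)
  })
}

#' @param spacers list of [spacer()] objects.
#' @rdname read_spacer_tsv
#' @export
write_spacer_tsv <- function(spacers, path) {
  tab <- do.call(rbind, lapply(spacers, function(s) data.frame(
    id = s$id, sequence = s$sequence, chrom = s$chrom, strand = s$strand,
    pam_start = s$pam_start,
    target_c_positions = paste(s$target_c_positions, collapse = ","))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## coerce genome argument to a named character vector of contigs
as_named_seqs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) names(out) <- paste0("contig", seq_along(out))
    return(as.list(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- if (length(genome) == 1) "chr1"
                       else paste0("contig", seq_along(genome))
    return(as.list(toupper(genome)))
  }
  stop("genome must be a character vector or DNAStringSet")
}
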