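## Shared low-level helpers: sequence arithmetic, IUPAC matching, rounding.

BASES <- c("A", "C", "G", "T")

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] accepting and
#' returning plain character vectors.
#'
#' @param x character vector of DNA sequences (IUPAC letters allowed).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TTTACCG")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## split sequence into uppercase single characters
seq_chars <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

## reverse complement of a character vector of bases (fast path used in
## scanning loops; no S4 dispatch)
revcomp_chars <- function(chars) {
  unname(rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]))
}

chars_to_seq <- function(x) paste(x, collapse = "")

## does each character of `chars` match the IUPAC pattern character `pat`?
iupac_char_match <- function(chars, pat) {
  allowed <- IUPAC_MAP[[toupper(pat)]]
  if (is.null(allowed)) stop("invalid IUPAC code: ", pat)
  chars %in% allowed
}

## all start positions (1-based) where IUPAC `pattern` matches `chars`
iupac_match_starts <- function(chars, pattern) {
  pat <- seq_chars(pattern)
  k <- length(pat)
  n <- length(chars)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & iupac_char_match(chars[j:(n - k + j)], pat[j])
  }
  which(ok)
}

#' Apportion counts by largest-remainder rounding
#'
#' Distributes `total` into integer counts proportional to `freqs`
#' (Hamilton's method): floor the quotas, then hand remaining units to the
#' largest fractional remainders. Ties go to the earlier element, so the
#' result is deterministic.
#'
#' @param freqs non-negative weights; must sum to a positive value.
#' @param total integer total to distribute.
#' @return integer vector of the same length as `freqs`, summing to `total`.
#' @export
#' @examples
#' largest_remainder(c(0.7, 0.2, 0.1), 200)
largest_remainder <- function(freqs, total) {
  stopifnot(total >= 0, all(freqs >= 0), sum(freqs) > 0)
  quota <- freqs / sum(freqs) * total
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Clonal C-to-T conversion percentages by chromosome copy number
#'
#' In a clonal cell line with `ploidy` copies of the target chromosome, an
#' edit fixed on k of the copies reads out as 100*k/ploidy percent
#' conversion. Enumerates k = 1..ploidy, so for four copies a single fully
#' edited allele yields 25% and clonal outcomes range over 25-100%.
#'
#' @param ploidy number of chromosome copies (default 4, the HEK293
#'   chromosome 21 copy number).
#' @return numeric vector of attainable conversion percentages for
#'   k = 1..ploidy edited copies.
#' @export
#' @examples
#' clonal_conversion_levels(4)  # 25 50 75 100
clonal_conversion_levels <- function(ploidy = 4) {
  stopifnot(ploidy >= 1)
  100 * seq_len(ploidy) / ploidy
}

## check a scalar probability-like value
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ",", hi, "]")
  invisible(x)
}
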