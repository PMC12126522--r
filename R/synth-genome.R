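## Synthetic genomes with planted Cas12a target sites, and synthetic Sanger
## traces with known per-position base proportions and noisy ends. All
## generators are deterministic for a fixed seed and leave the caller's RNG
## state untouched.

## evaluate expr under a fixed seed without disturbing the global RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## complement lookup
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate a genome with planted Cas12a target sites
#'
#' Draws a random genome at the requested GC fraction and plants
#' `n_sites` non-overlapping target sites, each a valid TTTV PAM
#' immediately 5' of a 20-nt protospacer on a random strand (Cas12a
#' convention: PAM 5' of the protospacer on the protospacer strand). Each
#' spacer is guaranteed at least one C so that C-to-T editing outcomes can
#' be planted. Placement is retried a bounded number of times; an
#' infeasible request errors.
#'
#' @param length genome length in bp; must be at least `n_sites * 30`.
#' @param gc GC fraction in (0,1).
#' @param n_sites number of target sites to plant.
#' @param seed integer seed; identical seeds give identical output.
#' @param chrom contig name.
#' @param pam PAM pattern planted (fixed TTTV template: TTT + one of
#'   A/C/G).
#' @return list with `genome` (named character vector of one contig) and
#'   `sites` (list of `sim_site` objects: `chrom`, `pam_start` 0-based,
#'   `strand`, `spacer`, `window` 0-based half-open, `truth_alleles`).
#' @export
simulate_genome <- function(length, gc = 0.5, n_sites = 1, seed = 1,
                            chrom = "chr1", pam = "TTTV") {
  stopifnot(n_sites >= 0)
  check_fraction(gc, "gc")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0,1)")
  if (length < n_sites * 30)
    stop("infeasible: length must be >= n_sites * 30")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    g <- sample(BASES, length, replace = TRUE, prob = p[BASES])
    footprint <- 24L  # 4 nt PAM + 20 nt spacer
    placed <- integer(0)  # footprint starts (1-based)
    sites <- list()
    tries <- 0L
    while (length(sites) < n_sites) {
      tries <- tries + 1L
      if (tries > 1000L * max(1L, n_sites))
        stop("infeasible site placement after bounded retries")
      a <- sample.int(length - footprint + 1L, 1)
      if (any(abs(placed - a) < footprint)) next
      strand <- sample(c("+", "-"), 1)
      v <- sample(c("A", "C", "G"), 1)
      spacer_chars <- sample(BASES, 20, replace = TRUE, prob = p[BASES])
      if (!any(spacer_chars == "C"))
        spacer_chars[sample.int(20, 1)] <- "C"
      if (strand == "+") {
        g[a:(a + 3)] <- c("T", "T", "T", v)
        g[(a + 4):(a + 23)] <- spacer_chars
        pam_start <- a - 1L                  # 0-based leftmost PAM base
        window <- c(a + 3L, a + 23L)         # 0-based half-open
      } else {
        ## minus strand: spacer occupies the left 20 nt of the footprint in
        ## plus coordinates, PAM the right 4 nt; both reverse-complemented
        g[(a + 20):(a + 23)] <- COMP[rev(c("T", "T", "T", v))]
        g[a:(a + 19)] <- COMP[rev(spacer_chars)]
        pam_start <- a + 19L
        window <- c(a - 1L, a + 19L)
      }
      placed <- c(placed, a)
      sites[[length(sites) + 1]] <- structure(
        list(chrom = chrom, pam_start = pam_start, strand = strand,
             spacer = chars_to_seq(spacer_chars),
             window = window,
             truth_alleles = setNames(1, chars_to_seq(spacer_chars))),
        class = "sim_site")
    }
    ord <- order(vapply(sites, `[[`, integer(1), "pam_start"))
    list(genome = setNames(chars_to_seq(g), chrom), sites = sites[ord])
  })
}

#' @export
print.sim_site <- function(x, ...) {
  cat(sprintf("<sim_site> %s:%d(%s) spacer %s, %d truth allele(s)\n",
              x$chrom, x$pam_start, x$strand, x$spacer,
              length(x$truth_alleles)))
  invisible(x)
}

#' Plant an allele mixture at a simulated site
#'
#' Replaces a site's ground-truth allele table with a mixture of the
#' reference window and C-to-T edited variants at given spacer positions.
#'
#' @param site a `sim_site` from [simulate_genome()].
#' @param edits list of integer vectors; each vector gives the spacer
#'   positions (1-based, PAM-proximal = 1) converted C-to-T in one edited
#'   allele. Positions must hold a C in the spacer.
#' @param freqs intended frequencies, one per element of `edits` plus the
#'   reference; must sum to 1. Order: reference first, then `edits`.
#' @return the site with `truth_alleles` replaced.
#' @export
plant_allele_mixture <- function(site, edits, freqs) {
  stopifnot(inherits(site, "sim_site"),
            length(freqs) == length(edits) + 1)
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  ref <- seq_chars(site$spacer)
  alleles <- c(site$spacer, vapply(edits, function(pos) {
    if (any(ref[pos] != "C")) stop("edit positions must hold a C")
    a <- ref
    a[pos] <- "T"
    chars_to_seq(a)
  }, character(1)))
  if (anyDuplicated(alleles)) stop("duplicate alleles in mixture")
  site$truth_alleles <- setNames(freqs, alleles)
  site
}

#' Noise profile for synthetic traces
#'
#' Describes signal degradation of a synthetic chromatogram: `end_len`
#' positions at each trace end carry `noise_level` of their signal in
#' non-basecall channels (the noisy ends that trimming removes), while
#' interior positions carry `interior_noise`.
#'
#' @param end_len degraded positions at each end.
#' @param noise_level fraction of end-position signal in non-basecall
#'   channels, in \[0,1\].
#' @param interior_noise baseline non-basecall fraction; must be smaller
#'   than `noise_level`.
#' @return object of class `noise_profile`.
#' @export
noise_profile <- function(end_len = 8, noise_level = 0.6,
                          interior_noise = 0.05) {
  check_fraction(noise_level, "noise_level")
  check_fraction(interior_noise, "interior_noise")
  stopifnot(end_len >= 0)
  if (interior_noise >= noise_level)
    stop("interior_noise must be < noise_level")
  structure(list(end_len = as.integer(end_len), noise_level = noise_level,
                 interior_noise = interior_noise),
            class = "noise_profile")
}

#' Simulate a Sanger trace with planted base proportions
#'
#' Synthesizes per-basecall channel intensities for a template sequence.
#' At positions named in `edit_spec`, the signal is split across bases
#' according to the stated proportions (mimicking mixed peaks at edited
#' Cs); elsewhere all signal sits in the template base's channel. A
#' fraction of each position's signal (`interior_noise`, or `noise_level`
#' within `end_len` of either end) is diverted equally to the three
#' non-basecall channels, so interior basecall-channel proportions are
#' recovered exactly when `interior_noise` is zero. Per-position total
#' signal is jittered (proportion-preserving) using the seed.
#'
#' @param template template sequence.
#' @param edit_spec named list: names are 1-based template positions,
#'   values named proportion vectors over bases summing to 1.
#' @param profile a [noise_profile()].
#' @param seed integer seed.
#' @param scale nominal total signal per position.
#' @return a [trace_data()] object; basecalls are the majority channel.
#' @export
simulate_trace <- function(template, edit_spec = list(),
                           profile = noise_profile(), seed = 1,
                           scale = 1000) {
  tmpl <- seq_chars(template)
  n <- length(tmpl)
  stopifnot(n >= 1)
  pos <- as.integer(names(edit_spec))
  if (length(edit_spec) > 0 && (any(is.na(pos)) || any(pos < 1 | pos > n)))
    stop("edit_spec position outside template")
  with_seed(seed, {
    intens <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
    calls <- character(n)
    noisy_end <- rep(FALSE, n)
    if (profile$end_len > 0) {
      k <- min(profile$end_len, n)
      noisy_end[seq_len(k)] <- TRUE
      noisy_end[(n - k + 1):n] <- TRUE
    }
    for (i in seq_len(n)) {
      p <- setNames(numeric(4), BASES)
      if (i %in% pos) {
        spec <- edit_spec[[match(i, pos)]]
        if (abs(sum(spec) - 1) > 1e-9)
          stop("proportions at position ", i, " must sum to 1")
        p[names(spec)] <- spec
      } else {
        p[tmpl[i]] <- 1
      }
      call <- BASES[which.max(p)]
      if (p[tmpl[i]] == max(p)) call <- tmpl[i]  # tie goes to template
      nu <- if (noisy_end[i]) profile$noise_level else profile$interior_noise
      ch <- (1 - nu) * p
      ch[setdiff(BASES, call)] <- ch[setdiff(BASES, call)] + nu / 3
      intens[i, ] <- ch * scale * runif(1, 0.8, 1.2)
      calls[i] <- call
    }
    trace_data(calls, intens, source_id = "synthetic")
  })
}
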