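---
title: "Analysis of multiplexed Cas12a base editing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of multiplexed Cas12a base editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbetools)
```

# Scope

`mbetools` implements the computational side of a multiplexed Cas12a
cytosine base-editing (CBE) experiment: a deaminase fused to a
catalytically impaired Cas12a converts cytosines to thymines inside a
protospacer targeted through a TTTV PAM, and many loci are edited at once
by expressing guides from a crRNA array that Cas12a itself processes at
its direct repeats (DRs). The package covers four analysis stages —
chromatogram-based editing quantification, guide/array design, off-target
site search, and alignment/VCF-based outcome analysis — plus a
synthetic-data module that plants known ground truth so every stage can
be validated end to end without external data. Wet-lab steps, read
alignment and variant calling themselves (consumed as SAM/VCF), guide
efficiency scoring, and structure-guided separator design are outside its
scope.

# Chromatogram quantification

A Sanger trace is reduced to one four-channel peak-intensity tuple per
called base (`trace_data`). Editing at a reference C is read as the
percentage of T-channel signal at that position:

$$\%B_i = 100 \cdot \frac{I_{B,i}}{\sum_{b \in \{A,C,G,T\}} I_{b,i}}$$

so the four percentages sum to 100 at every position. *Noise* at a
position is the summed signal of the three non-basecall channels divided
by total signal. Dividing by the total makes the measure scale-invariant,
which matters because absolute AB1 intensities vary widely between runs;
an `N` call is defined to have noise 1.

**Trimming.** Trace ends are degraded, so positions are removed from each
end until the rolling mean of noise over `window` consecutive positions
first drops below `threshold`. Defaults are `threshold = 0.2` and
`window = 5`; both are exposed in the configuration because the procedure
is only defined up to "a set threshold" and a smoothing choice. A window
above 1 prevents a single clean (or single noisy) position from
terminating the scan; with the defaults, a lone mixed peak in otherwise
clean sequence is never treated as a trim boundary. Trimming is
idempotent, and a trace with no qualifying window anywhere is returned
empty with a flag rather than as an error, so batch runs can report the
sample instead of aborting.

**Window location and numbering.** The spacer (or its reverse complement)
is located in the trace basecalls allowing up to `k = 3` mismatches —
slack that is needed precisely because edited positions differ from the
reference. Two equal-score placements are treated as an ambiguous window
and rejected. Spacer positions are numbered from the PAM-proximal end
(position 1 is the first base 3' of the PAM), matching the C7–C12
convention for naming target cytosines.

**Normalization.** The editing readout of an experimental condition is
its mean %T minus the mean %T of the non-targeting control (`nt-ctrl`)
condition at the same spacer position; replicate means are arithmetic
means. The difference is deliberately not clamped at zero: a negative
value is informative about control noise, and flooring is left to
presentation code.

# Guide and array design

Candidate spacers are every 20-nt stretch 3' of a TTTV PAM on either
strand (`scan_candidates`); IUPAC codes are honored with V = A/C/G.
Efficiency scoring is not reimplemented — the scan is deliberately a
plain PAM enumeration.

Truncated guides (default 15 nt) keep the PAM-proximal prefix and drop
PAM-distal 3' bases. The direction is a design choice: established
truncated-Cas12a practice shortens the 3' end and preserves the
PAM-proximal seed, and this choice also keeps position numbering stable
under truncation. Intentional mismatches (`mismatch_variant`) replace a
single base — typically the main target C with T or G — and the
substitution is recorded on the object; a no-op replacement is rejected
so variant sets are always truly distinct.

Arrays are assembled as ordered units of (separator, DR, spacer) in three
architectures: `standard` (no separator), `synsep_AAAT` (fixed 4-nt AAAT
separator upstream of each DR) and `varsep` (user-supplied 4-nt
separators; sequence design for them is out of scope). The default DR is
the 21-nt mature LbCas12a repeat, kept configurable because constructs
may carry the full-length repeat. Assembly is lossless — `parse_cassette`
recovers the spacer list from the cassette — and `reverse_array`
re-assembles with guide order reversed, the manipulation used to test
position effects within an array. `validate_cassette` scans both strands
for Golden Gate recognition sites (BsmBI/BbsI by default) since a site
inside the cassette would break assembly.

# Off-target search

`find_sites` reports, for every PAM match (default pattern TVVV, the
relaxed pattern used for off-target prediction), whether the spacer
aligns to the downstream genome with at most `max_mismatches`
substitutions (default 5) and at most one bulge event of size
`max_bulge` or less (default 2). A DNA bulge inserts extra genome
nucleotides between two spacer positions; an RNA bulge leaves spacer
positions unmatched. Numerical conventions, all of which the test-suite
oracle mirrors:

* At most one bulge event per alignment; DNA and RNA bulges are never
  mixed. This matches the one-bulge semantics of standard off-target
  search tools.
* A bulge may not involve or abut spacer position 1 (configurable):
  placements at the PAM junction are ambiguous with shifting the whole
  alignment, and excluding them makes reported alignments unique.
* Per PAM, the reported alignment minimizes `(bulge_size, n_mismatches)`
  lexicographically, with ties broken none < DNA < RNA; duplicate bulge
  placements at one PAM collapse to this minimum.
* Site windows are the fixed 20 nt 3' of the PAM in genomic coordinates
  (0-based, half-open), regardless of bulge-induced protospacer length;
  windows running off a contig are clipped and flagged.

The search is vectorized over PAM positions with cumulative
prefix-mismatch sums, so a 2-kb genome scans in about 10 ms; the package
targets amplicon- and locus-scale scans, not indexed genome-scale search.
`overlap_offtargets` intersects predicted windows with SNV positions
strand-agnostically (a window is just a genomic interval) and errors when
the two inputs share no chromosome names, which almost always indicates a
naming-scheme mismatch rather than true disjointness.

# Alignment and variant analysis

**Allele outcomes.** For each target site, only reads that cover the
entire 20-nt window with mapping quality at least 35 are counted;
duplicate-marked, secondary, supplementary and unmapped records are
excluded (duplicate exclusion mirrors duplicate-marked WGS input; it is
configurable in spirit but deliberately not exposed as a flag). A read
with a deletion inside the window leaves window positions unaligned and
is excluded by the entirety rule; a read with an insertion yields a
length-mismatched allele that is reported but routed to the indel/other
class rather than classified by edited Cs. Distinct window sequences are
alleles; alleles supported by fewer than 4 reads are removed, while the
frequency denominator stays the total number of spanning, MQ-passing
reads — so reported frequencies do not renormalize when rare alleles are
dropped. Alleles are reported in spacer orientation (minus-strand windows
are reverse-complemented), so C-to-T conversions read directly as C>T.

**Classification.** An allele's edited positions are those where a
reference C became a T; a non-C>T difference is counted separately as
"other". An allele is a bystander outcome when any edited position is
not a preferred target C. A site counts as edited for a clone when the
summed frequency of its C>T-bearing alleles reaches the reporting
threshold (default 0.1); the underlying per-clone edited-site rule is not
fully determined by the source procedure, so the threshold is exposed and
the count is monotone in it. On a chromosome present in four copies, a
clonal edit fixed on k copies reads out at $100k/4$ percent, so clonal
allele frequencies fall on the 25–100% grid (`clonal_conversion_levels`).

**VCF-based frequencies and de novo filtering.** On-target allele
frequencies taken from a variant table keep records with MQ ≥ 35 and
DP ≥ 10 (both inclusive). De novo candidate SNVs are filtered in a fixed
order with per-step counts logged: (a) variants called (non-reference
genotype asserted) in *every* sample are parental and removed —
coverage alone does not count as "called"; (b) variants whose control
genotype is unknown are removed; (c) MQ ≥ 40 (inclusive); (d) DP > 10
(strict — this stage's depth bound differs deliberately from the
on-target stage's inclusive one); (e) variants inside low-complexity
regions (BED, 0-based half-open) are removed. The log conserves totals,
and the filter is invariant to input row order. Spectra are reported in
the six strand-collapsed base-change classes (G>A counts as C>T, etc.);
an APOBEC-driven CBE is expected to leave a C>T-dominated spectrum.

Coordinate conventions throughout: VCF positions 1-based, BED and all
internal intervals 0-based half-open.

# The synthetic-data module

The generators define the conditions under which the pipeline is
validated:

* `simulate_genome` plants TTTV PAM + 20-nt spacer sites on random
  strands in a random background (default GC 0.5), guaranteeing at least
  one C per spacer so editable outcomes exist. Sites never overlap;
  infeasible requests fail explicitly.
* `simulate_edited_reads` plants allele mixtures *exactly*: counts are
  `round(frequency × n_reads)` with largest-remainder correction, so
  recovery tests can assert equality rather than approximation. A
  binomial mode exists behind the `sampling` flag for stochastic tests.
  Reads either fully span the window or (for a stated fraction) are
  trimmed to partial coverage, which the spanning rule must exclude.
* `simulate_variant_tables` emulates one control plus edited clones:
  shared parental variants called everywhere, private de novo SNVs with a
  chosen class spectrum (default C>T-dominated, 8:1:1 with C>A and T>C),
  optional placement inside generated low-complexity regions and optional
  unknown control genotypes — one planted failure mode per filter step.
  Default MQ/DP ranges (40–60, 11–80) pass the filter thresholds so that
  what is planted as "de novo" is exactly what the filter should keep.
* `simulate_trace` synthesizes intensities on the per-basecall grid — one
  4-tuple per called base, not a raw oversampled electropherogram —
  because the quantification layer only ever consumes per-call peak
  values. Edited positions split signal per the planted proportions; a
  noise fraction (`interior_noise` inside, `noise_level` within
  `end_len` of the ends) is diverted equally to the three non-basecall
  channels, so planted proportions are recovered exactly at zero interior
  noise and within `interior_noise` otherwise, and trimming with a
  threshold between the two noise levels removes exactly `end_len`
  positions per end. Per-position total signal is jittered
  (proportion-preserving) so intensities are not artificially constant.

All generators are deterministic for a fixed seed and restore the
caller's RNG state.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: sequencing error and PCR chimeras, basecaller
miscalls and mobility artifacts in real chromatograms, alignment errors
around true indels, and variant-caller idiosyncrasies (the simulated
"caller" is perfectly calibrated). Exact recovery on planted data
validates the bookkeeping and boundary semantics of the pipeline, not its
robustness to instrument noise.

# Validation problem sizes

The test suite exercises the off-target search against an independently
written exhaustive enumeration on one hundred random (2-kb genome, 20-nt
spacer) pairs over the full budget grid (mismatches 0–5 × bulge 0–2),
parameter recovery on sixteen planted target sites with one hundred reads
each plus planted multi-sample variant tables, and the randomized
invariants (proportion sums, filter-count conservation, normalization
antisymmetry) on over a thousand cases. These sizes were chosen so the
whole suite runs in a couple of minutes on one core while still covering
every parameter combination the search supports.

# Known limitations

* The off-target search is exact but unindexed; genome-scale scans are
  out of scope.
* Indel outcomes from traces are not deconvolved; chromatogram analysis
  is proportion-only, with no significance model for calling an edit
  against control noise.
* `read_trace`'s AB1 reader extracts basecalls, peak locations and
  analyzed traces from the ABIF container; exotic ABIF variants (missing
  `PBAS2`/`PLOC2`, re-basecalled files) fall back to the primary tags or
  fail loudly.
* "Called in all samples" relies on the caller asserting genotypes in
  every sample; joint-called VCFs satisfy this, per-sample VCFs merged
  naively may not.
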