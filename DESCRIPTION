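Package: mbetools
Title: Analysis Tools for Multiplexed Cas12a Base Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for multiplexed Cas12a cytosine base
    editing experiments: quantification of editing from Sanger chromatograms
    with automated noisy-end trimming and non-targeting-control normalization;
    design of Cas12a spacers and crRNA array expression cassettes (standard,
    fixed AAAT separator and variable 4-nt separator architectures, truncated
    and intentionally mismatched guides); genome-wide off-target site search
    under a PAM pattern with bounded mismatches and DNA/RNA bulges; extraction
    of on-target allele outcomes from alignments; multi-sample de novo variant
    filtering and mutation-spectrum summaries. A synthetic-data module
    generates genomes, traces, aligned reads and variant tables with known
    ground truth so every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
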