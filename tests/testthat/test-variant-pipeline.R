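## helpers to build small variant tables and alignment records in code

make_vt <- function(df, samples = c("nt-ctrl", "clone1")) {
  n <- nrow(df)
  called <- do.call(rbind, df$called)
  gt_known <- if (!is.null(df$gt_known)) do.call(rbind, df$gt_known)
              else matrix(TRUE, n, length(samples))
  af <- matrix(NA_real_, n, length(samples))
  af[called] <- 0.5
  variant_table(df[c("chrom", "pos", "ref", "alt", "mq", "dp")],
                called, af, gt_known, samples)
}

vrow <- function(pos, mq = 50, dp = 20, ref = "C", alt = "T",
                 called = c(FALSE, TRUE), gt_known = c(TRUE, TRUE)) {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt, mq = mq,
             dp = dp, called = I(list(called)),
             gt_known = I(list(gt_known)))
}

srec <- function(pos, seq, cigar = paste0(nchar(seq), "M"), mapq = 60L,
                 flag = 0L, qname = "r") {
  data.frame(qname = qname, flag = flag, rname = "chr1", pos = pos,
             mapq = mapq, cigar = cigar, rnext = "*", pnext = 0L,
             tlen = 0L, seq = seq, qual = "*")
}

test_that("ontarget_vcf_frequencies applies inclusive MQ/DP bounds inside windows", {
  sites <- data.frame(chrom = "chr1", window_start = 100,
                      window_end = 120)
  df <- rbind(vrow(105, mq = 35, dp = 10),   # boundary: kept
              vrow(106, mq = 34, dp = 50),   # MQ below: dropped
              vrow(107, mq = 60, dp = 9),    # DP below: dropped
              vrow(110, mq = 50, dp = 30),   # kept
              vrow(300, mq = 60, dp = 60))   # outside window
  vt <- make_vt(df)
  out <- ontarget_vcf_frequencies(vt, sites)
  expect_equal(sort(out$pos), c(105, 110))
  expect_true(all(out$sample == "clone1"))
  expect_true(all(out$af == 0.5))
})

test_that("planted VCF allele frequencies are recovered exactly", {
  sim <- simulate_genome(500, 0.5, 2, seed = 13)
  sites <- do.call(rbind, lapply(sim$sites, function(s) data.frame(
    chrom = s$chrom, window_start = s$window[1],
    window_end = s$window[2])))
  pos <- sites$window_start[1] + 5L  # 0-based inside window -> 1-based
  df <- vrow(pos + 1L, mq = 40, dp = 25)
  vt <- make_vt(df)
  vt$af[1, "clone1"] <- 0.73
  out <- ontarget_vcf_frequencies(vt, sites)
  expect_equal(out$af, 0.73)
})

test_that("window_allele_outcomes counts spanning reads and filters support < 4", {
  ## window chr1:[100,120) 0-based; reference alleles planted directly
  site <- list(chrom = "chr1", window = c(100L, 120L), strand = "+")
  ref <- strrep("A", 20)
  a1 <- paste0(strrep("A", 10), "T", strrep("A", 9))
  a2 <- paste0("T", strrep("A", 19))
  a3 <- paste0("G", strrep("A", 19))
  reads <- do.call(rbind, c(
    lapply(1:70, function(i) srec(96, paste0("CCCCC", ref, "CCCCC"))),
    lapply(1:20, function(i) srec(96, paste0("CCCCC", a1, "CCCCC"))),
    lapply(1:7, function(i) srec(96, paste0("CCCCC", a2, "CCCCC"))),
    lapply(1:3, function(i) srec(96, paste0("CCCCC", a3, "CCCCC")))))
  o <- window_allele_outcomes(reads, site, reference_window = ref)
  expect_equal(attr(o, "total_spanning"), 100L)
  expect_equal(nrow(o), 3)               # a3 removed at support 3
  got <- setNames(o$frequency, o$window_seq)
  expect_equal(unname(got[c(ref, a1, a2)]), c(0.70, 0.20, 0.07))
  removed <- attr(o, "removed")
  expect_equal(removed$window_seq, a3)
  ## retained + removed frequencies cover every spanning read
  expect_equal(sum(o$frequency) + sum(removed$frequency), 1)

  ## support exactly 4 is retained ("< 4" rule)
  reads4 <- rbind(reads[1:70, ],
                  do.call(rbind, lapply(1:4, function(i)
                    srec(96, paste0("CCCCC", a2, "CCCCC")))))
  o4 <- window_allele_outcomes(reads4, site, reference_window = ref)
  expect_true(a2 %in% o4$window_seq)
  expect_equal(o4$support[o4$window_seq == a2], 4)
})

test_that("the entirety rule and flag/MQ exclusions are enforced", {
  site <- list(chrom = "chr1", window = c(100L, 120L), strand = "+")
  ref <- strrep("A", 20)
  span <- srec(96, paste0("CCCCC", ref, "CCCCC"))
  nineteen <- srec(102, paste0(substr(ref, 2, 20), "CCCCC"))  # misses pos 101
  lowmq <- srec(96, paste0("CCCCC", ref, "CCCCC"), mapq = 34L)
  boundary_mq <- srec(96, paste0("CCCCC", ref, "CCCCC"), mapq = 35L)
  dup <- srec(96, paste0("CCCCC", ref, "CCCCC"), flag = 1024L)
  secondary <- srec(96, paste0("CCCCC", ref, "CCCCC"), flag = 256L)
  suppl <- srec(96, paste0("CCCCC", ref, "CCCCC"), flag = 2048L)
  ## a deletion inside the window leaves positions unaligned
  del <- srec(96, paste0("CCCCC", substr(ref, 1, 18)),
              cigar = "15M2D8M")
  o <- window_allele_outcomes(
    rbind(span, nineteen, lowmq, boundary_mq, dup, secondary, suppl,
          del), site, reference_window = ref)
  expect_equal(attr(o, "total_spanning"), 2L)  # span + boundary_mq only

  ## an insertion inside the window yields an indel/other allele
  ins <- srec(96, paste0("CCCCC", substr(ref, 1, 10), "GG",
                         substr(ref, 11, 20), "CCCCC"),
              cigar = "15M2I15M")
  o2 <- window_allele_outcomes(do.call(rbind, c(
    lapply(1:5, function(i) ins), list(span))), site,
    reference_window = ref, min_support = 1)
  expect_true(any(o2$indel))
  expect_equal(nchar(o2$window_seq[o2$indel]), 22)
  expect_true(is.na(o2$n_edited_c[o2$indel]))

  ## zero spanning reads flagged, not an error
  o3 <- window_allele_outcomes(srec(500, ref), site,
                               reference_window = ref)
  expect_true(attr(o3, "zero_spanning"))
  expect_equal(nrow(o3), 0)
})

test_that("minus-strand windows are reported in spacer orientation", {
  sim <- simulate_genome(800, 0.5, 4, seed = 17)
  strands <- vapply(sim$sites, `[[`, character(1), "strand")
  expect_true(all(c("+", "-") %in% strands))  # seed chosen to cover both
  for (s in sim$sites) {
    cpos <- which(strsplit(s$spacer, "")[[1]] == "C")[1]
    sm <- plant_allele_mixture(s, list(cpos), c(0.6, 0.4))
    reads <- simulate_edited_reads(sim$genome, sm, 50, 60, seed = 2)
    o <- window_allele_outcomes(reads, sm)
    got <- setNames(o$frequency, o$window_seq)
    expect_equal(got[names(sm$truth_alleles)], sm$truth_alleles,
                 tolerance = 1e-12)
    edited <- o[o$window_seq == names(sm$truth_alleles)[2], ]
    expect_equal(edited$n_edited_c, 1L)
    expect_equal(edited$edited_positions, as.character(cpos))
  }
})

test_that("classify_outcome counts edited Cs and flags bystanders", {
  ref <- "AACAACCAACCAAACAACCA"   # Cs at 3,6,7,10,11,15,18,19
  expect_equal(classify_outcome(ref, ref)$n_edited_c, 0)
  ed10 <- sub("^(.{9})C", "\\1T", ref)
  cl <- classify_outcome(ed10, ref, target_c_positions = 10)
  expect_equal(cl$n_edited_c, 1)
  expect_equal(cl$edited_positions, 10L)
  expect_false(cl$bystander)
  ## edits at 7 and 10 with target {10}: bystander
  ed7_10 <- sub("^(.{6})C", "\\1T", ed10)
  cl2 <- classify_outcome(ed7_10, ref, target_c_positions = 10)
  expect_equal(cl2$n_edited_c, 2)
  expect_equal(cl2$edited_positions, c(7L, 10L))
  expect_true(cl2$bystander)
  ## a non-C>T difference is "other", not an edited C
  other <- sub("^(.{2})C", "\\1G", ref)
  cl3 <- classify_outcome(other, ref)
  expect_equal(cl3$n_edited_c, 0)
  expect_equal(cl3$other_positions, 3L)
  ## plus-strand sequences for a minus-strand site: G>A reads as C>T
  cl4 <- classify_outcome(revcomp(ed10), revcomp(ref),
                          target_c_positions = 10, strand = "-")
  expect_equal(cl4$n_edited_c, 1)
  expect_equal(cl4$edited_positions, 10L)
  ## length mismatch flagged indel
  expect_true(classify_outcome(paste0(ref, "A"), ref)$indel)
})

test_that("filter_denovo applies the five steps in order with exact boundaries", {
  df <- rbind(
    vrow(100, called = c(TRUE, TRUE)),                    # (a) parental
    vrow(200, gt_known = c(FALSE, TRUE)),                 # (b) ctrl unknown
    vrow(300, mq = 39),                                   # (c) MQ < 40
    vrow(400, mq = 40, dp = 10),                          # (d) DP not > 10
    vrow(500, mq = 40, dp = 11),                          # kept (boundary)
    vrow(600),                                            # in LCR
    vrow(700))                                            # kept
  vt <- make_vt(df)
  lcr <- data.frame(chrom = "chr1", start = 590, end = 610)
  fd <- filter_denovo(vt, "nt-ctrl", lcr = lcr)
  expect_equal(fd$variants$records$pos, c(500, 700))
  expect_equal(fd$log$removed, c(1L, 1L, 1L, 1L, 1L))
  expect_equal(fd$log$remaining, c(6L, 5L, 4L, 3L, 2L))
  ## conservation: removals sum to input minus output
  expect_equal(sum(fd$log$removed), nrow(vt$records) -
                 nrow(fd$variants$records))
  ## order invariance
  perm <- c(4, 1, 6, 3, 7, 2, 5)
  vt_p <- make_vt(df[perm, ])
  fd_p <- filter_denovo(vt_p, "nt-ctrl", lcr = lcr)
  expect_equal(sort(fd_p$variants$records$pos), c(500, 700))
  expect_equal(sum(fd_p$log$removed), sum(fd$log$removed))
  expect_error(filter_denovo(vt, "missing"), "control sample")
})

test_that("mutation_spectrum collapses strands and normalizes fractions", {
  df <- data.frame(ref = c("C", "C", "C", "G", "G", "T", "AT"),
                   alt = c("T", "T", "T", "A", "A", "G", "A"))
  sp <- mutation_spectrum(df)
  expect_equal(unname(sp$counts["C>T"]), 5L)
  expect_equal(unname(sp$counts["T>G"]), 1L)
  expect_equal(sp$n_non_snv, 1L)
  expect_equal(sum(sp$fractions), 1)
  empty <- mutation_spectrum(data.frame(ref = character(0),
                                        alt = character(0)))
  expect_true(all(empty$counts == 0))
  expect_equal(empty$n_snv, 0L)
})

test_that("summarize_clone thresholds edited sites monotonically", {
  mk_outcome <- function(freq_edit) {
    structure(data.frame(
      window_seq = c("REF", "EDIT"), support = c(90, 10),
      frequency = c(1 - freq_edit, freq_edit), indel = FALSE,
      n_edited_c = c(0L, 1L), edited_positions = c("", "7"),
      other_diff = FALSE, bystander = FALSE),
      class = c("allele_outcomes", "data.frame"))
  }
  all_ref <- summarize_clone(list(mk_outcome(0), mk_outcome(0)))
  expect_equal(all_ref$n_sites_edited, 0)
  ## 12 of 16 sites above the default 0.1 threshold
  freqs <- c(rep(0.4, 12), rep(0.02, 4))
  cs <- summarize_clone(lapply(freqs, mk_outcome), clone_id = "c3")
  expect_equal(cs$n_sites_edited, 12)
  for (th in c(0.01, 0.1, 0.3, 0.5)) {
    lower <- summarize_clone(lapply(freqs, mk_outcome),
                             reporting_threshold = th)$n_sites_edited
    higher <- summarize_clone(lapply(freqs, mk_outcome),
                              reporting_threshold = min(1, th + 0.2))
    expect_true(higher$n_sites_edited <= lower)
  }
})
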