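test_that("simulate_genome plants valid non-overlapping PAM+spacer sites", {
  sim <- simulate_genome(1000, gc = 0.5, n_sites = 3, seed = 1)
  g <- sim$genome[[1]]
  expect_equal(nchar(g), 1000)
  expect_length(sim$sites, 3)
  for (s in sim$sites) {
    if (s$strand == "+") {
      pam <- substr(g, s$pam_start + 1, s$pam_start + 4)
      spc <- substr(g, s$pam_start + 5, s$pam_start + 24)
    } else {
      pam <- revcomp(substr(g, s$pam_start + 1, s$pam_start + 4))
      spc <- revcomp(substr(g, s$pam_start - 19, s$pam_start))
    }
    expect_match(pam, "^TTT[ACG]$")
    expect_identical(spc, s$spacer)
    expect_true(grepl("C", s$spacer, fixed = TRUE))
    expect_equal(sum(s$truth_alleles), 1)
  }
  ## windows of distinct sites do not overlap
  w <- t(vapply(sim$sites, `[[`, integer(2), "window"))
  w <- w[order(w[, 1]), , drop = FALSE]
  if (nrow(w) > 1)
    expect_true(all(w[-1, 1] >= w[-nrow(w), 2]))
})

test_that("simulate_genome errors on infeasible requests and is deterministic", {
  expect_error(simulate_genome(60, 0.5, 3, seed = 1), "infeasible")
  expect_error(simulate_genome(1000, 1.0, 1, seed = 1), "gc")
  a <- simulate_genome(800, 0.4, 4, seed = 7)
  b <- simulate_genome(800, 0.4, 4, seed = 7)
  expect_identical(a, b)
  c <- simulate_genome(800, 0.4, 4, seed = 8)
  expect_false(identical(a$genome, c$genome))
})

test_that("simulate_edited_reads plants allele counts exactly", {
  sim <- simulate_genome(600, 0.5, 1, seed = 3)
  site <- sim$sites[[1]]
  cpos <- which(strsplit(site$spacer, "")[[1]] == "C")[1]

  ## 50/50 mixture, n = 100: exactly 50 edited reads
  s2 <- plant_allele_mixture(site, list(cpos), c(0.5, 0.5))
  reads <- simulate_edited_reads(sim$genome, s2, 100, 60, seed = 1)
  expect_identical(unname(attr(reads, "truth_counts")), c(50L, 50L))
  edited_window <- names(s2$truth_alleles)[2]
  plus_window <- if (site$strand == "-") revcomp(edited_window)
                 else edited_window
  n_edit <- sum(vapply(seq_len(nrow(reads)), function(i) {
    off <- site$window[1] + 1L - reads$pos[i]
    grepl(plus_window, reads$seq[i], fixed = TRUE) ||
      substr(reads$seq[i], off + 1, off + 20) == plus_window
  }, logical(1)))
  expect_equal(n_edit, 50)

  ## pure reference: zero non-reference windows
  ref_reads <- simulate_edited_reads(sim$genome, site, 40, 60, seed = 2)
  o <- window_allele_outcomes(ref_reads, site)
  expect_equal(nrow(o), 1)
  expect_identical(o$window_seq, site$spacer)

  ## bad frequencies rejected
  s_bad <- site
  s_bad$truth_alleles <- c(A = 0.5, B = 0.4)
  expect_error(simulate_edited_reads(sim$genome, s_bad, 10, 60, seed = 1),
               "sum to 1")
})

test_that("planted 0.7/0.2/0.1 mixture is recovered exactly by allele extraction", {
  sim <- simulate_genome(600, 0.5, 1, seed = 11)
  site <- sim$sites[[1]]
  cpos <- which(strsplit(site$spacer, "")[[1]] == "C")
  ## need two distinct edited alleles; guarantee two Cs by regenerating
  skip_if(length(cpos) < 2 && {
    sim <- simulate_genome(600, 0.45, 1, seed = 12)
    site <- sim$sites[[1]]
    cpos <- which(strsplit(site$spacer, "")[[1]] == "C")
    length(cpos) < 2
  })
  s3 <- plant_allele_mixture(site, list(cpos[1], cpos[1:2]),
                             c(0.7, 0.2, 0.1))
  reads <- simulate_edited_reads(sim$genome, s3, 200, 60, seed = 4)
  o <- window_allele_outcomes(reads, s3)
  expect_equal(attr(o, "total_spanning"), 200L)
  got <- setNames(o$frequency, o$window_seq)
  expect_equal(got[names(s3$truth_alleles)],
               s3$truth_alleles, tolerance = 1e-12)
})

test_that("partial-coverage reads are generated and excluded by the spanning rule", {
  sim <- simulate_genome(600, 0.5, 1, seed = 5)
  site <- sim$sites[[1]]
  reads <- simulate_edited_reads(sim$genome, site, 100, 60, seed = 1,
                                 partial_fraction = 0.2)
  o <- window_allele_outcomes(reads, site)
  expect_equal(attr(o, "total_spanning"), 80L)
})

test_that("SAM round-trips through text and agrees with Rsamtools", {
  sim <- simulate_genome(500, 0.5, 1, seed = 6)
  site <- sim$sites[[1]]
  reads <- simulate_edited_reads(sim$genome, site, 30, 50, seed = 9,
                                 mq_values = c(20L, 60L))
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sam, setNames(nchar(sim$genome), names(sim$genome)))
  back <- read_sam(sam)
  expect_equal(back$contigs, setNames(nchar(sim$genome),
                                      names(sim$genome)))
  ord <- order(reads$rname, reads$pos)
  expect_equal(back$records$pos, reads$pos[ord])
  expect_equal(back$records$seq, reads$seq[ord])
  expect_equal(back$records$mapq, reads$mapq[ord])

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sb <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(sort(as.integer(sb$pos)), sort(back$records$pos))
  expect_setequal(as.character(sb$seq), back$records$seq)
})

test_that("simulate_variant_tables plants recoverable truth and round-trips VCF/BED", {
  sv <- simulate_variant_tables(n_samples = 4, n_shared = 10,
                                denovo_spec = c("C>T" = 5),
                                lcr_fraction = 0, seed = 21)
  truth <- sv$truth
  expect_equal(sum(truth$kind == "shared"), 10)
  expect_equal(sum(truth$kind == "denovo"), 15)
  ## shared variants called everywhere, de novos private
  shared_idx <- which(truth$kind == "shared")
  expect_true(all(rowSums(sv$variants$called[shared_idx, , drop = FALSE])
                  == 4))
  dn_idx <- which(truth$kind == "denovo")
  expect_true(all(rowSums(sv$variants$called[dn_idx, , drop = FALSE])
                  == 1))
  fd <- filter_denovo(sv$variants, "nt-ctrl", lcr = sv$lcr)
  expect_equal(nrow(fd$variants$records), 15)
  for (cl in paste0("clone", 1:3))
    expect_equal(sum(fd$variants$called[, cl]), 5)

  ## all-C>T spec gives a pure C>T spectrum
  sp <- mutation_spectrum(fd$variants)
  expect_equal(unname(sp$fractions["C>T"]), 1)

  ## VCF / BED round trip reproduces the in-memory truth
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(sv$variants, vcf)
  vt2 <- read_vcf_table(vcf)
  expect_equal(vt2$records$pos, sv$variants$records$pos)
  expect_equal(vt2$records$ref, sv$variants$records$ref)
  expect_equal(vt2$records$mq, sv$variants$records$mq)
  expect_equal(vt2$records$dp, sv$variants$records$dp)
  expect_identical(unname(vt2$called), unname(sv$variants$called))
  expect_identical(unname(vt2$gt_known), unname(sv$variants$gt_known))
  expect_equal(unname(vt2$af[vt2$called]),
               unname(sv$variants$af[sv$variants$called]))
  bed <- tempfile(fileext = ".bed")
  write_bed(sv$lcr, bed)
  expect_equal(read_bed(bed), sv$lcr)
})

test_that("lcr_fraction = 1 sends every de novo into low-complexity regions", {
  sv <- simulate_variant_tables(n_samples = 3, n_shared = 5,
                                denovo_spec = c("C>T" = 4),
                                lcr_fraction = 1, seed = 31)
  fd <- filter_denovo(sv$variants, "nt-ctrl", lcr = sv$lcr)
  expect_equal(nrow(fd$variants$records), 0)
  expect_equal(fd$log$removed[fd$log$step == "outside_low_complexity"], 8)
})

test_that("variant table simulation is deterministic per seed", {
  a <- simulate_variant_tables(seed = 5)
  b <- simulate_variant_tables(seed = 5)
  expect_identical(a, b)
})

test_that("simulate_trace plants proportions and noisy ends as specified", {
  tmpl <- "ACGTACGTACGTACGTACGTACGTACGT"
  ## zero interior noise: interior proportions exact
  tr <- simulate_trace(tmpl, profile = noise_profile(
    end_len = 8, noise_level = 0.6, interior_noise = 0), seed = 1)
  q <- quantify_bases(tr)
  tchars <- strsplit(tmpl, "")[[1]]
  interior <- 9:(nchar(tmpl) - 8)
  for (i in interior)
    expect_equal(q[[paste0("pct_", tchars[i])]][i], 100)
  ## planted 60/40 mixture read back exactly
  tr2 <- simulate_trace(tmpl, list(`10` = c(C = 0.4, T = 0.6)),
                        noise_profile(8, 0.6, 0), seed = 2)
  q2 <- quantify_bases(tr2)
  expect_equal(q2$pct_T[10], 60)
  expect_equal(q2$pct_C[10], 40)
  ## end noise equals the profile level, interior stays below it
  noise <- position_noise(tr)
  expect_true(all(abs(noise[c(1:8, 21:28)] - 0.6) < 1e-9))
  expect_true(all(noise[interior] < 1e-9))
  expect_error(simulate_trace("ACGT", list(`9` = c(A = 1))), "outside")
  expect_identical(simulate_trace(tmpl, seed = 3),
                   simulate_trace(tmpl, seed = 3))
})
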