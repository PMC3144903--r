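ps <- probe_set()

test_that("probe set defaults carry the printed assay sequences", {
  expect_identical(ps$forward_primer, "TCTGTCCGTCCGTCCCT")
  expect_identical(ps$reverse_primer, "GCCAGATGTGCTTGTCAAAGAAG")
  expect_identical(ps$wt_probe, "TGGCCGAGCTGCAG")
  expect_identical(ps$mut_probe, "TGGCCAAGCTGCAG")
  expect_error(probe_set(wt_probe = "ACGT", mut_probe = "ACGT"), "differ")
  expect_error(probe_set(forward_primer = ""), "non-empty")
})

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("amplicon extraction is delimited by the primer pair", {
  insert <- "AAATTTCCCGGG"
  template <- paste0("GG", ps$forward_primer, insert, rc(ps$reverse_primer), "TT")
  amp <- extract_amplicon(template, ps)
  expect_identical(amp, paste0(ps$forward_primer, insert, rc(ps$reverse_primer)))

  no_rev <- paste0("GG", ps$forward_primer, insert, "TT")
  expect_true(is.na(extract_amplicon(no_rev, ps)))

  # a template supplied on the reverse strand yields the same amplicon
  expect_identical(extract_amplicon(rc(template), ps), amp)

  two_products <- paste0(template, "NNNN", template)
  expect_error(extract_amplicon(two_products, ps), "ambiguous")
})

wt_chrom <- function(insert = "ACGTACGT") {
  paste0(ps$forward_primer, insert, ps$wt_probe, insert, rc(ps$reverse_primer))
}
mut_chrom <- function(insert = "ACGTACGT") {
  paste0(ps$forward_primer, insert, ps$mut_probe, insert, rc(ps$reverse_primer))
}

test_that("allelic discrimination calls follow exact probe containment", {
  expect_identical(call_genotype(wt_chrom(), wt_chrom(), ps), "wt/wt")
  expect_identical(call_genotype(wt_chrom(), mut_chrom(), ps), "wt/mut")
  expect_identical(call_genotype(mut_chrom(), mut_chrom(), ps), "mut/mut")
  neither <- paste0(ps$forward_primer, "AAAA", rc(ps$reverse_primer))
  expect_identical(call_genotype(neither, wt_chrom(), ps), "no-call")
  both <- paste0(wt_chrom(), mut_chrom())
  expect_identical(call_genotype(both, wt_chrom(), ps), "no-call")
})

test_that("calls are symmetric in chromosome order and strand", {
  expect_identical(
    call_genotype(wt_chrom(), mut_chrom(), ps),
    call_genotype(mut_chrom(), wt_chrom(), ps)
  )
  expect_identical(call_genotype(rc(wt_chrom()), rc(mut_chrom()), ps), "wt/mut")
})

test_that("cosegregation on a perfect 47/102 cohort has concordance 1", {
  calls <- tibble::tibble(
    sample = c(sprintf("A%d", 1:47), sprintf("U%d", 1:102)),
    call = c(rep("wt/mut", 47), rep("wt/wt", 102))
  )
  status <- stats::setNames(
    rep(c("affected", "unaffected"), c(47, 102)), calls$sample
  )
  summ <- cosegregation_summary(calls, status)
  expect_identical(summ$concordance, 1)
  expect_identical(summ$n_no_call, 0L)
  counts <- summ$counts
  expect_identical(
    counts$n[counts$status == "affected" & counts$category == "carrier het"], 47L
  )
  expect_identical(
    counts$n[counts$status == "unaffected" & counts$category == "non-carrier"], 102L
  )
  expect_identical(glance(summ)$concordance, 1)
})

test_that("discordant samples and no-calls are accounted separately", {
  calls <- tibble::tibble(
    sample = sprintf("S%d", 1:10),
    call = c(rep("wt/mut", 4), "wt/wt", rep("wt/wt", 4), "no-call")
  )
  status <- stats::setNames(
    rep(c("affected", "unaffected"), each = 5), calls$sample
  )
  summ <- cosegregation_summary(calls, status)
  # sample 5 is an affected non-carrier; sample 10 is not called
  expect_equal(summ$concordance, 8 / 9)
  expect_identical(summ$n_no_call, 1L)

  empty <- cosegregation_summary(
    tibble::tibble(sample = character(), call = character()),
    character(0)
  )
  expect_true(is.na(empty$concordance))
})

test_that("assay calls reproduce true genotypes on error-free synthetic amplicons", {
  sim <- simulate_cohort(cohort_sim_spec(
    n_affected = 4, n_unaffected = 6, n_background_sites = 10, seed = 21
  ))
  chroms <- simulate_amplicons(sim$truth, ps, flank_len = 30, seed = 21)
  calls <- call_genotypes(chroms, ps)
  cs <- sim$truth$causal_site
  truth_call <- vapply(calls$sample, function(s) {
    n_mut <- sum(c(sim$truth$hap1[cs, s], sim$truth$hap2[cs, s]) ==
      sim$truth$causal_alt)
    c("wt/wt", "wt/mut", "mut/mut")[n_mut + 1]
  }, character(1))
  expect_identical(calls$call, unname(truth_call))
  # FASTA round trip preserves the calls
  fa <- withr::local_tempfile(fileext = ".fa")
  write_chromosome_fasta(chroms, fa)
  back <- read_chromosome_fasta(fa)
  back <- back[match(calls$sample, back$sample), ]
  expect_identical(call_genotypes(back, ps)$call, calls$call)
})
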