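test_that("haplotype encoding round-trips, including the empty haplotype", {
  toks <- c("31A", "C", "Del", "GGG", "10C")
  expect_identical(encode_haplotype(toks), "31A-C-Del-GGG-10C")
  expect_identical(decode_haplotype(encode_haplotype(toks)), toks)
  expect_identical(encode_haplotype(character(0)), "")
  expect_identical(decode_haplotype(""), character(0))
  withr::with_seed(3, {
    for (k in 1:10) {
      h <- sample(c("A", "C", "G", "T", "10C", "22A", "Del"), 8, replace = TRUE)
      expect_identical(decode_haplotype(encode_haplotype(h)), h)
    }
  })
})

test_that("the published five-haplotype assignment is consistent with every genotype", {
  tab <- btpkd_variants()
  phs <- btpkd_haplotypes()
  v <- check_phasing(tab, phs$diplotypes, phs$haplotypes)
  expect_identical(nrow(v), 0L)
})

test_that("a swapped assignment is caught as a violation", {
  tab <- btpkd_variants()
  phs <- btpkd_haplotypes()
  dip <- phs$diplotypes
  dip$hap1[dip$sample == "Dog3"] <- "Hap4" # Hap4 disagrees with Dog3 at many sites
  v <- check_phasing(tab, dip, phs$haplotypes)
  expect_gt(nrow(v), 0L)
  expect_true(all(v$sample == "Dog3"))
})

test_that("check_phasing validates haplotype length and labels", {
  tab <- btpkd_variants()
  phs <- btpkd_haplotypes()
  short <- phs$haplotypes
  short$Hap1 <- short$Hap1[-1]
  expect_error(check_phasing(tab, phs$diplotypes, short), "length mismatch")
  dip <- phs$diplotypes
  dip$hap2[1] <- "Hap9"
  expect_error(check_phasing(tab, dip, phs$haplotypes), "Hap9")
})

test_that("a single-site heterozygote phases trivially", {
  tab <- tiny_table(list(S1 = "A/G", S2 = "G/G"))
  v <- check_phasing(
    tab,
    tibble::tibble(sample = c("S1", "S2"), hap1 = c("ha", "hg"), hap2 = c("hg", "hg")),
    list(ha = "A", hg = "G")
  )
  expect_identical(nrow(v), 0L)
})

test_that("fully homozygous tables need one haplotype per distinct vector", {
  tab <- tiny_table(
    list(S1 = c("A/A", "G/G"), S2 = c("A/A", "G/G"), S3 = c("C/C", "G/G")),
    status = c("affected", "unaffected", "unaffected")
  )
  res <- min_parsimony_phase(tab)
  expect_identical(res$n_haplotypes, 2L)
})

test_that("the double-heterozygote toy table phases to the enumerated minimum", {
  # S1 het at both sites phases as {AA, GG} or {AG, GA}; S2 is AA/AA.
  # The two candidate solutions are {AA, GG} u {AA} (2 haplotypes) and
  # {AG, GA} u {AA} (3), so the optimum shares AA and uses 2.
  tab <- tiny_table(list(S1 = c("A/G", "A/G"), S2 = c("A/A", "A/A")))
  enumerated <- min(
    length(unique(c("AA", "GG", "AA"))),
    length(unique(c("AG", "GA", "AA")))
  )
  res <- min_parsimony_phase(tab)
  expect_identical(res$n_haplotypes, enumerated)
  expect_identical(phase_exhaustive(tab), enumerated)
  expect_identical(res$n_haplotypes, 2L)
})

test_that("parsimony output always passes check_phasing", {
  for (seed in 1:8) {
    tab <- random_snv_table(n_sites = 6, n_samples = 3, seed = seed)
    res <- min_parsimony_phase(tab)
    haps <- stats::setNames(
      lapply(res$haplotypes$haplotype, decode_haplotype),
      res$haplotypes$label
    )
    v <- check_phasing(tab, res$diplotypes, haps)
    expect_identical(nrow(v), 0L)
  }
})

test_that("branch-and-bound with collapsing matches the exhaustive oracle", {
  for (seed in 1:30) {
    n_sites <- 2 + (seed %% 5)
    n_samples <- 2 + (seed %% 3)
    tab <- random_snv_table(n_sites = n_sites, n_samples = n_samples, seed = 100 + seed)
    expect_identical(
      min_parsimony_phase(tab)$n_haplotypes,
      phase_exhaustive(tab),
      info = sprintf("seed %d", seed)
    )
  }
})

test_that("ties are broken deterministically", {
  tab <- random_snv_table(n_sites = 5, n_samples = 3, seed = 9)
  a <- min_parsimony_phase(tab)
  b <- min_parsimony_phase(tab)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$diplotypes, b$diplotypes)
})

test_that("the search-space guard trips on overly heterozygous tables", {
  hets <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  homs <- c("A/A", "C/C", "G/G", "T/T")
  # 24 pattern-distinct columns, all heterozygous in S1
  tab <- tiny_table(list(
    S1 = rep(hets, each = 4),
    S2 = rep(homs, times = 6)
  ))
  expect_error(min_parsimony_phase(tab, max_het_columns = 10), "max_het_columns")
})

test_that("tidy and glance summarize a phasing", {
  tab <- btpkd_variants()
  res <- min_parsimony_phase(tab)
  expect_identical(res$n_haplotypes, 5L)
  long <- tidy(res)
  expect_identical(nrow(long), 5L * 37L)
  expect_identical(glance(res)$n_haplotypes, 5L)
  # every affected dog carries the exon 29 A on exactly one haplotype,
  # and no unaffected chromosome carries it
  slot <- which(tab$assay_id == "ss316885563")
  hap_has_a <- stats::setNames(
    vapply(
      res$haplotypes$haplotype,
      function(h) decode_haplotype(h)[slot] == "A", logical(1)
    ),
    res$haplotypes$label
  )
  status <- vt_status(tab)
  for (i in seq_len(nrow(res$diplotypes))) {
    n_a <- sum(hap_has_a[c(res$diplotypes$hap1[i], res$diplotypes$hap2[i])])
    if (status[[res$diplotypes$sample[i]]] == "affected") {
      expect_identical(n_a, 1L)
    } else {
      expect_identical(n_a, 0L)
    }
  }
})
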