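test_that("cohort spec validation rejects impossible study designs", {
  expect_error(cohort_sim_spec(n_affected = 0), "at least one")
  expect_error(cohort_sim_spec(allele_freq = 0), "frequency")
  expect_error(cohort_sim_spec(allele_freq = 1.2), "frequency")
  expect_error(cohort_sim_spec(allele_freq = c(-1, 2)), "positive")
  expect_error(cohort_sim_spec(penetrance = 1.5), "penetrance")
  expect_error(cohort_sim_spec(genotyping_error_rate = 1), "error_rate")
})

test_that("the same seed reproduces a bit-identical cohort", {
  a <- simulate_cohort(cohort_sim_spec(seed = 42))
  b <- simulate_cohort(cohort_sim_spec(seed = 42))
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_sim_spec(seed = 43))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c$table)))
})

test_that("affected individuals are het carriers on one shared founder haplotype", {
  sim <- simulate_cohort(cohort_sim_spec(
    n_affected = 5, n_unaffected = 5, n_background_sites = 20, seed = 3
  ))
  cs <- sim$truth$causal_site
  affected <- names(sim$truth$status)[sim$truth$status == "affected"]
  for (s in affected) {
    expect_identical(unname(sim$truth$hap1[cs, s]), sim$truth$causal_alt)
    expect_identical(unname(sim$truth$hap2[cs, s]), sim$truth$causal_ref)
    # identical-by-descent background on the carrier chromosome
    expect_identical(unname(sim$truth$hap1[, s]), unname(sim$truth$founder))
  }
  unaffected <- names(sim$truth$status)[sim$truth$status == "unaffected"]
  for (s in unaffected) {
    expect_false(any(c(sim$truth$hap1[cs, s], sim$truth$hap2[cs, s]) ==
      sim$truth$causal_alt))
  }
})

test_that("no causal homozygote is ever generated with lethality enabled", {
  # 10,000 individuals across penetrance settings
  for (pen in c(1, 0.5)) {
    sim <- simulate_cohort(cohort_sim_spec(
      n_affected = 2500, n_unaffected = 2500, n_background_sites = 1,
      penetrance = pen, seed = 11
    ))
    cs <- sim$truth$causal_site
    hom <- sim$truth$hap1[cs, ] == sim$truth$causal_alt &
      sim$truth$hap2[cs, ] == sim$truth$causal_alt
    expect_identical(sum(hom), 0L)
  }
})

test_that("silent carriers appear among unaffecteds at rate 1 - penetrance", {
  sim <- simulate_cohort(cohort_sim_spec(
    n_affected = 2, n_unaffected = 400, n_background_sites = 2,
    penetrance = 0.7, seed = 19
  ))
  carriers <- sum(sim$truth$silent_carrier)
  # binomial(400, 0.3): 120 +/- 3 SE (SE ~ 9.2)
  expect_gt(carriers, 120 - 28)
  expect_lt(carriers, 120 + 28)
  # silent carriers are heterozygous for the causal allele in the table
  cs <- sim$truth$causal_site
  for (s in names(which(sim$truth$silent_carrier))) {
    g <- parse_genotype(vt_genotypes(sim$table)[cs, s])
    expect_identical(sum(g == sim$truth$causal_alt), 1L)
  }
})

test_that("genotyping errors flip alleles at roughly the stated rate", {
  rate <- 0.1
  sim0 <- simulate_cohort(cohort_sim_spec(
    n_affected = 10, n_unaffected = 10, n_background_sites = 200,
    genotyping_error_rate = 0, seed = 5
  ))
  sim1 <- simulate_cohort(cohort_sim_spec(
    n_affected = 10, n_unaffected = 10, n_background_sites = 200,
    genotyping_error_rate = rate, seed = 5
  ))
  # same seed: identical truth, errors only in the observed table
  expect_identical(sim0$truth$hap1, sim1$truth$hap1)
  g0 <- vt_genotypes(sim0$table)
  g1 <- vt_genotypes(sim1$table)
  changed <- mean(g0 != g1)
  # a cell changes unless both alleles keep their state:
  # P(change) = 1 - ((1-e)^2 + e^2 * I(het flip swaps)) ~ 2e(1-e)
  expect_gt(changed, 0.12)
  expect_lt(changed, 0.25)
})

test_that("filter sensitivity decreases as genotyping error grows", {
  rates <- c(0, 0.1, 0.3)
  sens <- vapply(rates, function(e) {
    hits <- vapply(1:150, function(k) {
      sim <- simulate_cohort(cohort_sim_spec(
        n_affected = 2, n_unaffected = 2, n_background_sites = 4,
        genotyping_error_rate = e, seed = 1000 * e + k
      ))
      cs <- sim$truth$causal_site
      st <- unname(vt_status(sim$table))
      cand <- dominant_candidate(vt_genotypes(sim$table)[cs, ], st)
      !is.na(cand) && as.character(cand) == sim$truth$causal_alt
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_identical(sens[1], 1)
  expect_true(all(diff(sens) < 0))
})

test_that("the analytic null pass rate matches its closed form", {
  expect_identical(expected_null_pass_rate(0, 2, 2), 0)
  expect_identical(expected_null_pass_rate(1, 2, 2), 0)
  expect_equal(expected_null_pass_rate(0.25, 2, 2), 0.0444946, tolerance = 1e-6)
  # brute-force check by enumerating genotype configurations
  p <- 0.3
  geno_p <- c(hom_ref = (1 - p)^2, het = 2 * p * (1 - p), hom_alt = p^2)
  total <- 0
  for (a1 in 1:3) {
    for (a2 in 1:3) {
      for (u1 in 1:3) {
        for (u2 in 1:3) {
          if (a1 == 2 && a2 == 2 && u1 == 1 && u2 == 1) {
            total <- total + geno_p[a1] * geno_p[a2] * geno_p[u1] * geno_p[u2]
          }
        }
      }
    }
  }
  expect_equal(expected_null_pass_rate(p, 2, 2), unname(total))
})

test_that("beta-distributed site frequencies stay inside (0, 1)", {
  sim <- simulate_cohort(cohort_sim_spec(
    allele_freq = c(0.5, 0.5), n_background_sites = 50, seed = 8
  ))
  expect_true(all(sim$truth$freq > 0 & sim$truth$freq < 1))
})
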