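#' Specification of a synthetic dominant-disease cohort
#'
#' Describes the statistical structure the package's analyses assume: a
#' fully (or partially) penetrant dominant causal allele carried
#' heterozygously by every affected individual on a background haplotype
#' shared identically by descent from a common founder, absent (at
#' penetrance 1) from unaffected individuals, never homozygous in live
#' animals (embryonic lethality), plus unlinked background polymorphisms
#' in Hardy-Weinberg proportions.
#'
#' @param n_affected,n_unaffected Cohort sizes (each >= 1).
#' @param n_background_sites Number of non-causal sites; the simulated
#'   table has `n_background_sites + 1` sites in total.
#' @param allele_freq Either a single frequency in (0, 1) used for every
#'   background site, or a length-2 vector `c(shape1, shape2)` of Beta
#'   parameters from which per-site frequencies are drawn.
#' @param penetrance Probability that a carrier expresses disease; at 1
#'   no unaffected individual carries the causal allele, below 1 each
#'   unaffected is a silent heterozygous carrier with probability
#'   `1 - penetrance`.
#' @param causal_on_founder_haplotype Affected carriers share one founder
#'   background haplotype on the causal chromosome.
#' @param lethal_homozygote Forbid causal-allele homozygotes (always
#'   satisfied by this generator's construction; kept as an explicit,
#'   checked invariant).
#' @param genotyping_error_rate Per-allele probability of a symmetric
#'   flip to the site's other allele, applied after truth is recorded.
#' @param seed Master seed; every stage derives its own stream from it by
#'   a fixed offset, so results are reproducible and adding a stage never
#'   perturbs earlier ones.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_affected = 2,
                            n_unaffected = 2,
                            n_background_sites = 36,
                            allele_freq = 0.25,
                            penetrance = 1,
                            causal_on_founder_haplotype = TRUE,
                            lethal_homozygote = TRUE,
                            genotyping_error_rate = 0,
                            seed = 1L) {
  if (n_affected < 1 || n_unaffected < 1) {
    stop("need at least one affected and one unaffected individual",
      call. = FALSE
    )
  }
  if (length(allele_freq) == 1) {
    if (allele_freq <= 0 || allele_freq >= 1) {
      stop("fixed allele frequency must lie in (0, 1)", call. = FALSE)
    }
  } else if (length(allele_freq) == 2) {
    if (any(allele_freq <= 0)) {
      stop("Beta shape parameters must be positive", call. = FALSE)
    }
  } else {
    stop("allele_freq must be a single frequency or Beta shape pair",
      call. = FALSE
    )
  }
  if (penetrance < 0 || penetrance > 1) {
    stop("penetrance must lie in [0, 1]", call. = FALSE)
  }
  if (genotyping_error_rate < 0 || genotyping_error_rate >= 1) {
    stop("genotyping_error_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_affected = as.integer(n_affected),
      n_unaffected = as.integer(n_unaffected),
      n_background_sites = as.integer(n_background_sites),
      allele_freq = allele_freq,
      penetrance = penetrance,
      causal_on_founder_haplotype = isTRUE(causal_on_founder_haplotype),
      lethal_homozygote = isTRUE(lethal_homozygote),
      genotyping_error_rate = genotyping_error_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_spec"
  )
}

# fixed per-stage seed offsets (see cohort_sim_spec: one master seed,
# independent streams per stage)
SIM_STAGE_OFFSETS <- c(
  sites = 101L, founder = 202L, chromosomes = 303L,
  carriers = 404L, error = 505L, amplicons = 606L
)

stage_seed <- function(spec, stage) {
  (spec$seed + SIM_STAGE_OFFSETS[[stage]]) %% .Machine$integer.max
}

#' Simulate a cohort under a dominant-disease model
#'
#' Generates a `variant_table` with `n_background_sites` unlinked
#' Hardy-Weinberg background sites plus one causal site, together with
#' the complete simulation truth (per-chromosome haplotypes, causal site
#' index and alleles, silent-carrier flags) from which every observable
#' can be recomputed.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A list with elements `table` (a `variant_table`) and `truth`
#'   (list: `causal_site`, `causal_ref`, `causal_alt`, `founder`
#'   background haplotype tokens, `hap1`/`hap2` site-by-sample token
#'   matrices before genotyping error, `silent_carrier` logical per
#'   sample).
#' @examples
#' sim <- simulate_cohort(cohort_sim_spec(seed = 7))
#' prioritize(sim$table)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  n_sites <- spec$n_background_sites + 1L
  samples <- c(
    sprintf("A%d", seq_len(spec$n_affected)),
    sprintf("U%d", seq_len(spec$n_unaffected))
  )
  status <- stats::setNames(
    rep(c("affected", "unaffected"), c(spec$n_affected, spec$n_unaffected)),
    samples
  )
  bases <- c("A", "C", "G", "T")

  site_par <- withr::with_seed(stage_seed(spec, "sites"), {
    causal_site <- sample.int(n_sites, 1)
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1)))
    freq <- if (length(spec$allele_freq) == 1) {
      rep(spec$allele_freq, n_sites)
    } else {
      stats::rbeta(n_sites, spec$allele_freq[1], spec$allele_freq[2])
    }
    # keep Beta draws off the boundary so Hardy-Weinberg stays well defined
    freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
    list(causal_site = causal_site, ref = ref, alt = alt, freq = freq)
  })
  cs <- site_par$causal_site
  bg <- setdiff(seq_len(n_sites), cs)

  founder <- withr::with_seed(stage_seed(spec, "founder"), {
    ifelse(
      stats::runif(n_sites) < site_par$freq,
      site_par$alt, site_par$ref
    )
  })
  founder[cs] <- site_par$alt[cs]

  draw <- function(n) ifelse(stats::runif(n) < site_par$freq, site_par$alt, site_par$ref)
  hap <- withr::with_seed(stage_seed(spec, "chromosomes"), {
    hap1 <- vapply(samples, function(s) draw(n_sites), character(n_sites))
    hap2 <- vapply(samples, function(s) draw(n_sites), character(n_sites))
    list(hap1 = matrix(hap1, nrow = n_sites, dimnames = list(NULL, samples)),
         hap2 = matrix(hap2, nrow = n_sites, dimnames = list(NULL, samples)))
  })
  # the causal site never segregates as background: start everyone ref/ref
  hap$hap1[cs, ] <- site_par$ref[cs]
  hap$hap2[cs, ] <- site_par$ref[cs]

  # affected carriers: causal allele on the shared founder haplotype
  for (s in samples[status == "affected"]) {
    if (spec$causal_on_founder_haplotype) {
      hap$hap1[, s] <- founder
    } else {
      hap$hap1[cs, s] <- site_par$alt[cs]
    }
  }

  silent <- withr::with_seed(stage_seed(spec, "carriers"), {
    stats::runif(spec$n_unaffected) < (1 - spec$penetrance)
  })
  silent_carrier <- stats::setNames(
    c(rep(FALSE, spec$n_affected), silent), samples
  )
  for (s in samples[silent_carrier]) {
    hap$hap1[, s] <- founder
  }

  truth <- list(
    causal_site = cs,
    causal_ref = site_par$ref[cs],
    causal_alt = site_par$alt[cs],
    ref = site_par$ref,
    alt = site_par$alt,
    freq = site_par$freq,
    founder = founder,
    hap1 = hap$hap1,
    hap2 = hap$hap2,
    silent_carrier = silent_carrier,
    status = status
  )
  if (spec$lethal_homozygote) {
    hom_causal <- hap$hap1[cs, ] == site_par$alt[cs] &
      hap$hap2[cs, ] == site_par$alt[cs]
    stopifnot(!any(hom_causal))
  }

  obs1 <- hap$hap1
  obs2 <- hap$hap2
  if (spec$genotyping_error_rate > 0) {
    flip <- function(m, flips) {
      other <- matrix(
        ifelse(m == site_par$ref, site_par$alt, site_par$ref),
        nrow = n_sites
      )
      m[flips] <- other[flips]
      m
    }
    err <- withr::with_seed(stage_seed(spec, "error"), {
      list(
        f1 = matrix(stats::runif(length(obs1)) < spec$genotyping_error_rate,
          nrow = n_sites
        ),
        f2 = matrix(stats::runif(length(obs2)) < spec$genotyping_error_rate,
          nrow = n_sites
        )
      )
    })
    obs1 <- flip(obs1, err$f1)
    obs2 <- flip(obs2, err$f2)
  }

  tab <- tibble::tibble(
    assay_id = sprintf("sim%04d", seq_len(n_sites)),
    feature = "Simulated locus",
    position = as.character(seq_len(n_sites))
  )
  tab$db_ref <- as.list(site_par$ref)
  for (s in samples) {
    tab[[s]] <- vapply(
      seq_len(n_sites),
      function(i) render_genotype(c(obs1[i, s], obs2[i, s])),
      character(1)
    )
  }
  table <- new_variant_table(tab, samples = samples, status = status)
  list(table = table, truth = truth)
}

#' Simulate assay amplicons from a cohort's truth
#'
#' Builds two chromosome sequences per sample: each embeds the wild-type
#' or mutant probe core between the printed primer pair according to the
#' chromosome's true causal allele, padded with random flanking sequence.
#' Flanks are re-drawn if they would create a spurious probe or primer
#' match, so error-free assay calls reproduce true genotypes exactly.
#'
#' @param truth The `truth` element of [simulate_cohort()].
#' @param probes A [probe_set()].
#' @param flank_len Length of the random flank on each side of the probe
#'   core (must be at least the longer primer).
#' @param seed Seed for the flank stream.
#' @return Tibble with columns `sample`, `chrom1`, `chrom2`.
#' @export
simulate_amplicons <- function(truth, probes = probe_set(), flank_len = 30,
                               seed = 1L) {
  stopifnot(inherits(probes, "probe_set"))
  if (flank_len < max(nchar(probes$forward_primer), nchar(probes$reverse_primer))) {
    stop("flank_len must be at least the primer length", call. = FALSE)
  }
  samples <- colnames(truth$hap1)
  cs <- truth$causal_site
  bases <- c("A", "C", "G", "T")
  withr::with_seed((seed + SIM_STAGE_OFFSETS[["amplicons"]]) %% .Machine$integer.max, {
    build <- function(allele) {
      core <- if (allele == truth$causal_alt) probes$mut_probe else probes$wt_probe
      other <- if (allele == truth$causal_alt) probes$wt_probe else probes$mut_probe
      repeat {
        flanks <- vapply(
          1:2,
          function(k) paste(sample(bases, flank_len, replace = TRUE), collapse = ""),
          character(1)
        )
        seq <- paste0(
          probes$forward_primer, flanks[1], core, flanks[2],
          revcomp(probes$reverse_primer)
        )
        clean <- !contains_either_strand(other, seq) &&
          length(match_all(probes$forward_primer, seq)) == 1 &&
          length(match_all(revcomp(probes$reverse_primer), seq)) == 1
        if (clean) {
          return(seq)
        }
      }
    }
    tibble::tibble(
      sample = samples,
      chrom1 = vapply(samples, function(s) build(truth$hap1[cs, s]), character(1)),
      chrom2 = vapply(samples, function(s) build(truth$hap2[cs, s]), character(1))
    )
  })
}

#' Write simulated chromosomes as FASTA
#'
#' Records are named `<sample>/1` and `<sample>/2`, the convention
#' [read_chromosome_fasta()] expects.
#'
#' @param chromosomes Tibble with `sample`, `chrom1`, `chrom2`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chromosome_fasta <- function(chromosomes, path) {
  seqs <- Biostrings::DNAStringSet(c(
    stats::setNames(chromosomes$chrom1, paste0(chromosomes$sample, "/1")),
    stats::setNames(chromosomes$chrom2, paste0(chromosomes$sample, "/2"))
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Analytic null pass rate of the dominant filter
#'
#' For a biallelic site unlinked to disease with alt-allele frequency `p`
#' under Hardy-Weinberg, the probability that the alt allele survives the
#' dominant candidate rule — heterozygous in all `n_affected` samples and
#' absent from all `n_unaffected` — is
#' `(2 p (1 - p))^n_affected * ((1 - p)^2)^n_unaffected`.
#'
#' @param p Alt allele frequency (vectorized).
#' @param n_affected,n_unaffected Cohort sizes.
#' @return Probability in `[0, 1]`.
#' @examples
#' expected_null_pass_rate(0.25, 2, 2) # 0.044495
#' @export
expected_null_pass_rate <- function(p, n_affected, n_unaffected) {
  stopifnot(all(p >= 0), all(p <= 1))
  (2 * p * (1 - p))^n_affected * ((1 - p)^2)^n_unaffected
}
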