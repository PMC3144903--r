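#' Encode and decode haplotypes
#'
#' A haplotype is an ordered vector of allele tokens, one per site of a
#' variant table, rendered as dash-joined tokens
#' (`"31A-C-A-G-..."`).
#'
#' @param tokens Character vector of allele tokens (may be empty).
#' @return `encode_haplotype()`: the dash-joined string.
#'   `decode_haplotype()`: the token vector.
#' @examples
#' encode_haplotype(c("31A", "C", "Del"))
#' decode_haplotype("31A-C-Del")
#' @export
encode_haplotype <- function(tokens) {
  if (length(tokens) == 0) {
    return("")
  }
  paste(check_allele_tokens(tokens), collapse = "-")
}

#' @rdname encode_haplotype
#' @param string A dash-joined haplotype string.
#' @export
decode_haplotype <- function(string) {
  stopifnot(length(string) == 1)
  if (!nzchar(string)) {
    return(character(0))
  }
  check_allele_tokens(strsplit(string, "-", fixed = TRUE)[[1]])
}

#' Verify a proposed phasing against a genotype table
#'
#' A diplotype (pair of haplotypes) is consistent with a sample's
#' genotypes when, at every site, the unordered pair of haplotype alleles
#' equals the genotype call. This checks a complete proposed phasing and
#' reports every violation.
#'
#' @param table A `variant_table`.
#' @param diplotypes A data frame with columns `sample`, `hap1`, `hap2`
#'   (haplotype labels).
#' @param haplotypes Named list of per-site allele token vectors (or
#'   dash-joined strings), one entry per label used in `diplotypes`.
#' @return A tibble of violations with columns `sample`, `site`,
#'   `assay_id`, `expected` (haplotype-pair union) and `observed`
#'   (genotype call); zero rows means the phasing is consistent.
#' @examples
#' tab <- btpkd_variants()
#' phs <- btpkd_haplotypes()
#' check_phasing(tab, phs$diplotypes, phs$haplotypes)
#' @export
check_phasing <- function(table, diplotypes, haplotypes) {
  validate_variant_table(table)
  haplotypes <- lapply(haplotypes, function(h) {
    if (length(h) == 1 && grepl("-", h, fixed = TRUE)) decode_haplotype(h) else h
  })
  n_sites <- nrow(table)
  bad_len <- vapply(haplotypes, length, integer(1)) != n_sites
  if (any(bad_len)) {
    stop(sprintf(
      "haplotype length mismatch (%s): table has %d sites",
      paste(names(haplotypes)[bad_len], collapse = ", "), n_sites
    ), call. = FALSE)
  }
  missing <- setdiff(c(diplotypes$hap1, diplotypes$hap2), names(haplotypes))
  if (length(missing)) {
    stop(sprintf("unknown haplotype label(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  violations <- list()
  for (k in seq_len(nrow(diplotypes))) {
    s <- diplotypes$sample[k]
    h1 <- haplotypes[[diplotypes$hap1[k]]]
    h2 <- haplotypes[[diplotypes$hap2[k]]]
    for (i in seq_len(n_sites)) {
      expected <- render_genotype(c(h1[i], h2[i]))
      observed <- table[[s]][i]
      if (expected != observed) {
        violations[[length(violations) + 1]] <- tibble::tibble(
          sample = s, site = i, assay_id = table$assay_id[i],
          expected = expected, observed = observed
        )
      }
    }
  }
  if (length(violations)) {
    dplyr::bind_rows(violations)
  } else {
    tibble::tibble(
      sample = character(), site = integer(), assay_id = character(),
      expected = character(), observed = character()
    )
  }
}

# --- minimum-haplotype parsimony search -------------------------------------

# Collapse sites with identical genotype-pattern across samples.
# Returns representative site indices and the group each site belongs to.
collapse_patterns <- function(geno_mat) {
  keys <- apply(geno_mat, 1, paste, collapse = "\t")
  groups <- match(keys, unique(keys))
  list(reps = which(!duplicated(keys)), groups = groups)
}

# All phasings of one sample over the given (collapsed) sites.
# Each phasing is a 2 x n token matrix; the first het site is pinned to
# break the within-sample chromosome symmetry.
sample_phasings <- function(calls) {
  het <- vapply(calls, function(g) g[1] != g[2], logical(1))
  k <- sum(het)
  n_opts <- if (k <= 1) 1L else 2L^(k - 1L)
  het_idx <- which(het)
  lapply(seq_len(n_opts) - 1L, function(code) {
    h1 <- vapply(calls, `[`, character(1), 1)
    h2 <- vapply(calls, `[`, character(1), 2)
    if (k > 1) {
      flips <- as.logical(bitwAnd(
        bitwShiftR(code, seq_len(k - 1L) - 1L), 1L
      ))
      for (j in which(flips)) {
        i <- het_idx[j + 1L]
        tmp <- h1[i]
        h1[i] <- h2[i]
        h2[i] <- tmp
      }
    }
    rbind(h1, h2)
  })
}

hap_key <- function(tokens) paste(tokens, collapse = "\r")

#' Minimum-haplotype parsimony phasing
#'
#' Finds a phasing of all samples' unphased genotypes that minimizes the
#' number of distinct haplotypes across all chromosomes, by
#' branch-and-bound over per-sample phasings. Sites with identical
#' genotype patterns across samples are first collapsed to one
#' representative column (the minimal count is invariant under this
#' collapsing, since identical columns can be phased identically in some
#' optimum). Ties among equally parsimonious solutions are broken by
#' lexicographic order of the sorted rendered haplotypes, so the result is
#' deterministic.
#'
#' @param table A `variant_table`.
#' @param max_het_columns Guard on the search space: maximum number of
#'   collapsed heterozygous columns allowed for any single sample.
#' @return A list of class `pkd_phasing`: `haplotypes` (tibble with
#'   `label` and dash-joined `haplotype`), `diplotypes` (tibble `sample`,
#'   `hap1`, `hap2`), and `n_haplotypes`.
#' @examples
#' phase <- min_parsimony_phase(btpkd_variants())
#' phase$n_haplotypes
#' @export
min_parsimony_phase <- function(table, max_het_columns = 24) {
  validate_variant_table(table)
  samples <- vt_samples(table)
  geno_mat <- vt_genotypes(table)
  if (nrow(geno_mat) == 0) {
    haps <- tibble::tibble(label = character(), haplotype = character())
    dip <- tibble::tibble(
      sample = samples,
      hap1 = rep(NA_character_, length(samples)),
      hap2 = rep(NA_character_, length(samples))
    )
    return(structure(list(haplotypes = haps, diplotypes = dip, n_haplotypes = 0L),
      class = "pkd_phasing"
    ))
  }
  cp <- collapse_patterns(geno_mat)
  calls_by_sample <- lapply(samples, function(s) {
    lapply(cp$reps, function(i) parse_genotype(geno_mat[i, s]))
  })
  het_counts <- vapply(calls_by_sample, function(cl) {
    sum(vapply(cl, function(g) g[1] != g[2], logical(1)))
  }, integer(1))
  if (any(het_counts > max_het_columns)) {
    stop(sprintf(
      paste0(
        "search space too large: a sample has %d heterozygous pattern ",
        "columns after collapsing (limit %d); raise max_het_columns or ",
        "reduce the table"
      ),
      max(het_counts), max_het_columns
    ), call. = FALSE)
  }

  # enumerate samples most-heterozygous first so the expensive branching
  # happens once at the root
  ord <- order(-het_counts)
  phasings <- lapply(calls_by_sample[ord], sample_phasings)
  n_samp <- length(ord)

  # intern every haplotype any option can produce: the search then works
  # on small integer-id sets instead of strings
  keys_by_depth <- lapply(phasings, function(opts) {
    vapply(opts, function(ph) c(hap_key(ph[1, ]), hap_key(ph[2, ])), character(2))
  })
  all_keys <- unique(unlist(keys_by_depth))
  ids_by_depth <- lapply(keys_by_depth, function(k) {
    matrix(match(k, all_keys), nrow = 2)
  })
  # rendered (full-length) haplotype per interned key, for tie-breaking
  rendered <- vapply(all_keys, function(key) {
    toks <- strsplit(key, "\r", fixed = TRUE)[[1]]
    encode_haplotype(toks[cp$groups])
  }, character(1), USE.NAMES = FALSE)

  best <- list(count = Inf, sorted = NULL, choice = NULL)
  consider_leaf <- function(id_set, choice) {
    count <- length(id_set)
    sorted <- sort(rendered[id_set])
    if (count < best$count ||
      (count == best$count &&
        paste(sorted, collapse = "\n") < paste(best$sorted, collapse = "\n"))) {
      best <<- list(count = count, sorted = sorted, choice = choice)
    }
  }

  # greedy descent for an initial upper bound (a real solution, so the
  # branch-and-bound starts with a tight incumbent)
  greedy_set <- integer(0)
  greedy_choice <- integer(0)
  for (d in seq_len(n_samp)) {
    sizes <- apply(ids_by_depth[[d]], 2, function(pr) {
      length(unique(c(greedy_set, pr)))
    })
    pick <- which.min(sizes)
    greedy_set <- unique(c(greedy_set, ids_by_depth[[d]][, pick]))
    greedy_choice <- c(greedy_choice, pick)
  }
  consider_leaf(greedy_set, greedy_choice)

  recurse <- function(depth, id_set, choice) {
    if (depth > n_samp) {
      consider_leaf(id_set, choice)
      return(invisible(NULL))
    }
    ids <- ids_by_depth[[depth]]
    for (opt in seq_len(ncol(ids))) {
      new_set <- unique(c(id_set, ids[, opt]))
      if (length(new_set) > best$count) next
      recurse(depth + 1, new_set, c(choice, opt))
    }
    invisible(NULL)
  }
  recurse(1, integer(0), integer(0))

  # label the winning haplotypes in their sorted rendered order
  labels <- stats::setNames(
    sprintf("H%d", seq_along(best$sorted)), best$sorted
  )
  haps <- tibble::tibble(
    label = unname(labels),
    haplotype = best$sorted
  )
  dip <- tibble::tibble(
    sample = samples[ord],
    hap1 = NA_character_, hap2 = NA_character_
  )
  for (d in seq_len(n_samp)) {
    pair <- sort(labels[rendered[ids_by_depth[[d]][, best$choice[d]]]])
    dip$hap1[d] <- pair[1]
    dip$hap2[d] <- pair[2]
  }
  dip <- dip[match(samples, dip$sample), , drop = FALSE]
  structure(
    list(
      haplotypes = haps, diplotypes = dip,
      n_haplotypes = as.integer(best$count)
    ),
    class = "pkd_phasing"
  )
}

#' Exhaustive-enumeration phasing oracle
#'
#' Enumerates every phasing of every sample without pattern collapsing or
#' pruning and returns the minimum number of distinct haplotypes. Intended
#' as an independent check of [min_parsimony_phase()] on small tables.
#'
#' @param table A `variant_table`.
#' @param max_combinations Hard cap on the enumeration size.
#' @return Integer: the minimal distinct-haplotype count.
#' @export
phase_exhaustive <- function(table, max_combinations = 2^20) {
  validate_variant_table(table)
  samples <- vt_samples(table)
  geno_mat <- vt_genotypes(table)
  calls_by_sample <- lapply(samples, function(s) {
    lapply(seq_len(nrow(geno_mat)), function(i) parse_genotype(geno_mat[i, s]))
  })
  phasings <- lapply(calls_by_sample, sample_phasings)
  sizes <- vapply(phasings, length, integer(1))
  if (prod(sizes) > max_combinations) {
    stop("exhaustive enumeration too large for this table", call. = FALSE)
  }
  grid <- expand.grid(lapply(sizes, seq_len))
  counts <- apply(grid, 1, function(idx) {
    keys <- unlist(lapply(seq_along(idx), function(d) {
      ph <- phasings[[d]][[idx[d]]]
      c(hap_key(ph[1, ]), hap_key(ph[2, ]))
    }))
    length(unique(keys))
  })
  as.integer(min(counts))
}

#' @export
print.pkd_phasing <- function(x, ...) {
  cat(sprintf(
    "<pkd_phasing> %d distinct haplotypes over %d samples\n",
    x$n_haplotypes, nrow(x$diplotypes)
  ))
  print(x$haplotypes)
  print(x$diplotypes)
  invisible(x)
}
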