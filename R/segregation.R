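#' Dominant-model candidate allele at one site
#'
#' Under a fully penetrant autosomal dominant model with no causal-allele
#' homozygotes, the disease allele must be carried in exactly one copy by
#' every affected individual and in no copy by any unaffected individual.
#' This function applies that rule to one site's genotype calls.
#'
#' @param genotypes Character vector of `"X/Y"` genotype cells, one per
#'   sample.
#' @param status Character vector (`"affected"`/`"unaffected"`) parallel to
#'   `genotypes`.
#' @return The qualifying allele token, or `NA_character_` when no allele
#'   qualifies. If several alleles qualify (possible only at sites with
#'   three or more alleles), the lexicographically smallest is returned
#'   with attribute `multi = TRUE`.
#' @examples
#' dominant_candidate(c("G/A", "G/A", "G/G", "G/G"),
#'   c("affected", "affected", "unaffected", "unaffected"))
#' @export
dominant_candidate <- function(genotypes, status) {
  check_status(genotypes, status)
  calls <- lapply(genotypes, parse_genotype)
  affected <- calls[status == "affected"]
  unaffected <- calls[status == "unaffected"]
  alleles <- sort(unique(unlist(calls)))
  qualifies <- vapply(alleles, function(a) {
    all(vapply(affected, function(g) sum(g == a) == 1, logical(1))) &&
      all(vapply(unaffected, function(g) !any(g == a), logical(1)))
  }, logical(1))
  hits <- alleles[qualifies]
  if (length(hits) == 0) {
    return(NA_character_)
  }
  structure(hits[1], multi = length(hits) > 1)
}

check_status <- function(genotypes, status) {
  if (length(status) != length(genotypes) || any(is.na(status))) {
    stop("every sample needs a status", call. = FALSE)
  }
  if (!all(status %in% c("affected", "unaffected"))) {
    stop("status labels must be 'affected' or 'unaffected'", call. = FALSE)
  }
  if (!any(status == "affected") || !any(status == "unaffected")) {
    stop("need at least one affected and one unaffected sample", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify a non-candidate site into the exclusion taxonomy
#'
#' Sites that fail [dominant_candidate()] are labelled with one of five
#' exclusion patterns describing why they are unlikely to carry a dominant
#' disease allele:
#'
#' * `P1` — all samples homozygous for one shared allele;
#' * `P2` — all samples carry the identical heterozygous genotype;
#' * `P3` — exactly one affected sample is heterozygous and every other
#'   sample is homozygous for an allele **not** among the database
#'   reference alleles (the shared allele is itself a variant);
#' * `P4` — exactly one unaffected sample is heterozygous and every other
#'   sample is homozygous for a shared allele;
#' * `P5` — exactly one affected sample is heterozygous and every other
#'   sample is homozygous for a database (wild-type) allele;
#' * `OTHER` — any remaining configuration, including the multi-candidate
#'   corner case.
#'
#' The database reference is consulted only to split `P3` from `P5`; an
#' ambiguous two-allele reference containing the shared homozygous allele
#' resolves to `P5`.
#'
#' @inheritParams dominant_candidate
#' @param db_ref Character vector of 1-2 database reference allele tokens.
#' @return A one-row tibble with columns `verdict` and `candidate_allele`.
#' @export
classify_exclusion <- function(genotypes, status, db_ref) {
  check_status(genotypes, status)
  db_ref <- check_allele_tokens(db_ref)
  calls <- lapply(genotypes, parse_genotype)
  het <- vapply(calls, function(g) g[1] != g[2], logical(1))
  hom_allele <- vapply(calls, function(g) if (g[1] == g[2]) g[1] else NA_character_,
    character(1)
  )

  cand <- dominant_candidate(genotypes, status)
  if (!is.na(cand)) {
    if (isTRUE(attr(cand, "multi"))) {
      return(tibble::tibble(verdict = "OTHER", candidate_allele = NA_character_))
    }
    return(tibble::tibble(verdict = "CANDIDATE", candidate_allele = as.character(cand)))
  }

  verdict <- if (!any(het) && length(unique(hom_allele)) == 1) {
    "P1"
  } else if (all(het) && length(unique(vapply(calls, paste, character(1),
    collapse = "/"
  ))) == 1) {
    "P2"
  } else if (sum(het) == 1 && status[het] == "affected" &&
    length(unique(hom_allele[!het])) == 1) {
    if (unique(hom_allele[!het]) %in% db_ref) "P5" else "P3"
  } else if (sum(het) == 1 && status[het] == "unaffected" &&
    length(unique(hom_allele[!het])) == 1) {
    "P4"
  } else {
    "OTHER"
  }
  tibble::tibble(verdict = verdict, candidate_allele = NA_character_)
}

#' Prioritize every site of a variant table under the dominant model
#'
#' Applies the candidate rule and the exclusion taxonomy to each site and
#' orders the result with candidate sites first (input order preserved
#' within groups).
#'
#' @param table A `variant_table`.
#' @return A tibble of class `pkd_prioritization` with columns `assay_id`,
#'   `feature`, `position`, `verdict` and `candidate_allele`, carrying a
#'   `counts` attribute (verdict tally). Use [generics::glance()] for the
#'   tally as a one-row tibble.
#' @examples
#' prioritize(btpkd_variants())
#' @export
prioritize <- function(table) {
  validate_variant_table(table)
  samples <- vt_samples(table)
  status <- unname(vt_status(table)[samples])
  if (nrow(table) == 0) {
    out <- tibble::tibble(
      assay_id = character(), feature = character(), position = character(),
      verdict = character(), candidate_allele = character()
    )
    counts <- base::table(factor(character(),
      levels = c("CANDIDATE", "P1", "P2", "P3", "P4", "P5", "OTHER")
    ))
    return(structure(out,
      counts = counts,
      class = c("pkd_prioritization", class(tibble::tibble()))
    ))
  }
  verdicts <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    genotypes <- vapply(samples, function(s) table[[s]][i], character(1))
    classify_exclusion(genotypes, status, table$db_ref[[i]])
  })
  out <- tibble::tibble(
    assay_id = table$assay_id,
    feature = table$feature,
    position = table$position,
    verdict = verdicts$verdict,
    candidate_allele = verdicts$candidate_allele
  )
  out <- out[order(out$verdict != "CANDIDATE"), , drop = FALSE]
  counts <- base::table(factor(out$verdict,
    levels = c("CANDIDATE", "P1", "P2", "P3", "P4", "P5", "OTHER")
  ))
  structure(out,
    counts = counts,
    class = c("pkd_prioritization", class(tibble::tibble()))
  )
}

#' @export
print.pkd_prioritization <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf(
    "<pkd_prioritization> %d sites: %d candidate, %d excluded\n",
    nrow(x), counts[["CANDIDATE"]], nrow(x) - counts[["CANDIDATE"]]
  ))
  NextMethod()
}
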