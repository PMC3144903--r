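#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prioritization
#'
#' @param x A `pkd_prioritization` from [prioritize()].
#' @param ... Unused.
#' @return `tidy()`: the verdict table as a plain tibble. `glance()`: a
#'   one-row tibble of per-verdict counts plus `n_sites` and
#'   `n_candidates`.
#' @export
tidy.pkd_prioritization <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c(
    "assay_id", "feature", "position", "verdict", "candidate_allele"
  )])
}

#' @rdname tidy.pkd_prioritization
#' @export
glance.pkd_prioritization <- function(x, ...) {
  counts <- attr(x, "counts")
  out <- tibble::as_tibble(as.list(counts))
  out$n_sites <- nrow(x)
  out$n_candidates <- counts[["CANDIDATE"]]
  out
}

#' Tidy a parsimony phasing
#'
#' @param x A `pkd_phasing` from [min_parsimony_phase()].
#' @param ... Unused.
#' @return `tidy()`: one row per (haplotype, site) with the carried
#'   allele. `glance()`: one row with `n_haplotypes` and `n_samples`.
#' @export
tidy.pkd_phasing <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$haplotypes)), function(i) {
    toks <- decode_haplotype(x$haplotypes$haplotype[i])
    tibble::tibble(
      label = x$haplotypes$label[i],
      site = seq_along(toks),
      allele = toks
    )
  })
}

#' @rdname tidy.pkd_phasing
#' @export
glance.pkd_phasing <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = x$n_haplotypes,
    n_samples = nrow(x$diplotypes)
  )
}

#' Tidy a cosegregation summary
#'
#' @param x A `pkd_cosegregation` from [cosegregation_summary()].
#' @param ... Unused.
#' @return `tidy()`: the status-by-category count table. `glance()`: one
#'   row with `concordance` and `n_no_call`.
#' @export
tidy.pkd_cosegregation <- function(x, ...) {
  x$counts
}

#' @rdname tidy.pkd_cosegregation
#' @export
glance.pkd_cosegregation <- function(x, ...) {
  tibble::tibble(concordance = x$concordance, n_no_call = x$n_no_call)
}
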