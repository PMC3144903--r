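#' Allelic-discrimination probe set
#'
#' Bundles the two PCR primers and the two allele-discriminating probes of
#' a TaqMan-style genotyping assay. The default sequences are the
#' published BTPKD assay: the wild-type (G) and mutant (A) probes differ
#' at the single base of the exon 29 substitution (GAG vs AAG codon
#' context).
#'
#' @param forward_primer,reverse_primer PCR primer sequences (5'->3', the
#'   reverse primer on the opposite strand).
#' @param wt_probe,mut_probe Probe sequences matching the wild-type and
#'   mutant allele.
#' @param wt_allele,mut_allele Allele tokens the probes report.
#' @return A list of class `probe_set`.
#' @examples
#' probe_set()
#' @export
probe_set <- function(forward_primer = "TCTGTCCGTCCGTCCCT",
                      reverse_primer = "GCCAGATGTGCTTGTCAAAGAAG",
                      wt_probe = "TGGCCGAGCTGCAG",
                      mut_probe = "TGGCCAAGCTGCAG",
                      wt_allele = "G",
                      mut_allele = "A") {
  seqs <- c(forward_primer, reverse_primer, wt_probe, mut_probe)
  if (any(!nzchar(seqs)) || any(!grepl("^[ACGT]+$", seqs))) {
    stop("primers and probes must be non-empty A/C/G/T strings", call. = FALSE)
  }
  if (wt_probe == mut_probe) {
    stop("the two probes must differ at >= 1 position", call. = FALSE)
  }
  structure(
    list(
      forward_primer = forward_primer, reverse_primer = reverse_primer,
      wt_probe = wt_probe, mut_probe = mut_probe,
      wt_allele = wt_allele, mut_allele = mut_allele
    ),
    class = "probe_set"
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all start positions of fixed pattern in subject
match_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  m[m > 0]
}

contains_either_strand <- function(pattern, subject) {
  grepl(pattern, subject, fixed = TRUE) ||
    grepl(revcomp(pattern), subject, fixed = TRUE)
}

#' Extract the in-silico PCR amplicon from a template
#'
#' Models PCR delimitation by the primer pair: the amplicon runs from a
#' forward-primer match through the reverse complement of the reverse
#' primer, inclusive. Both strands of the template are searched; a
#' template carried on the reverse strand yields the same amplicon as its
#' forward-strand complement.
#'
#' @param seq Template nucleotide string.
#' @param probes A [probe_set()].
#' @return The amplicon string, or `NA_character_` when either primer site
#'   is absent or the sites are not properly ordered. Multiple distinct
#'   candidate amplicons raise an error (ambiguous template).
#' @export
extract_amplicon <- function(seq, probes) {
  stopifnot(inherits(probes, "probe_set"))
  fwd <- probes$forward_primer
  rev_site <- revcomp(probes$reverse_primer)
  amplicons <- character(0)
  for (strand in unique(c(toupper(seq), revcomp(toupper(seq))))) {
    starts <- match_all(fwd, strand)
    ends <- match_all(rev_site, strand)
    for (s in starts) {
      for (e in ends) {
        stop_at <- e + nchar(rev_site) - 1
        if (s < e) {
          amplicons <- c(amplicons, substr(strand, s, stop_at))
        }
      }
    }
  }
  amplicons <- unique(amplicons)
  if (length(amplicons) == 0) {
    return(NA_character_)
  }
  if (length(amplicons) > 1) {
    stop("ambiguous template: multiple candidate amplicons", call. = FALSE)
  }
  amplicons
}

# per-chromosome probe state: "wt", "mut" or "ambiguous"
chromosome_state <- function(seq, probes) {
  seq <- toupper(seq)
  wt_hit <- contains_either_strand(probes$wt_probe, seq)
  mut_hit <- contains_either_strand(probes$mut_probe, seq)
  if (wt_hit && !mut_hit) {
    "wt"
  } else if (mut_hit && !wt_hit) {
    "mut"
  } else {
    "ambiguous"
  }
}

#' Genotype a chromosome pair by in-silico allelic discrimination
#'
#' Each chromosome is probed by exact string containment of the wild-type
#' and mutant probe on either strand — the computational analogue of
#' competitive probe hybridization. A chromosome matched by exactly one
#' probe is called for that allele; a chromosome matching both or neither
#' probe is ambiguous and forces a no-call for the sample. The call is
#' symmetric in chromosome order and strand.
#'
#' @param chrom1,chrom2 The sample's two chromosome sequences.
#' @param probes A [probe_set()].
#' @return One of `"wt/wt"`, `"wt/mut"`, `"mut/mut"`, `"no-call"`.
#' @examples
#' ps <- probe_set()
#' call_genotype(ps$wt_probe, ps$mut_probe, ps) # "wt/mut"
#' @export
call_genotype <- function(chrom1, chrom2, probes) {
  stopifnot(inherits(probes, "probe_set"))
  states <- c(chromosome_state(chrom1, probes), chromosome_state(chrom2, probes))
  if (any(states == "ambiguous")) {
    return("no-call")
  }
  paste(sort(states, decreasing = TRUE), collapse = "/") # wt sorts after mut
}

#' Genotype a cohort of chromosome sequences
#'
#' @param chromosomes A data frame with columns `sample`, `chrom1`,
#'   `chrom2` (e.g. from [read_chromosome_fasta()] or
#'   [simulate_amplicons()]).
#' @param probes A [probe_set()].
#' @return Tibble with columns `sample` and `call`.
#' @export
call_genotypes <- function(chromosomes, probes = probe_set()) {
  tibble::tibble(
    sample = chromosomes$sample,
    call = vapply(
      seq_len(nrow(chromosomes)),
      function(i) call_genotype(chromosomes$chrom1[i], chromosomes$chrom2[i], probes),
      character(1)
    )
  )
}

#' Read two-records-per-sample chromosome FASTA
#'
#' Expects records named `<sample>/1` and `<sample>/2`.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `sample`, `chrom1`, `chrom2`.
#' @export
read_chromosome_fasta <- function(path) {
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  ids <- names(seqs)
  ok <- grepl("/[12]$", ids)
  if (!all(ok)) {
    stop("records must be named <sample>/1 and <sample>/2", call. = FALSE)
  }
  sample <- sub("/[12]$", "", ids)
  which_chrom <- sub("^.*/", "", ids)
  wide <- tibble::tibble(sample = sample, chrom = which_chrom, seq = unname(seqs))
  out <- tidyr::pivot_wider(wide,
    names_from = "chrom", values_from = "seq",
    names_prefix = "chrom"
  )
  if (anyNA(out$chrom1) || anyNA(out$chrom2)) {
    stop("every sample needs exactly two chromosome records", call. = FALSE)
  }
  out
}

#' Cosegregation summary of assay calls against disease status
#'
#' Cross-tabulates carrier category against affection status and computes
#' the concordance fraction — the proportion of called samples whose
#' genotype matches the dominant-model expectation (affected heterozygous
#' carriers plus unaffected non-carriers). No-calls are tallied separately
#' and excluded from the concordance denominator.
#'
#' @param calls A data frame with columns `sample` and `call` (as from
#'   [call_genotypes()]).
#' @param status Named character vector of `"affected"`/`"unaffected"` per
#'   sample.
#' @return A list of class `pkd_cosegregation`: `counts` (tibble of
#'   status x category tallies), `concordance` (fraction, `NA` when no
#'   sample could be called) and `n_no_call`.
#' @export
cosegregation_summary <- function(calls, status) {
  if (nrow(calls) == 0) {
    out <- list(
      counts = tibble::tibble(
        status = character(), category = character(), n = integer()
      ),
      concordance = NA_real_, n_no_call = 0L
    )
    return(structure(out, class = "pkd_cosegregation"))
  }
  if (!all(calls$sample %in% names(status))) {
    stop("every call needs a status", call. = FALSE)
  }
  st <- unname(status[calls$sample])
  category <- dplyr::case_match(
    calls$call,
    "wt/mut" ~ "carrier het",
    "mut/mut" ~ "carrier hom",
    "wt/wt" ~ "non-carrier",
    "no-call" ~ "no-call"
  )
  called <- category != "no-call"
  counts <- tidyr::complete(
    dplyr::count(
      tibble::tibble(status = st[called], category = category[called]),
      .data$status, .data$category
    ),
    status = c("affected", "unaffected"),
    category = c("carrier het", "carrier hom", "non-carrier"),
    fill = list(n = 0L)
  )
  concordant <- sum(
    (st == "affected" & category == "carrier het") |
      (st == "unaffected" & category == "non-carrier")
  )
  concordance <- if (any(called)) concordant / sum(called) else NA_real_
  structure(
    list(
      counts = counts,
      concordance = concordance,
      n_no_call = sum(!called)
    ),
    class = "pkd_cosegregation"
  )
}

#' @export
print.pkd_cosegregation <- function(x, ...) {
  cat(sprintf(
    "<pkd_cosegregation> concordance %s (%d no-call)\n",
    ifelse(is.na(x$concordance), "NA", format(x$concordance, digits = 4)),
    x$n_no_call
  ))
  print(x$counts)
  invisible(x)
}
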