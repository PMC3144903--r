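#' Map a cDNA position to its codon
#'
#' Coding positions are numbered from 1 at the first base of the
#' initiation codon, so residue `r`, codon offset `o` correspond to
#' cDNA position `3(r - 1) + o`.
#'
#' @param cdna_position 1-based coding position.
#' @return A list with `residue_number` and `offset_in_codon` (1, 2 or 3).
#' @examples
#' cdna_to_codon(9772) # residue 3258, first base of its codon
#' @export
cdna_to_codon <- function(cdna_position) {
  stopifnot(length(cdna_position) == 1, cdna_position >= 1)
  p <- as.integer(cdna_position)
  list(
    residue_number = (p - 1L) %/% 3L + 1L,
    offset_in_codon = (p - 1L) %% 3L + 1L
  )
}

#' Substitute one base of a codon
#'
#' @param codon A 3-mer over A/C/G/T.
#' @param offset Position within the codon (1-3).
#' @param alt Replacement base.
#' @return The mutated 3-mer.
#' @examples
#' mutate_codon("GAG", 1, "A") # "AAG"
#' @export
mutate_codon <- function(codon, offset, alt) {
  check_codon(codon)
  if (!offset %in% 1:3) stop("offset must be 1, 2 or 3", call. = FALSE)
  if (!grepl("^[ACGT]$", alt)) stop("alt must be a single A/C/G/T base", call. = FALSE)
  out <- strsplit(codon, "")[[1]]
  out[offset] <- alt
  paste(out, collapse = "")
}

check_codon <- function(codon) {
  if (length(codon) != 1 || !grepl("^[ACGT]{3}$", codon)) {
    stop(sprintf("'%s' is not an A/C/G/T 3-mer", codon), call. = FALSE)
  }
  invisible(codon)
}

#' Translate a codon under the standard genetic code
#'
#' @param codon A 3-mer over A/C/G/T.
#' @return A one-letter amino acid, or `"*"` for a stop codon.
#' @examples
#' translate_codon("GAG") # "E"
#' @export
translate_codon <- function(codon) {
  check_codon(codon)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# side-chain charge at neutral pH: only D/E (acidic) and K/R (basic)
# are counted; histidine is treated as neutral
aa_charge <- function(aa) {
  if (aa %in% c("D", "E")) -1L else if (aa %in% c("K", "R")) 1L else 0L
}

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' Annotate a coding substitution
#'
#' Maps a cDNA substitution onto its codon, translates reference and
#' alternate codons, classifies the consequence and computes the
#' side-chain charge change (alternate minus reference, at neutral pH;
#' aspartate/glutamate count -1, lysine/arginine +1, histidine 0).
#'
#' @param cdna_position 1-based coding position of the substituted base.
#' @param ref_base,alt_base Reference and alternate nucleotides (must
#'   differ).
#' @param codon_ref The reference codon containing the position; its base
#'   at the computed codon offset must equal `ref_base` (this guards
#'   against coordinate bookkeeping errors).
#' @return A one-row tibble: `residue_number`, `offset_in_codon`,
#'   `codon_ref`, `codon_alt`, `ref_aa`, `alt_aa`, `consequence`
#'   (`synonymous`/`missense`/`nonsense`/`stop-loss`), `charge_delta`,
#'   and HGVS-style `cdna_label` / `protein_label`.
#' @examples
#' annotate_substitution(9772, "G", "A", "GAG") # E3258K, missense, +2
#' @export
annotate_substitution <- function(cdna_position, ref_base, alt_base, codon_ref) {
  check_codon(codon_ref)
  if (identical(ref_base, alt_base)) {
    stop("ref and alt base must differ", call. = FALSE)
  }
  loc <- cdna_to_codon(cdna_position)
  have <- substr(codon_ref, loc$offset_in_codon, loc$offset_in_codon)
  if (have != ref_base) {
    stop(sprintf(
      "reference codon %s carries %s at codon offset %d, not %s: coordinate mismatch",
      codon_ref, have, loc$offset_in_codon, ref_base
    ), call. = FALSE)
  }
  codon_alt <- mutate_codon(codon_ref, loc$offset_in_codon, alt_base)
  ref_aa <- translate_codon(codon_ref)
  alt_aa <- translate_codon(codon_alt)
  consequence <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "nonsense"
  } else if (ref_aa == "*") {
    "stop-loss"
  } else {
    "missense"
  }
  out <- tibble::tibble(
    residue_number = loc$residue_number,
    offset_in_codon = loc$offset_in_codon,
    codon_ref = codon_ref,
    codon_alt = codon_alt,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    consequence = consequence,
    charge_delta = aa_charge(alt_aa) - aa_charge(ref_aa)
  )
  labels <- hgvs_name(out, cdna_position, ref_base, alt_base)
  out$cdna_label <- labels[["cdna"]]
  out$protein_label <- labels[["protein"]]
  out
}

#' HGVS-style names for a substitution
#'
#' @param sub A one-row annotation as produced by
#'   [annotate_substitution()] (needs `residue_number`, `ref_aa`,
#'   `alt_aa`, `consequence`).
#' @param cdna_position,ref_base,alt_base The underlying cDNA change.
#' @return Named character vector with elements `cdna` (e.g.
#'   `"c.9772G>A"`) and `protein` (e.g. `"p.Glu3258Lys"`; `"p.(=)"` for
#'   synonymous changes, `"...Ter"` for stop gains).
#' @export
hgvs_name <- function(sub, cdna_position, ref_base, alt_base) {
  cdna <- sprintf("c.%d%s>%s", as.integer(cdna_position), ref_base, alt_base)
  protein <- if (sub$consequence == "synonymous") {
    "p.(=)"
  } else {
    sprintf(
      "p.%s%d%s",
      AA_THREE[[sub$ref_aa]], sub$residue_number, AA_THREE[[sub$alt_aa]]
    )
  }
  c(cdna = cdna, protein = protein)
}

#' Consequence of each site of a variant table
#'
#' Non-exonic sites (introns, UTRs) are reported as
#' `"non-coding: not assessed"`; exonic sites would need a transcript
#' model to annotate and are reported as `"coding: codon context required"`
#' unless they are the site of a supplied annotation.
#'
#' @param table A `variant_table`.
#' @return A tibble with `assay_id`, `feature` and `annotation`.
#' @export
site_consequence_class <- function(table) {
  validate_variant_table(table)
  tibble::tibble(
    assay_id = table$assay_id,
    feature = table$feature,
    annotation = ifelse(
      grepl("^Exon", table$feature),
      "coding: codon context required",
      "non-coding: not assessed"
    )
  )
}
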