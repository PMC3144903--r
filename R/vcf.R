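#' Export a variant table as VCF
#'
#' Renders a `variant_table` as minimal VCF 4.2 text with unphased GT
#' fields. Because sites are positioned relative to gene features, the
#' caller supplies a mapping from feature names to the absolute 1-based
#' start of that feature on the contig; a site at feature position `p`
#' lands at `POS = offset + p - 1`.
#'
#' Allele rendering: base-string alleles are emitted verbatim, run-length
#' alleles as their literal expansion (`"10C"` becomes ten Cs), and
#' deletion sites in left-anchored style — the REF carries an anchor base
#' plus the present segment (as Ns when its sequence is unknown) while the
#' deletion ALT is the anchor alone. Only SNV and deletion alleles round-trip
#' losslessly.
#'
#' @param x A `variant_table`.
#' @param feature_offsets Named integer vector: absolute 1-based contig
#'   start of every feature occurring in `x`.
#' @param path Optional file to write.
#' @param contig Contig name for the CHROM column.
#' @return Character vector of VCF lines (invisibly when `path` is given).
#' @examples
#' tab <- parse_variant_table(c(
#'   "#status: S1=affected\tS2=unaffected",
#'   "assay_id\tfeature\tposition\tdb_ref\tS1\tS2",
#'   "ss1\tExon 29\t42\tG\tG/A\tG/G"
#' ))
#' export_vcf(tab, c("Exon 29" = 100))
#' @export
export_vcf <- function(x, feature_offsets, path = NULL, contig = "Pkd1") {
  validate_variant_table(x)
  missing_feats <- setdiff(unique(x$feature), names(feature_offsets))
  if (length(missing_feats)) {
    stop(sprintf(
      "no offset supplied for feature(s): %s",
      paste(missing_feats, collapse = ", ")
    ), call. = FALSE)
  }
  samples <- vt_samples(x)
  status <- vt_status(x)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pkdscan",
    sprintf("##contig=<ID=%s>", contig),
    paste0(
      "##sample_status=",
      paste(sprintf("%s:%s", samples, status[samples]), collapse = ",")
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )

  records <- vapply(seq_len(nrow(x)), function(i) {
    pos <- unname(feature_offsets[[x$feature[i]]]) +
      parse_position(x$position[i])[["start"]] - 1L
    db <- x$db_ref[[i]]
    observed <- unique(unlist(lapply(
      samples, function(s) parse_genotype(x[[s]][i])
    )))
    tokens <- unique(c(db[1], observed, db))
    has_del <- any(tokens == "Del")
    expand <- vapply(tokens, expand_allele, character(1))
    if (has_del) {
      # left-anchor every allele on an anchor base
      expand <- paste0("N", expand)
    }
    ref_seq <- expand[1]
    alt_tokens <- tokens[-1][expand[-1] != ref_seq]
    alt_seq <- unique(vapply(alt_tokens, expand_allele, character(1)))
    if (has_del) alt_seq <- paste0("N", alt_seq)
    allele_index <- stats::setNames(seq_along(c(tokens[1], alt_tokens)) - 1L,
      c(tokens[1], alt_tokens))
    gts <- vapply(samples, function(s) {
      g <- parse_genotype(x[[s]][i])
      paste(sort(allele_index[g]), collapse = "/")
    }, character(1))
    paste(c(
      contig, pos, x$assay_id[i], ref_seq,
      if (length(alt_seq)) paste(alt_seq, collapse = ",") else ".",
      ".", "PASS", ".", "GT", gts
    ), collapse = "\t")
  }, character(1))

  lines <- c(header, records)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Import a VCF produced by [export_vcf()]
#'
#' Restores a `variant_table` from SNV-only VCF text, mapping absolute
#' positions back to feature-relative coordinates through the same offset
#' table used at export. Sites with non-SNV alleles are not supported.
#'
#' @param lines Character vector of VCF lines, or a file path.
#' @param feature_offsets The named offset vector used at export.
#' @return A `variant_table`.
#' @export
import_vcf <- function(lines, feature_offsets) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  status_line <- lines[grepl("^##sample_status=", lines)]
  if (length(status_line) != 1) {
    stop("VCF lacks the ##sample_status header written by export_vcf",
      call. = FALSE
    )
  }
  kv <- strsplit(
    strsplit(sub("^##sample_status=", "", status_line), ",", fixed = TRUE)[[1]],
    ":",
    fixed = TRUE
  )
  status <- stats::setNames(
    vapply(kv, `[`, character(1), 2),
    vapply(kv, `[`, character(1), 1)
  )
  header <- lines[grepl("^#CHROM", lines)]
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!grepl("^#", lines)]

  # invert offsets: a POS belongs to the feature with the largest start <= POS
  off <- sort(unlist(feature_offsets))
  rows <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[2])
    feat_i <- max(which(off <= pos))
    feature <- names(off)[feat_i]
    rel <- pos - off[[feat_i]] + 1L
    alleles <- c(f[4], if (f[5] != ".") strsplit(f[5], ",", fixed = TRUE)[[1]])
    if (any(nchar(alleles) != 1)) {
      stop("import_vcf supports SNV records only", call. = FALSE)
    }
    gts <- vapply(f[-(1:9)], function(g) {
      idx <- as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) + 1L
      render_genotype(alleles[idx])
    }, character(1), USE.NAMES = FALSE)
    c(f[3], feature, as.character(rel), f[4], gts)
  })
  mat <- do.call(rbind, rows)
  tsv <- c(
    paste0("#status: ", paste(sprintf("%s=%s", samples, status[samples]),
      collapse = "\t"
    )),
    paste(c("assay_id", "feature", "position", "db_ref", samples),
      collapse = "\t"
    ),
    apply(mat, 1, paste, collapse = "\t")
  )
  parse_variant_table(tsv)
}
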