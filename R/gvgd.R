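#' Grantham amino-acid properties and distance
#'
#' The Grantham distance between residues combines three side-chain
#' properties — composition `c` (atomic weight ratio of non-carbon
#' elements), polarity `p` and molecular volume `v` — as
#' \deqn{D = \rho \sqrt{\alpha (\Delta c)^2 + \beta (\Delta p)^2 +
#'   \gamma (\Delta v)^2}}
#' with weights \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018},
#' \eqn{\gamma = 0.000399}. The scale \eqn{\rho = 50.723} is the published
#' constant that normalizes the mean of all 190 unordered residue-pair
#' distances to 100; recomputing the mean-100 calibration from the
#' unrounded property values gives 50.790 (mean distance 99.87 at the
#' published constant), so `grantham_rho(calibrate = TRUE)` exposes the
#' recalibrated value while the published constant — which exactly
#' reproduces the rounded distances in common use, e.g. an unrounded
#' Glu-Lys distance of 56.87 — is the default.
#'
#' @name grantham
NULL

GRANTHAM_PROPERTIES <- local({
  aa <- c(
    "S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
    "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"
  )
  m <- cbind(
    c = c(
      1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
      0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13
    ),
    p = c(
      9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
      6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4
    ),
    v = c(
      32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
      136, 55, 96, 85, 56, 119, 54, 83, 105, 170
    )
  )
  rownames(m) <- aa
  m
})

GRANTHAM_WEIGHTS <- c(alpha = 1.833, beta = 0.1018, gamma = 0.000399)
GRANTHAM_RHO <- 50.723

check_residues <- function(aa) {
  bad <- setdiff(aa, rownames(GRANTHAM_PROPERTIES))
  if (length(bad)) {
    stop(sprintf(
      "non-standard residue(s): %s",
      paste(unique(bad), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(aa)
}

#' @rdname grantham
#' @param calibrate If `TRUE`, recompute the scale so that the mean of all
#'   190 unordered-pair distances is exactly 100; otherwise return the
#'   published constant 50.723.
#' @return `grantham_rho()`: the scale factor.
#' @export
grantham_rho <- function(calibrate = FALSE) {
  if (!calibrate) {
    return(GRANTHAM_RHO)
  }
  aa <- rownames(GRANTHAM_PROPERTIES)
  pairs <- utils::combn(aa, 2)
  d <- vapply(
    seq_len(ncol(pairs)),
    function(k) grantham_distance(pairs[1, k], pairs[2, k], rho = 1),
    numeric(1)
  )
  100 / mean(d)
}

#' @rdname grantham
#' @param aa1,aa2 One-letter residues.
#' @param rho Scale factor; see `grantham_rho()`.
#' @return `grantham_distance()`: the (unrounded) distance; symmetric,
#'   non-negative, zero exactly when `aa1 == aa2`.
#' @examples
#' grantham_distance("E", "K") # 56.87
#' @export
grantham_distance <- function(aa1, aa2, rho = grantham_rho()) {
  check_residues(c(aa1, aa2))
  d <- GRANTHAM_PROPERTIES[aa1, ] - GRANTHAM_PROPERTIES[aa2, ]
  rho * sqrt(sum(GRANTHAM_WEIGHTS * d^2))
}

column_residues <- function(column) {
  res <- column[!column %in% c("-", ".")]
  if (length(res) == 0) {
    stop("alignment column is empty after gap removal", call. = FALSE)
  }
  check_residues(res)
  res
}

#' Grantham Variation of an alignment column
#'
#' GV measures the physicochemical spread of the residues observed at one
#' alignment position: the property-space range, scaled like the Grantham
#' distance. A column in which all species carry the same residue has
#' GV = 0; a two-residue column has GV equal to their pairwise Grantham
#' distance.
#'
#' @param column Character vector of one-letter residues observed at the
#'   position (gap characters `-`/`.` are dropped).
#' @param rho Scale factor.
#' @return Non-negative GV score.
#' @examples
#' gv(c("E", "E", "E", "E")) # 0
#' @export
gv <- function(column, rho = grantham_rho()) {
  res <- column_residues(column)
  props <- GRANTHAM_PROPERTIES[res, , drop = FALSE]
  rng <- apply(props, 2, function(x) max(x) - min(x))
  rho * sqrt(sum(GRANTHAM_WEIGHTS * rng^2))
}

#' Grantham Deviation of a variant from an alignment column
#'
#' GD measures how far a variant residue falls outside the property range
#' spanned by the residues observed at the position: per property the
#' deviation is zero when the variant lies within the observed
#' `[min, max]` interval, else the distance to the nearer bound. For an
#' invariant column GD reduces to the pairwise Grantham distance between
#' the variant and the single observed residue.
#'
#' @param column Character vector of observed residues (gaps dropped).
#' @param variant_aa The substituted one-letter residue.
#' @param rho Scale factor.
#' @return Non-negative GD score.
#' @examples
#' gd(c("E", "E", "E", "E"), "K") # 56.87
#' @export
gd <- function(column, variant_aa, rho = grantham_rho()) {
  res <- column_residues(column)
  check_residues(variant_aa)
  props <- GRANTHAM_PROPERTIES[res, , drop = FALSE]
  vprop <- GRANTHAM_PROPERTIES[variant_aa, ]
  dev <- vapply(colnames(props), function(q) {
    lo <- min(props[, q])
    hi <- max(props[, q])
    if (vprop[[q]] < lo) lo - vprop[[q]] else if (vprop[[q]] > hi) vprop[[q]] - hi else 0
  }, numeric(1))
  rho * sqrt(sum(GRANTHAM_WEIGHTS * dev^2))
}

GVGD_THRESHOLDS <- c(65, 55, 45, 35, 25, 15)

#' Seven-class GV/GD pathogenicity grade
#'
#' Assigns one of the seven grades C0, C15, C25, C35, C45, C55, C65 from a
#' (GV, GD) pair. The boundary for grade Cx is
#' `GD >= x + tan(10 degrees) * GV^2`; the label is the largest x whose
#' boundary the score clears, else C0. Higher grades indicate greater
#' predicted pathogenicity; the rule is monotone in GD at fixed GV.
#'
#' @param gv_score,gd_score Non-negative GV and GD values.
#' @return The class label as a string (`"C55"` etc.). The numeric
#'   threshold index is available from [gvgd_class_index()].
#' @examples
#' classify_gvgd(0, 56.87) # "C55"
#' @export
classify_gvgd <- function(gv_score, gd_score) {
  if (gv_score < 0 || gd_score < 0) {
    stop("GV and GD must be non-negative", call. = FALSE)
  }
  for (x in GVGD_THRESHOLDS) {
    if (gd_score >= x + tanpi(10 / 180) * gv_score^2) {
      return(sprintf("C%d", x))
    }
  }
  "C0"
}

#' @rdname classify_gvgd
#' @param label A class label such as `"C55"`.
#' @return `gvgd_class_index()`: the numeric threshold index (0 for C0).
#' @export
gvgd_class_index <- function(label) {
  as.numeric(sub("^C", "", label))
}

#' Score a substitution against an alignment column
#'
#' Convenience wrapper computing the full (GV, GD, class) triple for a
#' variant residue at one column of a protein alignment.
#'
#' @param alignment Character vector of equal-length aligned sequences, or
#'   the result of [read_alignment()].
#' @param column 1-based column index.
#' @param variant_aa Substituted residue.
#' @return One-row tibble with `gv`, `gd`, `class` and `class_index`.
#' @export
align_gvgd <- function(alignment, column, variant_aa) {
  col <- alignment_column(alignment, column)
  g1 <- gv(col)
  g2 <- gd(col, variant_aa)
  cls <- classify_gvgd(g1, g2)
  tibble::tibble(gv = g1, gd = g2, class = cls, class_index = gvgd_class_index(cls))
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal files into a named character vector of
#' equal-length gapped sequences. Gap characters `-` and `.` are
#' preserved.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"` (guessed from the extension by
#'   default).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE)) {
      "clustal"
    } else {
      "fasta"
    }
  }
  seqs <- if (format == "fasta") {
    as.character(Biostrings::readBStringSet(path))
  } else {
    parse_clustal(readLines(path, warn = FALSE))
  }
  if (length(unique(nchar(seqs))) > 1) {
    stop("aligned sequences must share one length", call. = FALSE)
  }
  toupper(seqs)
}

# Minimal Clustal block parser: a CLUSTAL header line, then one or more
# blocks of "name  gapped-sequence [cumulative-length]" lines; blank and
# conservation (*:. only) lines separate blocks. Sequences accumulate
# across blocks in first-appearance order.
parse_clustal <- function(lines) {
  if (!length(lines) || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file: missing CLUSTAL header line", call. = FALSE)
  }
  acc <- list()
  order_seen <- character(0)
  for (line in lines[-1]) {
    if (!nzchar(trimws(line))) next
    if (grepl("^\\s", line) || grepl("^[*:. ]+$", line)) next # conservation row
    m <- regmatches(
      line,
      regexec("^(\\S+)\\s+([A-Za-z.~-]+)(\\s+\\d+)?\\s*$", line)
    )[[1]]
    if (length(m) == 0) {
      stop(sprintf("unparseable Clustal line: '%s'", line), call. = FALSE)
    }
    nm <- m[2]
    if (!nm %in% order_seen) order_seen <- c(order_seen, nm)
    acc[[nm]] <- paste0(acc[[nm]] %||% "", m[3])
  }
  if (!length(acc)) stop("Clustal file contains no sequences", call. = FALSE)
  out <- unlist(acc[order_seen])
  if (length(unique(nchar(out))) > 1) {
    stop("aligned sequences must share one length", call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

alignment_column <- function(alignment, n) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("aligned sequences must share one length", call. = FALSE)
  }
  if (n < 1 || n > lens[1]) {
    stop(sprintf("column %d outside alignment of width %d", n, lens[1]),
      call. = FALSE
    )
  }
  toupper(substr(alignment, n, n))
}

#' Fully conserved column fraction of an alignment
#'
#' The fraction of alignment columns at which every sequence carries the
#' identical, non-gap symbol (the asterisk convention of printed
#' alignments). Works for nucleotide or protein alignments.
#'
#' @param alignment Character vector of >= 2 equal-length aligned
#'   sequences.
#' @param from,to Optional 1-based column window (defaults to the whole
#'   alignment).
#' @return Fraction in `[0, 1]`.
#' @examples
#' conservation_fraction(c("ACGT", "ACGA"))
#' @export
conservation_fraction <- function(alignment, from = 1, to = NULL) {
  if (length(alignment) < 2) {
    stop("conservation needs at least two sequences", call. = FALSE)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("aligned sequences must share one length (ragged alignment)",
      call. = FALSE
    )
  }
  if (is.null(to)) to <- lens[1]
  stopifnot(from >= 1, to <= lens[1], from <= to)
  cols <- from:to
  conserved <- vapply(cols, function(j) {
    col <- toupper(substr(alignment, j, j))
    !any(col %in% c("-", ".")) && length(unique(col)) == 1
  }, logical(1))
  mean(conserved)
}
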