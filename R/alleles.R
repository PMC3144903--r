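#' Parse an allele token
#'
#' Variant tables in this package use a compact token grammar for alleles:
#'
#' * base strings (`"G"`, `"GGG"`) — one or more of A/C/G/T;
#' * run-length tokens (`"10C"`, `"22A"`) — a mononucleotide run of the
#'   stated length, written `<count><base>`;
#' * the deletion token `"Del"` — absence of a reference segment;
#' * segment-presence tokens (`"59bp"`) — the undeleted counterpart of a
#'   `"Del"` allele, a reference segment of the stated length. These occur
#'   only as database reference alleles, never as genotype calls.
#'
#' Parsing then re-rendering a token is the identity, so tokens can be
#' compared as normalized strings throughout the package.
#'
#' @param token A single non-empty allele token (whitespace is trimmed).
#' @return An object of class `"allele"`: a list with elements `token`,
#'   `form` (one of `"base"`, `"run"`, `"deletion"`, `"segment"`), and for
#'   run-length/segment forms `count` and (runs only) `base`.
#' @examples
#' parse_allele("11C")
#' parse_allele("Del")
#' @export
parse_allele <- function(token) {
  if (length(token) != 1 || is.na(token)) {
    stop("allele token must be a single string", call. = FALSE)
  }
  tok <- trimws(token)
  if (!nzchar(tok)) {
    stop("malformed allele token: \"\" (empty)", call. = FALSE)
  }
  out <- if (tok == "Del") {
    list(token = tok, form = "deletion")
  } else if (grepl("^[ACGT]+$", tok)) {
    list(token = tok, form = "base")
  } else if (grepl("^[1-9][0-9]*[ACGT]$", tok)) {
    n <- nchar(tok)
    list(
      token = tok, form = "run",
      count = as.integer(substr(tok, 1, n - 1)),
      base = substr(tok, n, n)
    )
  } else if (grepl("^[1-9][0-9]*bp$", tok)) {
    list(
      token = tok, form = "segment",
      count = as.integer(sub("bp$", "", tok))
    )
  } else {
    stop(sprintf("malformed allele token: \"%s\"", tok), call. = FALSE)
  }
  structure(out, class = "allele")
}

#' @export
print.allele <- function(x, ...) {
  extra <- switch(x$form,
    run = sprintf(" (%d x %s)", x$count, x$base),
    segment = sprintf(" (%d bp present)", x$count),
    ""
  )
  cat(sprintf("<allele> %s [%s]%s\n", x$token, x$form, extra))
  invisible(x)
}

#' Render an allele back to its token
#'
#' @param allele An object returned by [parse_allele()].
#' @return The normalized token string.
#' @export
render_allele <- function(allele) {
  stopifnot(inherits(allele, "allele"))
  allele$token
}

# Validate a vector of tokens; returns the trimmed tokens or errors.
check_allele_tokens <- function(tokens) {
  vapply(tokens, function(t) render_allele(parse_allele(t)), character(1),
    USE.NAMES = FALSE
  )
}

#' Parse a genotype cell
#'
#' A genotype call is an unordered pair of alleles written `"X/Y"`.
#' Tokens are normalized and sorted so that order of writing never
#' matters: `"G/A"` and `"A/G"` are the same call.
#'
#' @param cell A single `"X/Y"` string.
#' @return A sorted length-2 character vector of allele tokens.
#' @examples
#' parse_genotype("G/A")
#' @export
parse_genotype <- function(cell) {
  if (length(cell) != 1 || is.na(cell) || !nzchar(trimws(cell))) {
    stop("genotype cell must be a single non-empty string", call. = FALSE)
  }
  hit <- .genotype_cache[[cell]]
  if (!is.null(hit)) {
    return(hit)
  }
  parts <- strsplit(trimws(cell), "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop(sprintf("genotype cell \"%s\" must contain exactly two alleles", cell),
      call. = FALSE
    )
  }
  out <- sort(check_allele_tokens(parts))
  # genotype vocabularies are tiny relative to table sizes: cache wins
  if (length(.genotype_cache) < 4096) assign(cell, out, envir = .genotype_cache)
  out
}

.genotype_cache <- new.env(parent = emptyenv())

#' @rdname parse_genotype
#' @param alleles A length-2 character vector of allele tokens.
#' @return `render_genotype()` returns the normalized `"X/Y"` string.
#' @export
render_genotype <- function(alleles) {
  stopifnot(length(alleles) == 2)
  paste(sort(alleles), collapse = "/")
}

#' @rdname parse_genotype
#' @param cell A genotype cell string.
#' @return `is_heterozygous()` returns `TRUE` when the two alleles differ.
#' @export
is_heterozygous <- function(cell) {
  g <- parse_genotype(cell)
  g[1] != g[2]
}

# Expand an allele token to literal nucleotides for VCF export.
# Deletions expand to "" (the anchor base is added by the exporter);
# segment-presence alleles expand to N-runs of the stated length.
expand_allele <- function(token) {
  a <- parse_allele(token)
  switch(a$form,
    base = a$token,
    run = strrep(a$base, a$count),
    deletion = "",
    segment = strrep("N", a$count)
  )
}
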