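#' Variant tables: per-feature sites by sample genotypes
#'
#' A variant table records, for each variant site in a gene survey, its
#' assay id, the feature it falls in (`"Exon 29"`, `"Intron 12"`,
#' `"5' UTR"`), its 1-based position (or inclusive range) from the 5' end
#' of that feature, the allele(s) reported by public sequence databases,
#' and one genotype call per sample. Sample affection status rides in a
#' leading `#status:` metadata line so a table is a single self-contained
#' TSV file.
#'
#' The TSV dialect is:
#' \preformatted{
#' #status: S1=affected<TAB>S2=unaffected ...
#' assay_id<TAB>feature<TAB>position<TAB>db_ref<TAB>S1<TAB>S2 ...
#' ss1<TAB>Exon 1<TAB>42<TAB>G<TAB>G/A<TAB>G/G
#' }
#' Ambiguous database references ("A or G" in print) are written `A|G`;
#' ranges are written `start-end`.
#'
#' @param text Either a single string containing the whole file or a
#'   character vector of lines.
#' @return A `variant_table`: a tibble with columns `assay_id`, `feature`,
#'   `position`, `db_ref` (list-column of token vectors) and one genotype
#'   column per sample, plus attributes `samples` (character) and `status`
#'   (named character, values `"affected"`/`"unaffected"`).
#' @examples
#' tab <- btpkd_variants()
#' nrow(tab)
#' vt_status(tab)
#' @export
parse_variant_table <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("variant table needs a #status: line, a header and at least no data rows",
      call. = FALSE
    )
  }
  status_line <- lines[grepl("^#status:", lines)]
  if (length(status_line) != 1) {
    stop("variant table must carry exactly one '#status:' metadata line",
      call. = FALSE
    )
  }
  status <- parse_status_line(status_line)
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("assay_id", "feature", "position", "db_ref")
  if (length(header) < 6 || !identical(header[1:4], fixed_cols)) {
    stop("header must be: assay_id, feature, position, db_ref, then >= 2 sample columns",
      call. = FALSE
    )
  }
  samples <- header[-(1:4)]
  unknown <- setdiff(samples, names(status))
  if (length(unknown)) {
    stop(sprintf(
      "sample column(s) missing from #status line: %s",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  status <- status[samples]

  if (length(body) == 1) { # header only: a zero-site table
    tab <- tibble::tibble(
      assay_id = character(), feature = character(), position = character()
    )
    tab$db_ref <- list()
    for (s in samples) tab[[s]] <- character()
    return(new_variant_table(tab, samples = samples, status = status))
  }

  rows <- lapply(seq_along(body[-1]), function(i) {
    fields <- strsplit(body[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop(sprintf(
        "row %d (%s): expected %d fields, found %d",
        i, fields[1], length(header), length(fields)
      ), call. = FALSE)
    }
    blank <- which(!nzchar(trimws(fields)))
    if (length(blank)) {
      stop(sprintf(
        "row %d (%s): missing cell in column '%s'",
        i, fields[1], header[blank[1]]
      ), call. = FALSE)
    }
    fields
  })
  mat <- do.call(rbind, rows)
  assay_id <- mat[, 1]
  if (anyDuplicated(assay_id)) {
    stop(sprintf(
      "duplicate assay_id: %s",
      paste(unique(assay_id[duplicated(assay_id)]), collapse = ", ")
    ), call. = FALSE)
  }

  pos <- lapply(mat[, 3], parse_position)
  db_ref <- lapply(mat[, 4], function(x) {
    toks <- check_allele_tokens(strsplit(x, "|", fixed = TRUE)[[1]])
    if (length(toks) < 1 || length(toks) > 2) {
      stop(sprintf("db_ref '%s' must list 1-2 alleles", x), call. = FALSE)
    }
    toks
  })

  tab <- tibble::tibble(
    assay_id = assay_id,
    feature = mat[, 2],
    position = mat[, 3]
  )
  tab$db_ref <- db_ref
  for (j in seq_along(samples)) {
    cells <- mat[, 4 + j]
    norm <- vapply(seq_along(cells), function(i) {
      g <- tryCatch(parse_genotype(cells[i]), error = function(e) {
        stop(sprintf(
          "row %d (%s), sample %s: %s",
          i, assay_id[i], samples[j], conditionMessage(e)
        ), call. = FALSE)
      })
      render_genotype(g)
    }, character(1))
    tab[[samples[j]]] <- norm
  }
  new_variant_table(tab, samples = samples, status = status)
}

parse_status_line <- function(line) {
  body <- sub("^#status:\\s*", "", line)
  parts <- strsplit(body, "[\t;]+")[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) {
    stop("each #status entry must look like 'Sample=affected'", call. = FALSE)
  }
  status <- vapply(kv, function(x) trimws(x[2]), character(1))
  names(status) <- vapply(kv, function(x) trimws(x[1]), character(1))
  ok <- status %in% c("affected", "unaffected")
  if (!all(ok)) {
    stop(sprintf(
      "unknown status label '%s' for sample %s",
      status[!ok][1], names(status)[!ok][1]
    ), call. = FALSE)
  }
  status
}

parse_position <- function(x) {
  if (grepl("^[0-9]+$", x)) {
    p <- as.integer(x)
    if (p < 1) stop(sprintf("position '%s' must be >= 1", x), call. = FALSE)
    c(start = p, end = p)
  } else if (grepl("^[0-9]+-[0-9]+$", x)) {
    se <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    if (se[1] < 1 || se[1] > se[2]) {
      stop(sprintf("bad position range '%s'", x), call. = FALSE)
    }
    c(start = se[1], end = se[2])
  } else {
    stop(sprintf("unparseable position '%s'", x), call. = FALSE)
  }
}

new_variant_table <- function(tab, samples, status) {
  structure(
    tibble::as_tibble(tab),
    samples = samples,
    status = status,
    class = c("variant_table", class(tibble::tibble()))
  )
}

#' @rdname parse_variant_table
#' @param path Path to a variant-table TSV file.
#' @export
read_variant_table <- function(path) {
  parse_variant_table(readLines(path, warn = FALSE))
}

#' @rdname parse_variant_table
#' @param x A `variant_table`.
#' @return `render_variant_table()` returns the TSV dialect as a character
#'   vector of lines; `write_variant_table()` writes it and returns `x`
#'   invisibly.
#' @export
render_variant_table <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  samples <- vt_samples(x)
  status <- vt_status(x)
  status_line <- paste0(
    "#status: ",
    paste(sprintf("%s=%s", samples, status[samples]), collapse = "\t")
  )
  header <- paste(c("assay_id", "feature", "position", "db_ref", samples),
    collapse = "\t"
  )
  db <- vapply(x$db_ref, paste, character(1), collapse = "|")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(
      x$assay_id[i], x$feature[i], x$position[i], db[i],
      vapply(samples, function(s) x[[s]][i], character(1))
    ), collapse = "\t")
  }, character(1))
  c(status_line, header, body)
}

#' @rdname parse_variant_table
#' @export
write_variant_table <- function(x, path) {
  writeLines(render_variant_table(x), path)
  invisible(x)
}

#' Accessors for variant tables
#'
#' @param x A `variant_table`.
#' @return `vt_samples()`: the ordered sample ids. `vt_status()`: named
#'   character of `"affected"`/`"unaffected"` per sample.
#'   `vt_genotypes()`: a site-by-sample character matrix of `"X/Y"` cells.
#' @export
vt_samples <- function(x) attr(x, "samples")

#' @rdname vt_samples
#' @export
vt_status <- function(x) attr(x, "status")

#' @rdname vt_samples
#' @export
vt_genotypes <- function(x) {
  samples <- vt_samples(x)
  m <- vapply(samples, function(s) x[[s]], character(nrow(x)))
  m <- matrix(m, nrow = nrow(x), dimnames = list(x$assay_id, samples))
  m
}

#' Validate a variant table's invariants
#'
#' Checks that every cell is populated, that statuses are known labels and
#' that the table contains at least one affected and one unaffected sample
#' (the precondition of the segregation filter).
#'
#' @param x A `variant_table`.
#' @return `x` invisibly; errors otherwise.
#' @export
validate_variant_table <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  samples <- vt_samples(x)
  status <- vt_status(x)
  if (!all(samples %in% names(status))) {
    stop("every sample needs a status", call. = FALSE)
  }
  if (!any(status == "affected") || !any(status == "unaffected")) {
    stop("filtering needs at least one affected and one unaffected sample",
      call. = FALSE
    )
  }
  for (s in samples) {
    cells <- x[[s]]
    if (any(is.na(cells)) || any(!nzchar(cells))) {
      stop(sprintf("missing genotype cell for sample %s", s), call. = FALSE)
    }
  }
  invisible(x)
}

#' Packaged canine Pkd1 variant survey fixture
#'
#' The 37-site variant survey of the canine Pkd1 gene in four English Bull
#' Terriers (two affected with autosomal dominant polycystic kidney
#' disease, two unaffected), transcribed from the published site-by-dog
#' genotype table. Positions are 1-based from the 5' end of the named
#' feature. The published two-base exon 17 substitution is transcribed as
#' two single-nucleotide sites (`ss316885543a`/`b`), matching the
#' two slots it occupies in the published haplotype strings.
#'
#' @return A `variant_table` with 37 sites and 4 samples.
#' @export
btpkd_variants <- function() {
  read_variant_table(
    system.file("extdata", "btpkd_pkd1_variants.tsv",
      package = "pkdscan", mustWork = TRUE
    )
  )
}

#' Packaged Pkd1 haplotype fixture
#'
#' The five haplotypes inferred across the eight chromosomes of the four
#' dogs in [btpkd_variants()], with the published per-dog assignment
#' (Dog1 = Hap5/Hap4, Dog2 = Hap5/Hap2, Dog3 = Hap1/Hap2,
#' Dog4 = Hap1/Hap3). Haplotype 5 carries the disease allele `A` at the
#' exon 29 site; Haplotype 1 is its background haplotype.
#'
#' @return A list with `haplotypes` (named list of per-site token vectors)
#'   and `diplotypes` (tibble with columns `sample`, `hap1`, `hap2`).
#' @export
btpkd_haplotypes <- function() {
  path <- system.file("extdata", "btpkd_pkd1_haplotypes.tsv",
    package = "pkdscan", mustWork = TRUE
  )
  lines <- readLines(path, warn = FALSE)
  dip_line <- lines[grepl("^#diplotypes:", lines)]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))][-1] # drop header
  fields <- strsplit(body, "\t", fixed = TRUE)
  haps <- lapply(fields, function(f) decode_haplotype(f[2]))
  names(haps) <- vapply(fields, `[`, character(1), 1)

  entries <- strsplit(sub("^#diplotypes:\\s*", "", dip_line), "[\t;]+")[[1]]
  entries <- trimws(entries[nzchar(trimws(entries))])
  kv <- strsplit(entries, "[=/]")
  diplotypes <- tibble::tibble(
    sample = vapply(kv, `[`, character(1), 1),
    hap1 = vapply(kv, `[`, character(1), 2),
    hap2 = vapply(kv, `[`, character(1), 3)
  )
  list(haplotypes = haps, diplotypes = diplotypes)
}

#' @export
print.variant_table <- function(x, ...) {
  status <- vt_status(x)
  cat(sprintf(
    "<variant_table> %d sites x %d samples (%d affected, %d unaffected)\n",
    nrow(x), length(vt_samples(x)),
    sum(status == "affected"), sum(status == "unaffected")
  ))
  NextMethod()
}
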