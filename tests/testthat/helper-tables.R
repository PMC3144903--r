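# Programmatic fixtures: random variant tables built in code.

# A random biallelic SNV table. Statuses split roughly half/half with at
# least one of each.
random_snv_table <- function(n_sites, n_samples, seed,
                             features = c("Exon 1", "Exon 2", "Intron 1")) {
  withr::with_seed(seed, {
    samples <- sprintf("S%d", seq_len(n_samples))
    n_aff <- max(1L, n_samples %/% 2L)
    status <- setNames(
      rep(c("affected", "unaffected"), c(n_aff, n_samples - n_aff)),
      samples
    )
    bases <- c("A", "C", "G", "T")
    lines <- c(
      paste0("#status: ", paste(sprintf("%s=%s", samples, status), collapse = "\t")),
      paste(c("assay_id", "feature", "position", "db_ref", samples), collapse = "\t")
    )
    for (i in seq_len(n_sites)) {
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      cells <- vapply(samples, function(s) {
        g <- sample(c(ref, alt), 2, replace = TRUE)
        paste(sort(g), collapse = "/")
      }, character(1))
      lines <- c(lines, paste(
        c(sprintf("rs%03d", i), sample(features, 1), as.character(i), ref, cells),
        collapse = "\t"
      ))
    }
    parse_variant_table(lines)
  })
}

# Minimal two-sample table from explicit cells.
tiny_table <- function(cells_by_sample, status = NULL, db_ref = NULL) {
  samples <- names(cells_by_sample)
  n_sites <- length(cells_by_sample[[1]])
  if (is.null(status)) {
    status <- rep(c("affected", "unaffected"), length.out = length(samples))
  }
  if (is.null(db_ref)) db_ref <- rep("G", n_sites)
  lines <- c(
    paste0("#status: ", paste(sprintf("%s=%s", samples, status), collapse = "\t")),
    paste(c("assay_id", "feature", "position", "db_ref", samples), collapse = "\t"),
    vapply(seq_len(n_sites), function(i) {
      paste(c(
        sprintf("site%d", i), "Exon 1", as.character(i), db_ref[i],
        vapply(samples, function(s) cells_by_sample[[s]][i], character(1))
      ), collapse = "\t")
    }, character(1))
  )
  parse_variant_table(lines)
}

expect_same_genotypes <- function(a, b) {
  expect_identical(vt_genotypes(a), vt_genotypes(b))
  expect_identical(vt_status(a), vt_status(b))
  expect_identical(a$assay_id, b$assay_id)
}
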