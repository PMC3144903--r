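AA20 <- rownames(pkdscan:::GRANTHAM_PROPERTIES)

test_that("Grantham distance is a symmetric premetric vanishing on the diagonal", {
  withr::with_seed(2, {
    for (k in 1:20) {
      pair <- sample(AA20, 2)
      d12 <- grantham_distance(pair[1], pair[2])
      expect_identical(d12, grantham_distance(pair[2], pair[1]))
      expect_gt(d12, 0)
    }
  })
  for (aa in AA20) expect_identical(grantham_distance(aa, aa), 0)
  expect_error(grantham_distance("E", "B"), "non-standard")
})

test_that("the E-K distance reproduces the published unrounded value", {
  expect_equal(grantham_distance("E", "K"), 56.87, tolerance = 0.05 / 56.87)
})

test_that("the published scale constant agrees with mean-100 recalibration to 0.2%", {
  rho_cal <- grantham_rho(calibrate = TRUE)
  expect_equal(rho_cal, grantham_rho(), tolerance = 0.002)
  # recalibration makes the 190-pair mean exactly 100
  pairs <- utils::combn(AA20, 2)
  d <- vapply(
    seq_len(ncol(pairs)),
    function(k) grantham_distance(pairs[1, k], pairs[2, k], rho = rho_cal),
    numeric(1)
  )
  expect_equal(mean(d), 100, tolerance = 1e-12)
})

test_that("GV is zero exactly for invariant columns and collapses to pairwise distance", {
  expect_identical(gv(c("E", "E", "E", "E")), 0)
  expect_identical(gv("W"), 0)
  withr::with_seed(4, {
    for (k in 1:15) {
      pair <- sample(AA20, 2)
      expect_equal(gv(pair), grantham_distance(pair[1], pair[2]))
      col <- sample(AA20, sample(2:6, 1), replace = TRUE)
      expect_gte(gv(col), 0)
      if (length(unique(col)) > 1) expect_gt(gv(col), 0)
    }
  })
})

test_that("GD deviates only outside the observed property range", {
  expect_equal(gd(c("E", "E", "E", "E"), "K"), 56.87, tolerance = 0.05 / 56.87)
  # a variant already present in the column deviates by nothing
  withr::with_seed(6, {
    for (k in 1:15) {
      col <- sample(AA20, sample(2:6, 1), replace = TRUE)
      expect_identical(gd(col, sample(col, 1)), 0)
      # GD is bounded by the worst pairwise distance to the column,
      # with equality for invariant columns
      v <- sample(AA20, 1)
      worst <- max(vapply(unique(col), function(a) grantham_distance(v, a), numeric(1)))
      expect_lte(gd(col, v), worst + 1e-9)
    }
    for (k in 1:10) {
      col1 <- sample(AA20, 1)
      v <- sample(AA20, 1)
      expect_equal(gd(rep(col1, 3), v), grantham_distance(col1, v))
    }
  })
  # gaps are ignored; an all-gap column is an error
  expect_equal(gd(c("E", "-", "E", "."), "K"), gd("E", "K"))
  expect_error(gd(c("-", "-"), "K"), "empty")
})

test_that("the seven-class rule bins GD against GV-widened thresholds", {
  expect_identical(classify_gvgd(0, 56.87), "C55")
  expect_identical(classify_gvgd(0, 0), "C0")
  expect_identical(classify_gvgd(0, 70), "C65")
  expect_identical(gvgd_class_index("C55"), 55)
  expect_identical(gvgd_class_index("C0"), 0)
  expect_error(classify_gvgd(-1, 10), "non-negative")
  # the GV term raises every boundary by tan(10 deg) * GV^2
  gv_val <- 5
  shift <- tan(10 * pi / 180) * gv_val^2
  expect_identical(classify_gvgd(gv_val, 55 + shift - 1e-9), "C45")
  expect_identical(classify_gvgd(gv_val, 55 + shift + 1e-9), "C55")
})

test_that("classification is monotone in GD at fixed GV", {
  gvs <- c(0, 2, 10, 30)
  gds <- seq(0, 120, by = 2.5)
  for (g in gvs) {
    idx <- vapply(gds, function(d) gvgd_class_index(classify_gvgd(g, d)), numeric(1))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("the invariant-column E->K pipeline yields (0, 56.87, C55) end to end", {
  col <- rep("E", 4)
  res <- align_gvgd(paste0(
    c("MA", "MA", "MA", "MA"), col, c("KL", "KL", "KL", "KL")
  ), column = 3, variant_aa = "K")
  expect_identical(res$gv, 0)
  expect_equal(res$gd, 56.87, tolerance = 0.05 / 56.87)
  expect_identical(res$class, "C55")
  expect_identical(res$class_index, 55)
})

test_that("conservation is the fully conserved gap-free column fraction", {
  expect_identical(conservation_fraction(c("ACGT", "ACGT", "ACGT")), 1)
  aln <- c(
    "ACGTACGTAC",
    "ACGTACGTAC",
    "ACGAACGAAC",
    "ACGTACGTAC"
  ) # columns 4 and 8 vary: 8 of 10 conserved
  expect_identical(conservation_fraction(aln), 0.8)
  # a gapped column is never conserved
  expect_identical(conservation_fraction(c("A-GT", "ACGT")), 0.75)
  expect_identical(conservation_fraction(c("ACGTAC", "ACGAAC"), from = 1, to = 3), 1)
  expect_error(conservation_fraction("ACGT"), "two sequences")
  expect_error(conservation_fraction(c("ACGT", "ACG")), "ragged")
})

test_that("aligned FASTA and Clustal files read identically", {
  seqs <- c(dog = "MAEKL-Q", cat = "MAEKLSQ", mouse = "MAEKV-Q")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)), fa)
  aln_fa <- read_alignment(fa)
  expect_identical(unname(aln_fa), unname(seqs))

  clw <- withr::local_tempfile(fileext = ".aln")
  writeLines(c(
    "CLUSTAL W (1.83) multiple sequence alignment",
    "",
    sprintf("%-10s%s", names(seqs), seqs),
    ""
  ), clw)
  aln_clw <- read_alignment(clw)
  expect_identical(unname(aln_clw), unname(seqs))
  expect_identical(names(aln_clw), names(seqs))
  # column 3 of this toy alignment is invariant E: the GV/GD scores follow
  expect_identical(align_gvgd(aln_fa, 3, "K")$class, "C55")
})
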