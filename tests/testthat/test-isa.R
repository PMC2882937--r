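test_that("the normalised pair satisfies its moment contracts", {
  x <- noise_matrix(20, 6, seed = 3)
  pair <- normalize_pair(x)
  expect_equal(unname(rowMeans(pair$row_normalized)), rep(0, 20), tolerance = 1e-9)
  expect_equal(unname(apply(pair$row_normalized, 1, var)), rep(1, 20), tolerance = 1e-9)
  expect_equal(unname(colMeans(pair$column_normalized)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(pair$column_normalized, 2, var)), rep(1, 6), tolerance = 1e-9)

  # already row-normalised input passes through unchanged
  z <- beem:::scale_rows(x)
  expect_equal(normalize_pair(z)$row_normalized, z, tolerance = 1e-9)

  x[5, ] <- 2
  expect_error(normalize_pair(x), "g0005")
})

test_that("sample and gene scores are means of the normalised matrices", {
  x <- noise_matrix(10, 4, seed = 5)
  pair <- normalize_pair(x)

  # single gene: the gene's own row-normalised profile
  expect_equal(sample_scores(pair, "g0001"),
               pair$row_normalized["g0001", ])
  # averaging two identical rows changes nothing
  y <- x; y["g0002", ] <- y["g0001", ]
  pair2 <- normalize_pair(y)
  expect_equal(sample_scores(pair2, c("g0001", "g0002")),
               sample_scores(pair2, "g0001"))
  # two z-scored two-sample genes with opposite signs cancel exactly:
  # rows (1,-1)/sqrt and its negation average to zero in every sample
  w <- rbind(a = c(3, 1), b = c(-2, 4), c = c(0, 7))
  colnames(w) <- c("s1", "s2")
  pw <- normalize_pair(w)
  expect_equal(unname(sample_scores(pw, c("a", "b"))), c(0, 0), tolerance = 1e-12)

  # gene scores over all samples equal the row means of the column-normalised
  # matrix (direct computation)
  expect_equal(gene_scores(pair, colnames(x)),
               rowMeans(pair$column_normalized))
  expect_equal(gene_scores(pair, "s002"), pair$column_normalized[, "s002"])
  expect_length(gene_scores(pair, c("s001", "s003")), 10)

  expect_error(sample_scores(pair, "nope"), "unknown gene")
  expect_error(gene_scores(pair, "nope"), "unknown sample")
})

test_that("percentile thresholding selects the top fraction", {
  s <- setNames(as.numeric(1:10), letters[1:10])
  # sort-based oracle: type-7 quantile of 1..10 at 0.8 is 8.2, so 9 and 10
  expect_setequal(threshold_select(s, 0.2), c("i", "j"))
  expect_identical(threshold_select(setNames(rep(1, 5), letters[1:5]), 0.2),
                   character(0))
  # fraction near 1: threshold near the minimum, everything above it selected
  expect_setequal(threshold_select(s, 0.999), letters[2:10])
  expect_error(threshold_select(s, 1.2), "fraction")
})

test_that("seeded ISA recovers a planted bicluster in both directions", {
  genes <- sprintf("g%04d", 1:200)
  planted_g <- genes[1:20]
  x_up <- planted_block_matrix(200, 50, 20, 10, shift = +5, seed = 42)
  pair_up <- normalize_pair(x_up)
  setting <- isa_setting(t_gene = 0.1, t_sample = 0.2, direction = "up")
  b <- run_isa(pair_up, planted_g[1:10], setting)
  expect_true(b$converged)
  expect_setequal(b$genes, planted_g)
  expect_setequal(b$samples, sprintf("s%03d", 1:10))

  # fixed-point property: the output seeds itself
  b2 <- run_isa(pair_up, b$genes, setting)
  expect_setequal(b2$genes, b$genes)
  expect_setequal(b2$samples, b$samples)

  x_dn <- planted_block_matrix(200, 50, 20, 10, shift = -5, seed = 42)
  b_dn <- run_isa(normalize_pair(x_dn), planted_g[1:10],
                  isa_setting(0.1, 0.2, "down"))
  expect_true(b_dn$converged)
  expect_setequal(b_dn$genes, planted_g)
  expect_setequal(b_dn$samples, sprintf("s%03d", 1:10))
})

test_that("ISA is sign-symmetric and sizes track the thresholds", {
  for (seed in 1:5) {
    x <- noise_matrix(150, 40, seed = seed)
    pair_pos <- normalize_pair(x)
    pair_neg <- normalize_pair(-x)
    seed_genes <- rownames(x)[1:12]
    up <- run_isa(pair_pos, seed_genes, isa_setting(0.1, 0.2, "up"))
    dn <- run_isa(pair_neg, seed_genes, isa_setting(0.1, 0.2, "down"))
    expect_identical(up$converged, dn$converged)
    expect_setequal(up$genes, dn$genes)
    expect_setequal(dn$samples, up$samples)
    if (up$converged) {
      # continuous scores: selected sizes within 1 of fraction * dimension
      expect_lte(abs(length(up$genes) - 0.1 * 150), 1)
      expect_lte(abs(length(up$samples) - 0.2 * 40), 1)
    }
  }
})

test_that("isa_setting validates its thresholds", {
  expect_error(isa_setting(1.5, 0.2), "t_gene")
  expect_error(isa_setting(0.1, 0), "t_sample")
  expect_length(default_isa_grid(), 18)
})
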