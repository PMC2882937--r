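test_that("the hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeometric_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(6, 3, 3, 3), 1 / 20, tolerance = 1e-12)
  expect_identical(hypergeometric_tail(50, 10, 8, 0), 1)
  for (N in c(5, 9, 12)) {
    for (b in 0:N) {
      for (m in 0:N) {
        for (k in 0:min(b, m)) {
          expect_equal(hypergeometric_tail(N, b, m, k),
                       hyper_tail_enum(N, b, m, k), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_tail(10, 11, 2, 1), "exceed")
  expect_error(hypergeometric_tail(10, 5, 4, 5), "observed")
})

test_that("the BEEM statistic counts the set/bicluster overlap", {
  # G lies entirely inside a planted bicluster that ISA recovers
  x <- planted_block_matrix(1000, 60, 100, 12, shift = 5, seed = 13)
  z <- beem:::scale_rows(x)
  pair <- normalize_pair(z)
  setting <- isa_setting(t_gene = 0.1, t_sample = 0.2, direction = "up")
  planted <- rownames(x)[1:100]
  bic <- run_isa(pair, planted[1:20], setting)
  expect_setequal(bic$genes, planted)          # recovery verified first
  G <- planted[1:50]
  st <- beem_statistic(z, pair, G, setting)
  expect_identical(st$k, length(G))
  expect_setequal(st$module, G)
  expect_true(all(st$module %in% bic$genes))

  # pure noise: overlaps stay small relative to |G|, yet above the plain
  # binomial-overlap expectation because the random set's core still seeds
  # the bicluster search
  noise <- beem:::scale_rows(noise_matrix(1000, 60, seed = 14))
  pair_n <- normalize_pair(noise)
  setting_n <- isa_setting(t_gene = 0.05, t_sample = 0.2, direction = "up")
  set.seed(15)
  ks <- replicate(100, {
    beem_statistic(noise, pair_n, sample(rownames(noise), 50), setting_n)$k
  })
  expect_lte(median(ks), 0.25 * 50)
  expect_gt(mean(ks), 50 * (0.05 * 1000) / 1000)
})

test_that("null statistics reproduce the seeded-pipeline inflation", {
  x <- planted_block_matrix(600, 50, 80, 10, shift = 4, seed = 16)
  z <- beem:::scale_rows(x)
  pair <- normalize_pair(z)
  setting <- isa_setting(0.15, 0.2, "up")
  n1 <- null_statistics(z, pair, set_size = 60, setting = setting,
                        n_null = 200, seed = 17)
  n2 <- null_statistics(z, pair, set_size = 60, setting = setting,
                        n_null = 200, seed = 17)
  expect_identical(n1, n2)
  expect_length(n1, 200)
  # the coherent core of a random set seeds the bicluster search, so the
  # null overlap exceeds the plain binomial-overlap expectation m*b/N
  b_typical <- 0.15 * 600
  expect_gt(mean(n1), 60 * b_typical / 600)
})

test_that("empirical p-values count null exceedances with smoothing", {
  expect_equal(empirical_pvalue(100, 1:99), 1 / 100)
  expect_equal(empirical_pvalue(0, 1:99), 1)
  expect_equal(empirical_pvalue(50, 1:99), 0.51)
  expect_error(empirical_pvalue(1, numeric(0)), "non-empty")
})

test_that("calibration recovers an exact linear relation and falls back", {
  x <- 1:12
  p1 <- 10^(-x)
  p2 <- 10^(-(2 * x + 0.1))
  cal <- calibrate_and_extrapolate(p1, p2, targets_p1 = 10^(-c(13, 14)),
                                   floor = 1e-30)
  expect_equal(cal$fit$slope, 2, tolerance = 1e-9)
  expect_equal(cal$fit$intercept, 0.1, tolerance = 1e-9)
  expect_equal(cal$fit$r_squared, 1, tolerance = 1e-9)
  expect_false(cal$fit$fallback)
  # smaller p1 -> smaller predicted p2 under a positive slope
  expect_lt(cal$predicted[2], cal$predicted[1])
  expect_equal(cal$predicted[1], 10^(-(2 * 13 + 0.1)), tolerance = 1e-9)

  few <- calibrate_and_extrapolate(p1[1:5], p2[1:5], targets_p1 = c(1e-4, 0.5),
                                   floor = 0.01)
  expect_true(few$fit$fallback)
  expect_equal(few$predicted, c(0.01, 0.5))
})

test_that("the library screen separates planted sets and corrects multiplicity", {
  ds <- simulate_bicluster(n_genes = 1000, n_samples = 60, n_modules = 6,
                           module_size = 120, sample_ratio = 0.2, signal = 3,
                           seed = 31)
  lib <- make_labeled_library(ds, n_pos = 5, n_neg = 5, size = 100,
                              purity = 0.8, seed = 32)
  z <- beem:::scale_rows(ds$matrix)
  grid <- default_isa_grid(t_gene = 0.1, t_sample = c(0.2, 0.3),
                           directions = "up")
  res <- beem_screen(z, lib, grid = grid, n_null = 100, seed = 33)
  labels <- gene_set_labels(lib)[res$set]
  expect_lt(max(res$p_final[labels == "positive"]),
            min(res$p_final[labels == "negative"]))

  # correction and containment invariants
  expect_true(all(res$p_final >= res$p_best - 1e-12))
  expect_equal(res$p_final, 1 - (1 - res$p_best)^length(grid), tolerance = 1e-12)
  expect_true(all(res$k <= pmin(lengths(lib)[res$set], res$bicluster_size)))
  mods <- attr(res, "modules")
  for (nm in res$set) {
    expect_true(all(mods[[nm]] %in% lib[[nm]]))
  }
  expect_identical(res$p_final, sort(res$p_final))

  # a single-setting grid needs no correction
  res1 <- beem_screen(z, lib[1:3], grid = grid[1], n_null = 100, seed = 34)
  expect_equal(res1$p_final, res1$p_best)
  expect_error(beem_screen(z, lib, grid = list(), seed = 1), "grid")
})
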