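test_that("per-sample tails have the right size and are disjoint", {
  x <- beem:::scale_rows(noise_matrix(20, 6, seed = 8))
  tails <- tail_sets(x, fraction = 0.05)
  expect_identical(tails$tail_size, 1L)
  for (j in colnames(x)) {
    expect_length(tails$up[[j]], 1)
    expect_length(intersect(tails$up[[j]], tails$down[[j]]), 0)
    # the unique maximum of a sample is in its up tail
    expect_identical(tails$up[[j]], rownames(x)[which.max(x[, j])])
  }
  expect_error(tail_sets(x, fraction = 0.01), "empty tail")
})

test_that("the per-sample p-value vector matches the enumeration oracle", {
  x <- beem:::scale_rows(noise_matrix(10, 3, seed = 12))
  tails <- tail_sets(x, fraction = 0.2)        # 2 genes per tail
  G <- tails$up[["s001"]]                       # exactly one sample's up tail
  pv <- ssa_pvector(G, tails)
  expect_length(pv, 6)
  expect_equal(unname(pv["up.s001"]), 1 / choose(10, 2), tolerance = 1e-12)
  # every entry agrees with the exhaustive oracle
  for (j in 1:3) {
    s <- sprintf("s%03d", j)
    k_up <- length(intersect(G, tails$up[[s]]))
    expect_equal(unname(pv[paste0("up.", s)]),
                 hyper_tail_enum(10, 2, 2, k_up), tolerance = 1e-12)
  }
  # a set disjoint from every tail scores 1 everywhere
  outside <- setdiff(rownames(x), c(unlist(tails$up), unlist(tails$down)))
  pv0 <- ssa_pvector(outside[1:2], tails)
  expect_true(all(pv0 == 1))
})

test_that("Fisher combination follows the chi-square identity", {
  expect_equal(fisher_combine(rep(1, 7)), list(statistic = 0, p = 1))
  expect_equal(fisher_combine(0.37)$p, 0.37, tolerance = 1e-12)
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$statistic, -4 * log(0.05), tolerance = 1e-9)
  # closed-form chi-square(4) upper tail, independent of pchisq
  expect_equal(fc$p, chisq4_tail(fc$statistic), tolerance = 1e-9)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("Brown calibration tracks inter-sample correlation", {
  # Independent baseline of the same width as the duplicated matrix below.
  x12 <- beem:::scale_rows(noise_matrix(2000, 12, seed = 18))
  x24 <- beem:::scale_rows(noise_matrix(2000, 24, seed = 20))
  sizes <- rep(200, 5)
  cal <- estimate_brown(tail_sets(x24, 0.05), sizes, n_null = 400, seed = 19)
  cal2 <- estimate_brown(tail_sets(x24, 0.05), sizes, n_null = 400, seed = 19)
  expect_identical(cal$null_statistics, cal2$null_statistics)
  expect_identical(cal$expected, 2 * (2 * 24))
  expect_gt(cal$dof, 0)
  # discrete hypergeometric components plus the fixed-set-size constraint
  # keep Var(X) below the continuous-limit 2 * df even for independent
  # samples, so the scale sits below 1
  expect_lt(cal$scale, 1)

  # duplicating every sample doubles the Fisher variance relative to an
  # independent matrix of equal width, doubling the scale and halving the dof
  dup <- x12[, rep(1:12, 2)]
  colnames(dup) <- sprintf("d%03d", 1:24)
  cal_dup <- estimate_brown(tail_sets(dup, 0.05), sizes, n_null = 400,
                            seed = 19)
  expect_equal(cal_dup$scale / cal$scale, 2, tolerance = 0.3)
  expect_equal(cal_dup$dof / cal$dof, 0.5, tolerance = 0.3)
})

test_that("Brown combination reduces to Fisher in the independence limit", {
  cal <- structure(list(expected = 24, variance = 2 * 24, scale = 1, dof = 24,
                        n_null = 1000, null_statistics = NULL),
                   class = "brown_calibration")
  p <- runif(12, 0.05, 1)
  fc <- fisher_combine(p)
  expect_equal(brown_combine(fc$statistic, cal), fc$p, tolerance = 1e-12)
  expect_equal(brown_combine(0, cal), 1)
  xs <- c(5, 10, 20, 40)
  expect_true(all(diff(vapply(xs, brown_combine, numeric(1),
                              calibration = cal)) < 0))
})

test_that("the SSA screen flags single-sample signal and stays calibrated", {
  x <- noise_matrix(300, 15, seed = 25)
  # plant a gene set strongly over-expressed in one sample
  x[1:15, 4] <- x[1:15, 4] + 6
  z <- beem:::scale_rows(x)
  lib <- c(list(planted = rownames(x)[1:15]),
           with(list(), {
             set.seed(26)
             sets <- replicate(30, sample(rownames(x)[16:300], 15),
                               simplify = FALSE)
             names(sets) <- sprintf("null%02d", 1:30)
             sets
           }))
  res <- ssa_screen(z, lib, n_null = 300, seed = 27)
  expect_identical(nrow(res), length(lib))
  expect_lt(res$brown_p[res$set == "planted"], 0.01)
  expect_lt(res$brown_p[res$set == "planted"],
            min(res$brown_p[res$set != "planted"]))
  expect_true(all(res$ssa_min_p > 0 & res$ssa_min_p <= 1))

  # permuted-null matrix: false-positive fraction controlled
  xp <- permute_gene_labels(beem:::scale_rows(noise_matrix(300, 15, seed = 28)),
                            seed = 29)
  nulls <- with(list(), {
    set.seed(30)
    sets <- replicate(100, sample(rownames(xp), 20), simplify = FALSE)
    names(sets) <- sprintf("n%03d", 1:100)
    sets
  })
  res0 <- ssa_screen(xp, nulls, n_null = 300, seed = 31)
  expect_lte(mean(res0$brown_p < 0.05), 0.10)
})
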