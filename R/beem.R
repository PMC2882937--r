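# The BEEM statistic and its three-step p-value calibration over the ISA
# setting grid: hypergeometric screen (p1), empirical null (p2), linear
# regression extrapolation in -log10 space, and multiplicity correction.

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for the overlap `X` between a fixed set of `b` marked genes
#' and a random draw of `m` genes from a population of `N`.
#'
#' @param population population size N.
#' @param successes number of marked genes b.
#' @param draws number of drawn genes m.
#' @param observed observed overlap k.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(population, successes, draws, observed) {
  if (successes > population || draws > population) {
    stop("`successes` and `draws` cannot exceed `population`", call. = FALSE)
  }
  if (observed < 0 || observed > min(successes, draws)) {
    stop("`observed` must lie in [0, min(successes, draws)]", call. = FALSE)
  }
  stats::phyper(observed - 1, successes, population - successes, draws,
                lower.tail = FALSE)
}

#' Compute the BEEM statistic for one gene set
#'
#' The coherent core of the set (extracted from the set's submatrix) seeds
#' ISA on the FULL matrix; the statistic is `k = |G intersect B|`, the size
#' of the overlap between the input set G and the biclustered gene set B. A
#' non-converged ISA run yields `k = 0` and an empty module. Cores smaller
#' than `min_seed` fall back to the full set as seed.
#'
#' @param matrix preprocessed genes-by-samples matrix (rows z-scored).
#' @param pair the matrix's [normalize_pair()] (passed in so callers can
#'   reuse it across sets and settings).
#' @param genes character vector: the input gene set, restricted to the
#'   matrix.
#' @param setting an [isa_setting()].
#' @param radius coherence radius for the seed extraction.
#' @param min_seed minimum usable core size (default 3).
#' @return A list: `k`, `seed_genes`, `bicluster`, `module` (= G intersect B).
#' @export
beem_statistic <- function(matrix, pair, genes, setting, radius = NULL,
                           min_seed = 3) {
  if (is.null(radius)) radius <- default_coherence_radius(ncol(matrix))
  core <- coherent_subset(matrix[genes, , drop = FALSE], radius)
  seed_genes <- if (length(core$genes) < min_seed) genes else core$genes
  bic <- run_isa(pair, seed_genes, setting)
  module <- if (bic$converged) intersect(genes, bic$genes) else character(0)
  list(k = length(module), seed_genes = seed_genes, bicluster = bic,
       module = module)
}

#' Empirical null distribution of the BEEM statistic
#'
#' Runs the full seeding pipeline (coherent core -> seeded ISA -> overlap)
#' on `n_null` gene sets of size `set_size` drawn uniformly without
#' replacement from the matrix's genes. The full pipeline matters: because
#' the core of a random set still seeds the bicluster search, the null
#' overlap is stochastically larger than the plain hypergeometric
#' expectation, which is exactly why the hypergeometric screen alone is
#' liberal.
#'
#' @inheritParams beem_statistic
#' @param set_size size of each null gene set.
#' @param n_null number of null draws.
#' @param seed integer seed (deterministic output).
#' @return Integer vector of length `n_null`.
#' @export
null_statistics <- function(matrix, pair, set_size, setting, radius = NULL,
                            n_null = 1000, seed = 1) {
  genes_all <- rownames(matrix)
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      g <- sample(genes_all, set_size)
      beem_statistic(matrix, pair, g, setting, radius)$k
    }, integer(1))
  })
}

#' Empirical p-value of an observed statistic against a null sample
#'
#' Add-one smoothed ratio of null statistics at least as large as the
#' observation, `p = (1 + #(null >= k)) / (R + 1)`, so the result can never
#' be exactly zero; its floor is `1 / (R + 1)`.
#'
#' @param k_observed observed statistic.
#' @param nulls numeric vector of null statistics.
#' @return Probability in `(0, 1]`.
#' @export
empirical_pvalue <- function(k_observed, nulls) {
  if (length(nulls) == 0) stop("`nulls` must be non-empty", call. = FALSE)
  (1 + sum(nulls >= k_observed)) / (length(nulls) + 1)
}

#' Calibrate the p1 -> p2 relation and extrapolate saturated p2 values
#'
#' For a fixed matrix and ISA setting, `-log10 p2` is very nearly linear in
#' `-log10 p1` across screened sets; an ordinary least-squares fit on the
#' sets whose empirical p2 is above its floor predicts p2 for the sets where
#' the empirical estimate saturates. With fewer than `min_points` usable
#' pairs the fit is abandoned and predictions fall back to
#' `max(floor, p1)`.
#'
#' @param p1 hypergeometric p-values of the usable (non-saturated) sets.
#' @param p2 their empirical p-values.
#' @param targets_p1 p1 values of the sets needing a predicted p2.
#' @param floor the empirical p-value floor `1 / (n_null + 1)`.
#' @param min_points minimum usable pairs for fitting (default 10).
#' @return A list: `fit` (slope, intercept, n_points, r_squared, fallback)
#'   and `predicted` (numeric, same length as `targets_p1`, clamped to
#'   `(0, 1]`).
#' @export
calibrate_and_extrapolate <- function(p1, p2, targets_p1, floor,
                                      min_points = 10) {
  usable <- is.finite(p1) & is.finite(p2) & p2 > floor
  x <- -log10(p1[usable])
  y <- -log10(p2[usable])
  if (sum(usable) < min_points || stats::var(x) == 0) {
    fit <- list(slope = NA_real_, intercept = NA_real_,
                n_points = sum(usable), r_squared = NA_real_, fallback = TRUE)
    predicted <- pmax(floor, targets_p1)
    return(list(fit = fit, predicted = pmin(predicted, 1)))
  }
  ls <- stats::lm.fit(cbind(1, x), y)
  intercept <- ls$coefficients[1]
  slope <- ls$coefficients[2]
  r2 <- if (stats::var(y) == 0) 1 else 1 - sum(ls$residuals^2) / sum((y - mean(y))^2)
  yhat <- slope * (-log10(targets_p1)) + intercept
  predicted <- pmin(10^(-yhat), 1)
  list(fit = list(slope = unname(slope), intercept = unname(intercept),
                  n_points = sum(usable), r_squared = r2, fallback = FALSE),
       predicted = predicted)
}

#' Correct a best-over-settings p-value for the number of settings examined
#'
#' The default is the Sidak form `1 - (1 - p)^n`, matching the selection of
#' the most significant result among `n` ISA settings under independence;
#' Bonferroni (`min(1, n p)`) is available as a more conservative option.
#'
#' @param p_best minimum p-value over the setting grid.
#' @param n_settings number of settings examined.
#' @param method `"sidak"` or `"bonferroni"`.
#' @return Corrected p-value(s).
#' @export
correct_multiplicity <- function(p_best, n_settings,
                                 method = c("sidak", "bonferroni")) {
  method <- match.arg(method)
  if (n_settings < 1) stop("`n_settings` must be positive", call. = FALSE)
  switch(method,
         sidak = 1 - (1 - p_best)^n_settings,
         bonferroni = pmin(1, n_settings * p_best))
}

#' Screen a gene-set library with BEEM
#'
#' For every ISA setting in the grid, each set's BEEM statistic `k` is
#' screened with the hypergeometric p-value `p1`; sets passing
#' `p1 < p1_threshold` get an empirical p-value `p2` against a shared null
#' (cached per set size and setting), with regression extrapolation for sets
#' whose empirical p2 saturates at the floor. A set's p-value for a setting
#' is its p2 when screened and 1 otherwise; `p_best` is the minimum over the
#' grid and `p_final` corrects `p_best` for the number of settings examined.
#'
#' @param matrix preprocessed genes-by-samples matrix (rows z-scored).
#' @param library gene-set library already restricted to the matrix.
#' @param grid list of [isa_setting()]s; default [default_isa_grid()] (18
#'   settings).
#' @param radius coherence radius for seed extraction; default
#'   [default_coherence_radius()].
#' @param p1_threshold hypergeometric screen threshold (default 0.01).
#' @param n_null null draws per (set size, setting) (default 1000).
#' @param min_points minimum pairs for the calibration fit (default 10).
#' @param correction `"sidak"` (`1 - (1 - p)^n`) or `"bonferroni"`
#'   (`min(1, n p)`).
#' @param seed master integer seed.
#' @return A data frame of class `beem_screen` sorted by `p_final`, with
#'   columns `set`, `t_gene`, `t_sample`, `direction` (the best setting),
#'   `k`, `seed_size`, `bicluster_size`, `p1`, `p2`, `p_best`, `p_final`,
#'   `p2_extrapolated`, `isa_converged`. The modules (`G intersect B` at the
#'   best setting) are in `attr(, "modules")`, a named list.
#' @export
beem_screen <- function(matrix, library, grid = default_isa_grid(),
                        radius = NULL, p1_threshold = 1e-2, n_null = 1000,
                        min_points = 10, correction = c("sidak", "bonferroni"),
                        seed = 1) {
  check_expression_matrix(matrix)
  correction <- match.arg(correction)
  if (length(grid) == 0) stop("`grid` must contain at least one setting", call. = FALSE)
  if (is.null(radius)) radius <- default_coherence_radius(ncol(matrix))
  pair <- normalize_pair(matrix)
  n_set <- length(library)
  n_grid <- length(grid)
  floor_p <- 1 / (n_null + 1)

  p_mat <- matrix(1, n_grid, n_set)          # per-setting calibrated p
  p1_mat <- matrix(1, n_grid, n_set)
  p2_mat <- matrix(NA_real_, n_grid, n_set)
  k_mat <- matrix(0L, n_grid, n_set)
  b_mat <- matrix(0L, n_grid, n_set)
  seed_mat <- matrix(0L, n_grid, n_set)
  conv_mat <- matrix(FALSE, n_grid, n_set)
  extr_mat <- matrix(FALSE, n_grid, n_set)
  modules <- vector("list", n_grid)
  sizes <- lengths(library)
  N <- nrow(matrix)

  for (s in seq_len(n_grid)) {
    setting <- grid[[s]]
    stats_s <- lapply(library, function(g) {
      beem_statistic(matrix, pair, g, setting, radius)
    })
    modules[[s]] <- lapply(stats_s, `[[`, "module")
    k_mat[s, ] <- vapply(stats_s, `[[`, integer(1), "k")
    b_mat[s, ] <- vapply(stats_s, function(x) length(x$bicluster$genes), integer(1))
    seed_mat[s, ] <- vapply(stats_s, function(x) length(x$seed_genes), integer(1))
    conv_mat[s, ] <- vapply(stats_s, function(x) x$bicluster$converged, logical(1))
    p1_mat[s, ] <- vapply(seq_len(n_set), function(i) {
      hypergeometric_tail(N, b_mat[s, i], sizes[i], k_mat[s, i])
    }, numeric(1))

    screened <- which(p1_mat[s, ] < p1_threshold)
    if (length(screened)) {
      null_cache <- new.env(parent = emptyenv())
      for (i in screened) {
        key <- as.character(sizes[i])
        if (is.null(null_cache[[key]])) {
          null_cache[[key]] <- null_statistics(
            matrix, pair, sizes[i], setting, radius, n_null,
            seed = derive_seed(seed, "beem_null", s, sizes[i]))
        }
        p2_mat[s, i] <- empirical_pvalue(k_mat[s, i], null_cache[[key]])
      }
      saturated <- screened[p2_mat[s, screened] <= floor_p]
      usable <- screened[p2_mat[s, screened] > floor_p]
      if (length(saturated)) {
        cal <- calibrate_and_extrapolate(p1_mat[s, usable], p2_mat[s, usable],
                                         p1_mat[s, saturated], floor_p,
                                         min_points)
        p2_mat[s, saturated] <- cal$predicted
        extr_mat[s, saturated] <- TRUE
      }
      p_mat[s, screened] <- p2_mat[s, screened]
    }
  }

  best_idx <- apply(p_mat, 2, which.min)
  p_best <- p_mat[cbind(best_idx, seq_len(n_set))]
  p_final <- correct_multiplicity(p_best, n_grid, correction)
  pick <- function(m) m[cbind(best_idx, seq_len(n_set))]
  res <- data.frame(
    set = names(library),
    t_gene = vapply(best_idx, function(s) grid[[s]]$t_gene, numeric(1)),
    t_sample = vapply(best_idx, function(s) grid[[s]]$t_sample, numeric(1)),
    direction = vapply(best_idx, function(s) grid[[s]]$direction, character(1)),
    k = pick(k_mat),
    seed_size = pick(seed_mat),
    bicluster_size = pick(b_mat),
    p1 = pick(p1_mat),
    p2 = pick(p2_mat),
    p_best = p_best,
    p_final = p_final,
    p2_extrapolated = pick(extr_mat),
    isa_converged = pick(conv_mat),
    row.names = NULL, stringsAsFactors = FALSE)
  mods <- lapply(seq_len(n_set), function(i) modules[[best_idx[i]]][[i]])
  names(mods) <- names(library)
  ord <- order(res$p_final, res$p_best, res$set)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "modules") <- mods[res$set]
  attr(res, "n_settings") <- n_grid
  attr(res, "p_matrix") <- p_mat
  attr(res, "p1_matrix") <- p1_mat
  attr(res, "p2_matrix") <- p2_mat
  class(res) <- c("beem_screen", "data.frame")
  res
}
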