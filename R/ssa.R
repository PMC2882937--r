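# Single Sample Analysis: per-sample hypergeometric tests against each
# sample's extreme-expression tails, combined by Fisher's method with
# Brown's scaled chi-square correction for inter-sample correlation.

#' Per-sample top/bottom expression tails
#'
#' For each sample, the `floor(fraction * N)` genes with the largest
#' per-gene-normalised value form the up tail, and the smallest the down
#' tail. Ties at the boundary are broken by row order of the matrix.
#'
#' @param matrix genes-by-samples matrix, rows z-scored (callers such as
#'   [ssa_screen()] normalise first).
#' @param fraction tail fraction in (0,1), default 0.05.
#' @return A list of class `sample_tails`: `up` and `down` (named lists of
#'   gene-id vectors per sample), logical membership matrices `up_matrix` /
#'   `down_matrix` (genes x samples), `fraction`, `tail_size`, `gene_ids`.
#' @export
tail_sets <- function(matrix, fraction = 0.05) {
  check_expression_matrix(matrix)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(matrix)
  tail_size <- as.integer(floor(fraction * n))
  if (tail_size == 0L) {
    stop("`fraction` yields an empty tail for this matrix", call. = FALSE)
  }
  up_m <- matrix(FALSE, n, ncol(matrix), dimnames = dimnames(matrix))
  down_m <- up_m
  for (j in seq_len(ncol(matrix))) {
    ord <- order(matrix[, j], decreasing = TRUE)  # stable: row order on ties
    up_m[ord[seq_len(tail_size)], j] <- TRUE
    ord <- order(matrix[, j])
    down_m[ord[seq_len(tail_size)], j] <- TRUE
  }
  ids <- rownames(matrix)
  structure(list(
    up = apply(up_m, 2, function(z) ids[z], simplify = FALSE),
    down = apply(down_m, 2, function(z) ids[z], simplify = FALSE),
    up_matrix = up_m, down_matrix = down_m,
    fraction = fraction, tail_size = tail_size, gene_ids = ids),
    class = "sample_tails")
}

#' Per-sample hypergeometric p-value vector of a gene set
#'
#' For each sample an upper-tail hypergeometric p-value of the overlap
#' between the gene set and the sample's up tail, then the same for the down
#' tail: a vector of length 2M (all up p-values in sample order, then all
#' down).
#'
#' @param genes character vector, restricted to the matrix's genes.
#' @param tails a [tail_sets()] object.
#' @return Named numeric vector of length `2 * M`.
#' @export
ssa_pvector <- function(genes, tails) {
  stopifnot(inherits(tails, "sample_tails"))
  miss <- setdiff(genes, tails$gene_ids)
  if (length(miss)) {
    stop(sprintf("unknown gene id(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  N <- length(tails$gene_ids)
  b <- tails$tail_size
  m <- length(genes)
  idx <- match(genes, tails$gene_ids)
  k_up <- colSums(tails$up_matrix[idx, , drop = FALSE])
  k_down <- colSums(tails$down_matrix[idx, , drop = FALSE])
  p_up <- stats::phyper(k_up - 1, b, N - b, m, lower.tail = FALSE)
  p_down <- stats::phyper(k_down - 1, b, N - b, m, lower.tail = FALSE)
  stats::setNames(c(p_up, p_down),
                  c(paste0("up.", colnames(tails$up_matrix)),
                    paste0("down.", colnames(tails$down_matrix))))
}

#' Combine p-values by Fisher's method
#'
#' `X = -2 * sum(log p)` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom, valid when the components are
#' independent.
#'
#' @param p_vector probabilities in (0, 1].
#' @return A list: `statistic` (X) and `p`.
#' @export
fisher_combine <- function(p_vector) {
  if (any(p_vector <= 0) || any(p_vector > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  X <- -2 * sum(log(p_vector))
  list(statistic = X,
       p = stats::pchisq(X, df = 2 * length(p_vector), lower.tail = FALSE))
}

#' Estimate Brown's scaled chi-square calibration from null gene sets
#'
#' Under correlated samples the Fisher statistic's variance exceeds its
#' independence value `2 * df`; Brown's approximation refers `X / c` to a
#' chi-square with `f` degrees of freedom, where `c = Var(X) / (2 E[X])` and
#' `f = 2 E[X]^2 / Var(X)`. The mean is the analytic `2 * (2M)`; the
#' variance is estimated empirically from the Fisher statistics of random
#' null gene sets whose sizes follow the input library's size distribution.
#' (Summing pairwise covariances term by term targets the same variance but
#' is far less stable at 2M components.)
#'
#' @param tails a [tail_sets()] object for the matrix under study.
#' @param size_distribution integer vector of input gene-set sizes (sampled
#'   from with replacement).
#' @param n_null number of null gene sets (default 1000, minimum 30).
#' @param seed integer seed.
#' @return A list of class `brown_calibration`: `expected`, `variance`,
#'   `scale` (c), `dof` (f), `n_null`, `null_statistics`.
#' @export
estimate_brown <- function(tails, size_distribution, n_null = 1000, seed = 1) {
  stopifnot(inherits(tails, "sample_tails"))
  if (n_null < 30) stop("`n_null` must be at least 30", call. = FALSE)
  if (length(size_distribution) == 0) {
    stop("`size_distribution` must be non-empty", call. = FALSE)
  }
  ids <- tails$gene_ids
  xs <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      g <- sample(ids, sample(size_distribution, 1))
      fisher_combine(ssa_pvector(g, tails))$statistic
    }, numeric(1))
  })
  m2 <- 2L * ncol(tails$up_matrix)          # number of combined p-values
  expected <- 2 * m2
  variance <- stats::var(xs)
  if (!is.finite(variance) || variance <= 0) {
    stop("degenerate null variance in Brown calibration", call. = FALSE)
  }
  structure(list(expected = expected, variance = variance,
                 scale = variance / (2 * expected),
                 dof = 2 * expected^2 / variance,
                 n_null = n_null, null_statistics = xs),
            class = "brown_calibration")
}

#' Brown-corrected combined p-value
#'
#' @param X Fisher statistic `-2 * sum(log p)`.
#' @param calibration an [estimate_brown()] result.
#' @return Probability in `(0, 1]`.
#' @export
brown_combine <- function(X, calibration) {
  stopifnot(inherits(calibration, "brown_calibration"))
  stats::pchisq(X / calibration$scale, df = calibration$dof,
                lower.tail = FALSE)
}

#' Single-sample analysis screen of a gene-set library
#'
#' Rows of the input matrix are z-scored, per-sample tails are formed, each
#' set's 2M per-sample hypergeometric p-values are combined by Fisher's
#' method, and one shared Brown calibration (estimated from `n_null` null
#' gene sets matching the library's size distribution) corrects for
#' inter-sample correlation. The minimum pre-combined p-value per set is
#' reported as a diagnostic (`ssa_min_p`).
#'
#' @param matrix genes-by-samples matrix (z-scored internally).
#' @param library gene-set library already restricted to the matrix.
#' @param fraction tail fraction (default 0.05).
#' @param n_null null sets for the Brown calibration (default 1000).
#' @param seed integer seed.
#' @return A data frame with columns `set`, `fisher_statistic`, `fisher_p`,
#'   `brown_p`, `ssa_min_p`; the calibration is in `attr(, "calibration")`.
#' @export
ssa_screen <- function(matrix, library, fraction = 0.05, n_null = 1000,
                       seed = 1) {
  check_expression_matrix(matrix)
  tails <- tail_sets(scale_rows(matrix), fraction)
  calib <- estimate_brown(tails, lengths(library), n_null = n_null,
                          seed = derive_seed(seed, "brown"))
  rows <- lapply(names(library), function(nm) {
    pv <- ssa_pvector(library[[nm]], tails)
    fc <- fisher_combine(pv)
    data.frame(set = nm, fisher_statistic = fc$statistic, fisher_p = fc$p,
               brown_p = brown_combine(fc$statistic, calib),
               ssa_min_p = min(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calibration") <- calib
  out
}
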