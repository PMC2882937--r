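# Coherent-core extraction (the ISA seed) and the EEM-style comparator
# screen: maximal gene subset within a fixed-radius sphere in expression
# space, with an empirical null for significance.

#' Default coherence radius from a correlation floor
#'
#' On per-gene z-scored profiles the squared Euclidean distance between two
#' genes is `2 * (M - 1) * (1 - r)` with `r` their Pearson correlation, so a
#' radius can be stated as the distance equivalent to a minimum correlation
#' `rho0` with the core centroid.
#'
#' @param n_samples number of samples M.
#' @param rho0 correlation floor (default 0.6).
#' @return Numeric radius.
#' @export
default_coherence_radius <- function(n_samples, rho0 = 0.6) {
  sqrt(2 * (n_samples - 1) * (1 - rho0))
}

#' Extract the maximal coherent gene subset of a matrix
#'
#' Greedy sphere search: every member gene in turn is used as the initial
#' centre, and additionally the centroid of the full set (a shrinking start:
#' distant genes drop out first). Membership (genes within `radius` of the
#' centre) and the centre (centroid of the members) are alternately updated
#' until the member set is stable. The full-set start matters because a
#' coherent module's genes can each lie within `radius` of the module
#' centroid while being pairwise farther apart than `radius`, in which case
#' no single-gene start can nucleate the core. The largest stable set over
#' all starts wins; ties are broken by the smallest mean member-to-centre
#' distance, then by input order. No significance is attached to the size
#' here.
#'
#' @param submatrix genes-by-samples matrix restricted to the input gene set,
#'   rows per-gene z-scored.
#' @param radius positive Euclidean radius.
#' @param max_iterations cap on membership/centroid updates per start.
#' @return A list of class `coherent_core`: `genes`, `center`, `radius`,
#'   `mean_distance`.
#' @export
coherent_subset <- function(submatrix, radius, max_iterations = 100) {
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  X <- submatrix
  n <- nrow(X)
  if (is.null(rownames(X)) || n < 1) stop("submatrix must have gene row names", call. = FALSE)
  sq <- rowSums(X^2)
  r2 <- radius^2
  best <- NULL
  search_from <- function(center, fallback_idx) {
    members <- fallback_idx
    for (it in seq_len(max_iterations)) {
      d2 <- sq - 2 * drop(X %*% center) + sum(center^2)
      new_members <- which(d2 <= r2)
      if (length(new_members) == 0) new_members <- fallback_idx
      if (length(new_members) == 0) return(NULL)
      if (identical(new_members, members) && it > 1) break
      members <- new_members
      center <- colMeans(X[members, , drop = FALSE])
    }
    d2 <- sq - 2 * drop(X %*% center) + sum(center^2)
    list(idx = members, center = center,
         mean_dist = mean(sqrt(pmax(d2[members], 0))))
  }
  consider <- function(cand) {
    if (is.null(cand)) return()
    if (is.null(best) ||
        length(cand$idx) > length(best$idx) ||
        (length(cand$idx) == length(best$idx) &&
           cand$mean_dist < best$mean_dist - 1e-12)) {
      best <<- cand
    }
  }
  consider(search_from(colMeans(X), integer(0)))
  for (s in seq_len(n)) {
    consider(search_from(X[s, ], s))
  }
  if (is.null(best)) {
    best <- list(idx = 1L, center = X[1, ], mean_dist = 0)
  }
  structure(list(genes = rownames(X)[best$idx],
                 center = best$center,
                 radius = radius,
                 mean_distance = best$mean_dist),
            class = "coherent_core")
}

#' EEM-style coherence screen of a gene-set library
#'
#' Each set's statistic is the size of its maximal coherent subset in the
#' matrix; significance comes from an empirical null built by running the
#' same extraction on random gene sets of equal size drawn without
#' replacement from the matrix's genes. Null statistics are cached and shared
#' across sets of equal size.
#'
#' @param matrix preprocessed genes-by-samples matrix (rows z-scored).
#' @param library gene-set library already restricted to the matrix.
#' @param radius coherence radius; default [default_coherence_radius()] at
#'   `rho0 = 0.6`.
#' @param n_null number of null draws per set size (default 1000).
#' @param seed master integer seed.
#' @return A data frame with columns `set`, `statistic`, `p`, sorted as the
#'   input library.
#' @export
eem_screen <- function(matrix, library, radius = NULL, n_null = 1000, seed) {
  check_expression_matrix(matrix)
  if (n_null < 1) stop("`n_null` must be at least 1", call. = FALSE)
  if (is.null(radius)) radius <- default_coherence_radius(ncol(matrix))
  genes_all <- rownames(matrix)
  stat <- vapply(library, function(g) {
    length(coherent_subset(matrix[g, , drop = FALSE], radius)$genes)
  }, numeric(1))
  null_cache <- new.env(parent = emptyenv())
  null_for_size <- function(size) {
    key <- as.character(size)
    if (is.null(null_cache[[key]])) {
      sub_seed <- derive_seed(seed, "eem_null", size)
      null_cache[[key]] <- with_seed(sub_seed, {
        vapply(seq_len(n_null), function(i) {
          g <- sample(genes_all, size)
          length(coherent_subset(matrix[g, , drop = FALSE], radius)$genes)
        }, numeric(1))
      })
    }
    null_cache[[key]]
  }
  p <- vapply(seq_along(library), function(i) {
    nulls <- null_for_size(length(library[[i]]))
    (1 + sum(nulls >= stat[i])) / (n_null + 1)
  }, numeric(1))
  data.frame(set = names(library), statistic = stat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}
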