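# Iterative Signature Algorithm: normalized matrix pair, score vectors,
# percentile thresholding, seeded fixed-point iteration.

#' Build the row-/column-normalised matrix pair used by ISA
#'
#' ISA scores samples on a matrix whose rows are z-scored (mean 0, variance 1
#' per gene) and genes on a matrix whose columns are z-scored (per sample).
#'
#' @param matrix genes-by-samples numeric matrix, no constant row or column.
#' @return An object of class `beem_pair` with components `row_normalized`
#'   and `column_normalized` (both genes-by-samples).
#' @export
normalize_pair <- function(matrix) {
  check_expression_matrix(matrix)
  rv <- row_vars(matrix)
  if (any(rv <= .Machine$double.eps)) {
    stop(sprintf("constant gene row(s): %s",
                 paste(utils::head(rownames(matrix)[rv <= .Machine$double.eps], 5),
                       collapse = ", ")), call. = FALSE)
  }
  cv <- row_vars(t(matrix))
  if (any(cv <= .Machine$double.eps)) {
    stop(sprintf("constant sample column(s): %s",
                 paste(utils::head(colnames(matrix)[cv <= .Machine$double.eps], 5),
                       collapse = ", ")), call. = FALSE)
  }
  structure(list(row_normalized = scale_rows(matrix),
                 column_normalized = scale_cols(matrix),
                 gene_ids = rownames(matrix),
                 sample_ids = colnames(matrix)),
            class = "beem_pair")
}

#' An ISA threshold setting
#'
#' @param t_gene gene-threshold fraction in (0,1): on convergence the
#'   bicluster holds approximately `t_gene * N` genes.
#' @param t_sample sample-threshold fraction in (0,1).
#' @param direction `"up"` or `"down"` (down-regulated biclusters are found
#'   by sign-inverting both normalised matrices before iterating).
#' @param max_iterations iteration cap (default 100).
#' @return A list of class `isa_setting`.
#' @export
isa_setting <- function(t_gene, t_sample, direction = c("up", "down"),
                        max_iterations = 100) {
  direction <- match.arg(direction)
  if (!is.numeric(t_gene) || t_gene <= 0 || t_gene >= 1) {
    stop("`t_gene` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(t_sample) || t_sample <= 0 || t_sample >= 1) {
    stop("`t_sample` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (max_iterations < 1) stop("`max_iterations` must be positive", call. = FALSE)
  structure(list(t_gene = t_gene, t_sample = t_sample, direction = direction,
                 max_iterations = as.integer(max_iterations)),
            class = "isa_setting")
}

#' The default 18-setting ISA grid
#'
#' Three gene-threshold fractions crossed with three sample-threshold
#' fractions, each run for up- and down-regulated biclusters.
#'
#' @param t_gene gene-threshold fractions (default 0.05, 0.1, 0.15).
#' @param t_sample sample-threshold fractions (default 0.1, 0.2, 0.3).
#' @param directions bicluster directions (default both).
#' @param max_iterations iteration cap per setting.
#' @return A list of `isa_setting` objects.
#' @export
default_isa_grid <- function(t_gene = c(0.05, 0.1, 0.15),
                             t_sample = c(0.1, 0.2, 0.3),
                             directions = c("up", "down"),
                             max_iterations = 100) {
  grid <- expand.grid(t_gene = t_gene, t_sample = t_sample,
                      direction = directions, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    isa_setting(grid$t_gene[i], grid$t_sample[i], grid$direction[i],
                max_iterations)
  })
}

#' Score samples against a gene indicator set
#'
#' The score of sample j is the mean, over the selected genes, of the
#' row-normalised expression in sample j: how strongly the gene set is
#' up-regulated in that sample.
#'
#' @param pair a `beem_pair`.
#' @param genes character vector of selected gene ids.
#' @return Named numeric vector of length M (samples).
#' @export
sample_scores <- function(pair, genes) {
  if (length(genes) == 0) stop("empty gene indicator", call. = FALSE)
  miss <- setdiff(genes, pair$gene_ids)
  if (length(miss)) {
    stop(sprintf("unknown gene id(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  colMeans(pair$row_normalized[genes, , drop = FALSE])
}

#' Score genes against a sample indicator set
#'
#' The score of gene i is the mean, over the selected samples, of the
#' column-normalised expression of gene i.
#'
#' @param pair a `beem_pair`.
#' @param samples character vector of selected sample ids.
#' @return Named numeric vector of length N (genes).
#' @export
gene_scores <- function(pair, samples) {
  if (length(samples) == 0) stop("empty sample indicator", call. = FALSE)
  miss <- setdiff(samples, pair$sample_ids)
  if (length(miss)) {
    stop(sprintf("unknown sample id(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  rowMeans(pair$column_normalized[, samples, drop = FALSE])
}

#' Select the top fraction of a score vector by percentile threshold
#'
#' The threshold is the `(1 - fraction)` empirical quantile (type 7,
#' linear interpolation) of the scores; elements strictly greater than the
#' threshold are selected, so approximately `fraction * length` elements come
#' back. With heavily tied scores the selection can be empty, which upstream
#' iteration reports as non-convergence.
#'
#' @param scores named numeric vector.
#' @param fraction target selected fraction in (0,1).
#' @return Character vector of selected names.
#' @export
threshold_select <- function(scores, fraction) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  thr <- stats::quantile(scores, probs = 1 - fraction, type = 7, names = FALSE)
  names(scores)[scores > thr]
}

#' Run seeded ISA to a fixed point
#'
#' Starting from a seed gene set, alternates sample scoring/thresholding and
#' gene scoring/thresholding until the gene set stops changing. A recurring
#' (non-adjacent) gene set indicates an oscillation and is reported as
#' non-convergence, as is an empty selection at any step or reaching the
#' iteration cap. For `direction = "down"` both normalised matrices are
#' sign-inverted before iterating.
#'
#' @param pair a `beem_pair`.
#' @param seed_genes non-empty character vector of seed gene ids.
#' @param setting an [isa_setting()].
#' @return A list of class `bicluster`: `genes`, `samples`, `direction`,
#'   `converged`, `iterations`.
#' @export
run_isa <- function(pair, seed_genes, setting) {
  stopifnot(inherits(pair, "beem_pair"), inherits(setting, "isa_setting"))
  if (length(seed_genes) == 0) stop("empty seed gene set", call. = FALSE)
  if (setting$direction == "down") {
    pair <- structure(list(row_normalized = -pair$row_normalized,
                           column_normalized = -pair$column_normalized,
                           gene_ids = pair$gene_ids,
                           sample_ids = pair$sample_ids),
                      class = "beem_pair")
  }
  failed <- function(iter) {
    structure(list(genes = character(0), samples = character(0),
                   direction = setting$direction, converged = FALSE,
                   iterations = iter), class = "bicluster")
  }
  genes <- sort(unique(seed_genes))
  seen <- new.env(parent = emptyenv())
  assign(paste(genes, collapse = "\r"), 0L, envir = seen)
  samples <- character(0)
  for (iter in seq_len(setting$max_iterations)) {
    sc <- sample_scores(pair, genes)
    samples <- threshold_select(sc, setting$t_sample)
    if (length(samples) == 0) return(failed(iter))
    gs <- gene_scores(pair, samples)
    new_genes <- sort(threshold_select(gs, setting$t_gene))
    if (length(new_genes) == 0) return(failed(iter))
    if (identical(new_genes, genes)) {
      return(structure(list(genes = new_genes, samples = samples,
                            direction = setting$direction, converged = TRUE,
                            iterations = iter), class = "bicluster"))
    }
    key <- paste(new_genes, collapse = "\r")
    if (!is.null(seen[[key]])) return(failed(iter))  # cycle, not a fixed point
    assign(key, iter, envir = seen)
    genes <- new_genes
  }
  failed(setting$max_iterations)
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("ISA bicluster (%s): %d genes x %d samples; %s after %d iteration(s)\n",
              x$direction, length(x$genes), length(x$samples),
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}
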