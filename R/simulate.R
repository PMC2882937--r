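# Simulation models of expression modules, labelled benchmark libraries,
# and the AUC benchmark comparing the three screening methods.

#' Simulate a coherent-module expression matrix
#'
#' Non-overlapping modules of genes co-expressed across ALL samples. Each
#' module's anchor gene is standard normal across samples; every other
#' member is `signal * anchor + sqrt(1 - signal^2) * noise`, so members stay
#' marginally standard normal with correlation `signal` to the anchor.
#' Remaining genes are i.i.d. standard normal background.
#'
#' @param n_genes total genes (default 4000).
#' @param n_samples samples (default 100).
#' @param n_modules number of modules (default 20); must satisfy
#'   `n_modules * module_size <= n_genes`.
#' @param module_size genes per module (default 200).
#' @param signal correlation-strength parameter rho in `[0, 1]`.
#' @param seed integer seed.
#' @return A list of class `simulated_dataset`: `matrix`, `modules` (named
#'   list of gene-id vectors), `model = "coherent"`, and the parameters.
#' @export
simulate_coherent <- function(n_genes = 4000, n_samples = 100, n_modules = 20,
                              module_size = 200, signal, seed = 1) {
  stopifnot(signal >= 0, signal <= 1)
  if (n_modules * module_size > n_genes) {
    stop("modules are non-overlapping: need n_modules * module_size <= n_genes",
         call. = FALSE)
  }
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  mat <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    for (m in seq_len(n_modules)) {
      rows <- (m - 1) * module_size + seq_len(module_size)
      anchor <- x[rows[1], ]
      eps <- matrix(stats::rnorm((module_size - 1) * n_samples),
                    module_size - 1, n_samples)
      x[rows[-1], ] <- signal * matrix(anchor, module_size - 1, n_samples,
                                       byrow = TRUE) +
        sqrt(1 - signal^2) * eps
    }
    x
  })
  dimnames(mat) <- list(gene_ids, sample_ids)
  modules <- lapply(seq_len(n_modules), function(m) {
    gene_ids[(m - 1) * module_size + seq_len(module_size)]
  })
  names(modules) <- sprintf("module%02d", seq_len(n_modules))
  structure(list(matrix = mat, modules = modules, sample_sets = NULL,
                 model = "coherent", signal = signal, seed = seed),
            class = "simulated_dataset")
}

#' Simulate a planted-bicluster expression matrix
#'
#' Modules are gene-by-sample blocks: each module draws `module_size` genes
#' and `floor(sample_ratio * n_samples)` samples uniformly (modules may
#' overlap in genes and samples). An entry inside any module's block is
#' drawn as `signal + N(0,1)` (once, even when blocks overlap); all other
#' entries are standard normal.
#'
#' @inheritParams simulate_coherent
#' @param n_modules number of planted biclusters (default 50).
#' @param sample_ratio fraction q of samples per bicluster, in (0,1).
#' @param signal mean shift mu inside the blocks.
#' @return A `simulated_dataset` with `sample_sets` (per-module sample ids).
#' @export
simulate_bicluster <- function(n_genes = 4000, n_samples = 100, n_modules = 50,
                               module_size = 200, sample_ratio, signal,
                               seed = 1) {
  stopifnot(sample_ratio > 0, sample_ratio < 1, signal >= 0)
  n_block_samples <- floor(sample_ratio * n_samples)
  if (n_block_samples < 1) stop("`sample_ratio` selects no samples", call. = FALSE)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  out <- with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    z <- matrix(FALSE, n_genes, n_samples)
    modules <- vector("list", n_modules)
    sample_sets <- vector("list", n_modules)
    for (m in seq_len(n_modules)) {
      rows <- sample.int(n_genes, module_size)
      cols <- sample.int(n_samples, n_block_samples)
      z[rows, cols] <- TRUE
      modules[[m]] <- sort(rows)
      sample_sets[[m]] <- sort(cols)
    }
    x[z] <- x[z] + signal
    list(x = x, modules = modules, sample_sets = sample_sets)
  })
  mat <- out$x
  dimnames(mat) <- list(gene_ids, sample_ids)
  modules <- lapply(out$modules, function(r) gene_ids[r])
  sample_sets <- lapply(out$sample_sets, function(cc) sample_ids[cc])
  names(modules) <- names(sample_sets) <- sprintf("module%02d", seq_len(n_modules))
  structure(list(matrix = mat, modules = modules, sample_sets = sample_sets,
                 model = "bicluster", signal = signal,
                 sample_ratio = sample_ratio, seed = seed),
            class = "simulated_dataset")
}

#' Build a labelled positive/negative gene-set library for benchmarking
#'
#' Each positive set takes `floor(purity * size)` genes from one planted
#' module (modules drawn without replacement while enough remain) plus
#' random fill from the remaining genes; each negative set is a uniform
#' random draw. All sets have identical size.
#'
#' @param dataset a `simulated_dataset`.
#' @param n_pos,n_neg numbers of positive and negative sets (default 10
#'   each).
#' @param size set size (default 200).
#' @param purity fraction r of module genes in each positive set, in [0,1].
#' @param seed integer seed.
#' @return A gene-set library (named list) with a `labels` attribute.
#' @export
make_labeled_library <- function(dataset, n_pos = 10, n_neg = 10, size = 200,
                                 purity, seed = 1) {
  stopifnot(inherits(dataset, "simulated_dataset"), purity >= 0, purity <= 1)
  genes_all <- rownames(dataset$matrix)
  if (size > length(genes_all)) {
    stop("`size` exceeds the number of simulated genes", call. = FALSE)
  }
  n_module_genes <- floor(purity * size)
  with_seed(seed, {
    module_idx <- if (length(dataset$modules) >= n_pos) {
      sample(seq_along(dataset$modules), n_pos)
    } else {
      sample(seq_along(dataset$modules), n_pos, replace = TRUE)
    }
    sets <- vector("list", n_pos + n_neg)
    for (i in seq_len(n_pos)) {
      mod <- dataset$modules[[module_idx[i]]]
      core <- sample(mod, min(n_module_genes, length(mod)))
      fill <- sample(setdiff(genes_all, core), size - length(core))
      sets[[i]] <- c(core, fill)
    }
    for (i in seq_len(n_neg)) {
      sets[[n_pos + i]] <- sample(genes_all, size)
    }
    names(sets) <- c(sprintf("positive%02d", seq_len(n_pos)),
                     sprintf("negative%02d", seq_len(n_neg)))
    attr(sets, "labels") <- stats::setNames(
      rep(c("positive", "negative"), c(n_pos, n_neg)), names(sets))
    sets
  })
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outscores a random negative, with
#' midrank handling of ties (the normalised Mann-Whitney statistic). Larger
#' scores mean more significant.
#'
#' @param scores numeric scores (e.g. `-log10 p`).
#' @param labels character vector of `"positive"`/`"negative"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) {
    stop("both positive and negative labels are required", call. = FALSE)
  }
  r <- rank(scores)  # midranks on ties
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Monte Carlo AUC benchmark of BEEM, EEM and SSA
#'
#' Per trial a fresh simulated data set and labelled library are generated,
#' each requested method screens the library, sets are scored by
#' `-log10 p`, and the ROC AUC against the planted labels is recorded.
#'
#' @param model `"coherent"` or `"bicluster"`.
#' @param signal model signal strength (rho or mu).
#' @param sample_ratio bicluster-model sample fraction q (ignored for the
#'   coherent model).
#' @param purity positive-set purity r (default 0.8).
#' @param n_genes,n_samples,n_modules,module_size matrix scale; defaults
#'   follow the models' standard protocol (4000 x 100; 20 or 50 modules of
#'   200).
#' @param set_size library set size (default 200).
#' @param n_trials Monte Carlo trials (default 20).
#' @param methods subset of `c("beem", "eem", "ssa")`.
#' @param grid ISA grid for the BEEM screen (default [default_isa_grid()]).
#' @param n_null null draws for BEEM/EEM p-values and the Brown calibration.
#' @param radius coherence radius (default [default_coherence_radius()]).
#' @param p1_threshold BEEM hypergeometric screen threshold.
#' @param seed master integer seed.
#' @return A list: `mean_auc` (named numeric) and `auc` (trials x methods
#'   matrix).
#' @export
benchmark_methods <- function(model = c("coherent", "bicluster"), signal,
                              sample_ratio = 0.2, purity = 0.8,
                              n_genes = 4000, n_samples = 100,
                              n_modules = NULL, module_size = 200,
                              set_size = 200, n_trials = 20,
                              methods = c("beem", "eem", "ssa"),
                              grid = default_isa_grid(), n_null = 1000,
                              radius = NULL, p1_threshold = 1e-2, seed = 1) {
  model <- match.arg(model)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(n_modules)) n_modules <- if (model == "coherent") 20 else 50
  auc <- matrix(NA_real_, n_trials, length(methods),
                dimnames = list(NULL, methods))
  for (trial in seq_len(n_trials)) {
    ds_seed <- derive_seed(seed, "dataset", model, trial)
    dataset <- if (model == "coherent") {
      simulate_coherent(n_genes, n_samples, n_modules, module_size,
                        signal = signal, seed = ds_seed)
    } else {
      simulate_bicluster(n_genes, n_samples, n_modules, module_size,
                         sample_ratio = sample_ratio, signal = signal,
                         seed = ds_seed)
    }
    library <- make_labeled_library(dataset, size = set_size, purity = purity,
                                    seed = derive_seed(seed, "library", trial))
    labels <- gene_set_labels(library)
    mat <- scale_rows(dataset$matrix)
    for (meth in methods) {
      m_seed <- derive_seed(seed, meth, trial)
      p <- switch(meth,
        beem = {
          res <- beem_screen(mat, library, grid = grid, radius = radius,
                             p1_threshold = p1_threshold, n_null = n_null,
                             seed = m_seed)
          stats::setNames(res$p_final, res$set)[names(library)]
        },
        eem = {
          res <- eem_screen(mat, library, radius = radius, n_null = n_null,
                            seed = m_seed)
          stats::setNames(res$p, res$set)[names(library)]
        },
        ssa = {
          res <- ssa_screen(mat, library, n_null = max(n_null, 30),
                            seed = m_seed)
          stats::setNames(res$brown_p, res$set)[names(library)]
        })
      auc[trial, meth] <- roc_auc(-log10(p), labels[names(library)])
    }
  }
  list(mean_auc = colMeans(auc), auc = auc)
}
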