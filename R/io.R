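# Reading, writing and preprocessing of genes-by-samples expression tables.

#' Read an expression matrix from a delimited table
#'
#' Accepts a plain tab-separated table (header row of sample identifiers, one
#' row per gene with the gene identifier in column 1) or a GCT v1.2 file
#' ("#1.2" preamble, dimensions line, then `Name`/`Description` columns before
#' the samples; the description column is ignored).
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @return A numeric genes-by-samples matrix with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression_table <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (is.character(path) && !file.exists(path)) {
    stop(sprintf("expression file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
      stop("not a GCT v1.2 file: missing '#1.2' preamble", call. = FALSE)
    }
    lines <- lines[-c(1, 2)]
    drop_desc <- TRUE
  } else {
    drop_desc <- FALSE
  }
  if (length(lines) < 2) stop("expression table has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  id_cols <- if (drop_desc) 2L else 1L
  sample_ids <- header[-seq_len(id_cols)]
  body <- fields[-1]
  gene_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene identifier: '%s'",
                 gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  }
  n <- length(gene_ids)
  m <- length(sample_ids)
  values <- matrix(NA_real_, n, m, dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(n)) {
    row <- body[[i]][-seq_len(id_cols)]
    if (length(row) != m) {
      stop(sprintf("row %d ('%s') has %d values, expected %d",
                   i, gene_ids[i], length(row), m), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(row))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   row[j], gene_ids[i], sample_ids[j]), call. = FALSE)
    }
    values[i, ] <- v
  }
  values
}

#' Write an expression matrix as a tab-separated table
#'
#' @param matrix genes-by-samples numeric matrix.
#' @param path output path.
#' @param id_header name of the leading identifier column.
#' @export
write_expression_table <- function(matrix, path, id_header = "gene") {
  check_expression_matrix(matrix)
  header <- paste(c(id_header, colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], format(matrix[i, ], digits = 15, trim = TRUE,
                                        scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Collapse probe-level rows to gene symbols
#'
#' When several probes map to one symbol, the probe with the largest row
#' variance across samples is kept and renamed to the symbol; ties are broken
#' by input order (first probe wins). Probes absent from the map are dropped.
#'
#' @param matrix probes-by-samples numeric matrix.
#' @param probe_to_symbol named character vector, names = probe ids,
#'   values = gene symbols.
#' @return A genes-by-samples matrix with symbol row names.
#' @export
collapse_probes <- function(matrix, probe_to_symbol) {
  check_expression_matrix(matrix)
  keep <- rownames(matrix) %in% names(probe_to_symbol)
  matrix <- matrix[keep, , drop = FALSE]
  if (nrow(matrix) == 0) stop("no probes left after mapping", call. = FALSE)
  symbols <- unname(probe_to_symbol[rownames(matrix)])
  vars <- row_vars(matrix)
  # which.max is stable: first index of the maximum, so earlier probes win ties
  pick <- vapply(split(seq_len(nrow(matrix)), factor(symbols, levels = unique(symbols))),
                 function(idx) idx[which.max(vars[idx])], integer(1))
  out <- matrix[pick, , drop = FALSE]
  rownames(out) <- unique(symbols)
  out
}

#' Preprocess an expression matrix for module screening
#'
#' Fixed pipeline: (1) optional log transform; (2) per-sample normalisation to
#' mean 0 and variance 1; (3) retention of the `n_top` rows of highest
#' variance (all rows when fewer); (4) per-gene normalisation of the retained
#' rows. Zero-variance rows that cannot be z-scored at step 4 are dropped with
#' a warning; an error is raised only if that would empty the matrix.
#'
#' @param matrix genes-by-samples numeric matrix.
#' @param n_top number of highest-variance genes to retain (default 8000).
#' @param log_transform take logarithms first (requires all values > 0).
#' @param log_base base of the logarithm (default natural log).
#' @return A genes-by-samples matrix of per-gene z-scores.
#' @export
preprocess_expression <- function(matrix, n_top = 8000, log_transform = TRUE,
                                  log_base = exp(1)) {
  check_expression_matrix(matrix)
  if (log_transform) {
    if (any(matrix <= 0)) {
      stop("log transform requires all values > 0", call. = FALSE)
    }
    matrix <- log(matrix, base = log_base)
  }
  matrix <- scale_cols(matrix)
  vars <- row_vars(matrix)
  if (nrow(matrix) > n_top) {
    keep <- order(vars, decreasing = TRUE)[seq_len(n_top)]
    matrix <- matrix[sort(keep), , drop = FALSE]
    vars <- vars[sort(keep)]
  }
  zero <- vars <= .Machine$double.eps
  if (any(zero)) {
    if (all(zero)) {
      stop(sprintf("all retained genes are constant: %s",
                   paste(rownames(matrix)[zero], collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("dropping %d constant gene row(s): %s", sum(zero),
                    paste(utils::head(rownames(matrix)[zero], 5), collapse = ", ")),
            call. = FALSE)
    matrix <- matrix[!zero, , drop = FALSE]
  }
  scale_rows(matrix)
}

#' Permute the gene labels of an expression matrix
#'
#' Row values are untouched; the gene identifiers are reassigned by a uniform
#' random permutation. Used to build null data sets that preserve the full
#' expression structure while destroying any gene-set association.
#'
#' @param matrix genes-by-samples numeric matrix.
#' @param seed integer seed (deterministic output).
#' @return The same matrix with permuted row names.
#' @export
permute_gene_labels <- function(matrix, seed) {
  check_expression_matrix(matrix)
  perm <- with_seed(seed, sample.int(nrow(matrix)))
  rownames(matrix) <- rownames(matrix)[perm]
  matrix
}
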