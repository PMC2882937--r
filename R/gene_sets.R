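# Gene-set libraries: GMT parsing/writing, restriction to a matrix, labels.
#
# A library is a named list of character vectors (set name -> member gene
# ids). Optional attributes: "descriptions" (named character) and "labels"
# (named character with values "positive"/"negative", used by benchmarks).

#' Read a gene-set library from a GMT file
#'
#' One set per line: name TAB description TAB member TAB member ... Duplicate
#' members within a line are stored once (first occurrence kept).
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop(sprintf("GMT file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  names_out <- character(length(fields))
  desc <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    names_out[i] <- f[1]
    desc[i] <- f[2]
    sets[[i]] <- unique(f[-c(1, 2)])
  }
  if (anyDuplicated(names_out)) {
    stop(sprintf("duplicate gene-set name: '%s'",
                 names_out[duplicated(names_out)][1]), call. = FALSE)
  }
  names(sets) <- names_out
  names(desc) <- names_out
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set library to a GMT file
#'
#' @param library named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to the library's `descriptions` attribute or empty strings.
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(library, "descriptions")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(library)), names(library))
  }
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "", library[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Restrict a library to a matrix's genes and drop small sets
#'
#' Each set is intersected with the matrix's gene identifiers; sets whose
#' intersection has fewer than `min_size` members are removed (strictly "less
#' than", so a set with exactly `min_size` genes present is retained).
#'
#' @param library named list of character vectors.
#' @param matrix genes-by-samples matrix (or a character vector of gene ids).
#' @param min_size minimum post-restriction size (default 10).
#' @return The filtered library, original order preserved; labels and
#'   descriptions attributes are subset accordingly.
#' @export
restrict_and_filter <- function(library, matrix, min_size = 10) {
  genes <- if (is.character(matrix)) matrix else rownames(matrix)
  restricted <- lapply(library, function(s) s[s %in% genes])
  keep <- lengths(restricted) >= min_size
  if (!any(keep)) {
    stop("no gene set retains at least `min_size` genes in the matrix",
         call. = FALSE)
  }
  out <- restricted[keep]
  for (a in c("descriptions", "labels")) {
    v <- attr(library, a)
    if (!is.null(v)) attr(out, a) <- v[names(out)]
  }
  out
}

#' Positive/negative labels of a benchmark library
#'
#' @param library a gene-set library produced by [make_labeled_library()].
#' @return Named character vector of `"positive"`/`"negative"`.
#' @export
gene_set_labels <- function(library) {
  attr(library, "labels")
}
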