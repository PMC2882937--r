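# Post-screening interpretation of discovered modules: activity profiles,
# module-overlap significance, annotation enrichment, and redundancy
# clustering of position weight matrices by Kullback-Leibler distance.

#' Activity profile of a module
#'
#' The per-sample mean of the module genes' (normalised) expression: a
#' length-M vector showing in which samples the module is up- or
#' down-regulated.
#'
#' @param matrix genes-by-samples matrix.
#' @param module non-empty character vector of member gene ids.
#' @return Named numeric vector of length M.
#' @export
activity_profile <- function(matrix, module) {
  check_expression_matrix(matrix)
  if (length(module) == 0) stop("empty module", call. = FALSE)
  miss <- setdiff(module, rownames(matrix))
  if (length(miss)) {
    stop(sprintf("unknown gene id(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  colMeans(matrix[module, , drop = FALSE])
}

#' Activity profiles of several modules as a matrix
#'
#' @param matrix genes-by-samples matrix.
#' @param modules named list of gene-id vectors.
#' @return A modules-by-samples numeric matrix.
#' @export
activity_profiles <- function(matrix, modules) {
  out <- t(vapply(modules, function(m) activity_profile(matrix, m),
                  numeric(ncol(matrix))))
  colnames(out) <- colnames(matrix)
  out
}

#' Pairwise module-overlap significance matrix
#'
#' Entry (i, j) is the upper-tail hypergeometric p-value of the overlap
#' between modules i and j in a population of `population` genes, shown as
#' `-log10 p` and capped at `cap`; the diagonal is set to the cap by
#' convention. Symmetric.
#'
#' @param modules named list of gene-id vectors.
#' @param population population (universe) size N.
#' @param cap cap on `-log10 p` (default 10).
#' @return A symmetric modules-by-modules numeric matrix.
#' @export
overlap_pmatrix <- function(modules, population, cap = 10) {
  n <- length(modules)
  out <- matrix(cap, n, n, dimnames = list(names(modules), names(modules)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- length(intersect(modules[[i]], modules[[j]]))
      p <- hypergeometric_tail(population, length(modules[[i]]),
                               length(modules[[j]]), k)
      out[i, j] <- out[j, i] <- min(cap, -log10(p))
    }
  }
  out
}

#' Hypergeometric enrichment of a module against an annotation library
#'
#' One upper-tail hypergeometric p-value per annotation term; no
#' multiple-testing correction is applied here (apply e.g.
#' [stats::p.adjust()] downstream as needed).
#'
#' @param module character vector of gene ids.
#' @param annotations named list of term gene-id vectors.
#' @param universe universe size N (module and terms assumed inside it).
#' @return A data frame with columns `term`, `term_size`, `overlap`, `p`.
#' @export
enrichment_test <- function(module, annotations, universe) {
  rows <- lapply(names(annotations), function(nm) {
    term <- annotations[[nm]]
    k <- length(intersect(module, term))
    data.frame(term = nm, term_size = length(term), overlap = k,
               p = hypergeometric_tail(universe, length(term),
                                       length(module), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- position weight matrices ------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param name motif name.
#' @param probs L x 4 matrix of base probabilities (columns A, C, G, T);
#'   rows are renormalised to sum to 1.
#' @return A list of class `pwm`.
#' @export
pwm <- function(name, probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("a PWM needs 4 base columns", call. = FALSE)
  if (any(probs < 0)) stop("PWM probabilities must be non-negative", call. = FALSE)
  s <- rowSums(probs)
  if (any(s <= 0)) stop("each PWM position needs positive total weight", call. = FALSE)
  probs <- probs / s
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, probs = probs), class = "pwm")
}

#' Read PWMs from a TRANSFAC-like plain matrix file
#'
#' Blocks introduced by an identifier line (`ID name` or `DE name` or
#' `>name`), followed by numbered rows of four counts/probabilities
#' (position, A, C, G, T), terminated by `//` or the next identifier.
#'
#' @param path file path.
#' @return A list of `pwm` objects.
#' @export
read_transfac <- function(path) {
  lines <- trimws(readLines(path))
  pwms <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(name) && length(rows)) {
      pwms[[length(pwms) + 1]] <<- pwm(name, do.call(rbind, rows))
    }
    rows <<- list()
  }
  for (ln in lines) {
    if (ln == "" || ln == "//" || startsWith(ln, "XX")) next
    if (grepl("^(ID|DE)\\s+", ln)) {
      flush(); name <- sub("^(ID|DE)\\s+", "", ln)
    } else if (startsWith(ln, ">")) {
      flush(); name <- trimws(sub("^>", "", ln))
    } else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      rows[[length(rows) + 1]] <- as.numeric(f[2:5])
    } else if (grepl("^P0", ln)) {
      next  # column-header line
    }
  }
  flush()
  if (!length(pwms)) stop("no PWM blocks found", call. = FALSE)
  pwms
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#'
#' @param path file path.
#' @return A list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  pwms <- list()
  i <- 1
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      name <- strsplit(lines[i], "\\s+")[[1]][2]
      while (i <= length(lines) &&
             !startsWith(lines[i], "letter-probability matrix")) i <- i + 1
      if (i > length(lines)) break
      i <- i + 1
      rows <- list()
      while (i <= length(lines) && grepl("^[0-9.eE+-]", lines[i])) {
        rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
        i <- i + 1
      }
      pwms[[length(pwms) + 1]] <- pwm(name, do.call(rbind, rows))
    } else {
      i <- i + 1
    }
  }
  if (!length(pwms)) stop("no MOTIF blocks found", call. = FALSE)
  pwms
}

#' Kullback-Leibler distance between two PWMs
#'
#' Minimum over ungapped offsets (requiring at least `min_overlap` aligned
#' positions) of the total per-column symmetric KL divergence
#' `KL(p||q) + KL(q||p)` across the aligned columns, computed on
#' pseudocount-smoothed (`pseudocount`, renormalised) probabilities with
#' natural logarithms.
#'
#' @param a,b `pwm` objects.
#' @param pseudocount smoothing added to every probability (default 0.01).
#' @param min_overlap minimum aligned columns (default 4).
#' @return Non-negative distance.
#' @export
pwm_distance <- function(a, b, pseudocount = 0.01, min_overlap = 4) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  pa <- a$probs; pb <- b$probs
  if (nrow(pa) < min_overlap || nrow(pb) < min_overlap) {
    stop(sprintf("PWMs must have at least %d positions", min_overlap),
         call. = FALSE)
  }
  smooth <- function(p) {
    p <- p + pseudocount
    p / rowSums(p)
  }
  pa <- smooth(pa); pb <- smooth(pb)
  la <- nrow(pa); lb <- nrow(pb)
  best <- Inf
  for (offset in seq(-(lb - min_overlap), la - min_overlap)) {
    ia <- max(1, 1 + offset):min(la, lb + offset)
    ib <- ia - offset
    x <- pa[ia, , drop = FALSE]; y <- pb[ib, , drop = FALSE]
    d <- sum(x * log(x / y) + y * log(y / x))
    if (d < best) best <- d
  }
  best
}

#' Greedy redundancy clustering of PWMs by KL distance
#'
#' The input must be sorted by ascending p-value (most significant first).
#' Repeatedly the most significant remaining motif becomes a new cluster's
#' representative, and every remaining motif within `cutoff` of it joins
#' that cluster, until the list is empty. Output clusters partition the
#' input.
#'
#' @param pwms list of `pwm` objects, pre-sorted by significance.
#' @param cutoff KL distance cutoff (default 15) discriminating cognate
#'   from non-cognate motif pairs under [pwm_distance()].
#' @param pseudocount,min_overlap passed to [pwm_distance()].
#' @return A list of clusters; each is a list with `representative` (motif
#'   name) and `members` (character vector of motif names, representative
#'   first).
#' @export
pwm_kl_cluster <- function(pwms, cutoff = 15, pseudocount = 0.01,
                           min_overlap = 4) {
  if (length(pwms) == 0) stop("empty PWM list", call. = FALSE)
  remaining <- pwms
  clusters <- list()
  while (length(remaining)) {
    rep_pwm <- remaining[[1]]
    remaining <- remaining[-1]
    if (length(remaining)) {
      d <- vapply(remaining, pwm_distance, numeric(1), b = rep_pwm,
                  pseudocount = pseudocount, min_overlap = min_overlap)
      near <- d < cutoff
    } else {
      near <- logical(0)
    }
    members <- c(rep_pwm$name,
                 vapply(remaining[near], `[[`, character(1), "name"))
    remaining <- remaining[!near]
    clusters[[length(clusters) + 1]] <- list(representative = rep_pwm$name,
                                             members = members)
  }
  clusters
}
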