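# Side-information similarity matrices for the collaborative filter:
# cell lines compared by cosine similarity of expression profiles, drugs by
# the Tanimoto coefficient of their binary structural fingerprints.

similarity_matrix <- function(values, metric) {
  values <- (values + t(values)) / 2  # kill floating asymmetry
  diag(values) <- 1
  structure(list(values = values, metric = metric, ids = rownames(values)),
            class = "similarity_matrix")
}

#' Cell-line cosine similarity on expression profiles
#'
#' Computes `W[i, j] = <x_i, x_j> / (||x_i|| * ||x_j||)` over the gene
#' expression vectors of each pair of cell lines. Profiles are used raw by
#' default; `center = TRUE` subtracts each profile's mean first (giving a
#' correlation-like similarity, which may be negative).
#'
#' @param x an [omics_matrix()] (genes x cell lines).
#' @param center centre each cell-line profile before computing cosines.
#' @return A `similarity_matrix` (cell lines x cell lines, unit diagonal).
#' @export
cosine_cell_similarity <- function(x, center = FALSE) {
  stopifnot(inherits(x, "omics_matrix"))
  m <- x$values
  if (ncol(m) < 2L) abort("Need at least 2 cell lines.")
  if (center) m <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  zero <- nrm == 0
  if (any(zero)) {
    abort(paste0("Zero-norm expression profile for cell line(s): ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  w <- crossprod(sweep(m, 2, nrm, "/"))
  w <- pmin(pmax(w, -1), 1)
  similarity_matrix(w, "cosine")
}

#' Drug Tanimoto similarity on binary fingerprints
#'
#' `W[i, j] = |a AND b| / |a OR b|` over the drugs' fingerprint bit vectors.
#'
#' @param f a [fingerprint_matrix()].
#' @return A `similarity_matrix` (drugs x drugs, values in \[0, 1\]).
#' @export
tanimoto_drug_similarity <- function(f) {
  stopifnot(inherits(f, "fingerprint_matrix"))
  b <- f$bits
  if (nrow(b) < 2L) abort("Need at least 2 drugs.")
  nset <- rowSums(b)
  if (any(nset == 0)) {
    abort(paste0("All-zero fingerprint for drug(s): ",
                 paste(rownames(b)[nset == 0], collapse = ", ")))
  }
  common <- tcrossprod(b)
  union <- outer(nset, nset, "+") - common
  similarity_matrix(common / union, "tanimoto")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix metric=%s: %d x %d>\n",
              x$metric, nrow(x$values), ncol(x$values)))
  invisible(x)
}
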