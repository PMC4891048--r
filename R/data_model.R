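#' @importFrom rlang .data abort warn inform
#' @importFrom stats cor pnorm phyper quantile rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

# ---- constructors -----------------------------------------------------------

#' Construct an omics matrix (expression or copy number)
#'
#' A gene x cell-line numeric matrix with a declared kind. Expression values
#' are expected in log2 array units, CNV in copy-number (or log-ratio) units.
#'
#' @param values numeric matrix, genes in rows (rownames), cell lines in
#'   columns (colnames).
#' @param kind `"expression"` or `"cnv"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, kind = c("expression", "cnv")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  check_id_matrix(values, what = kind)
  structure(list(kind = kind, values = values), class = "omics_matrix")
}

#' Construct a drug x cell-line response matrix in pIC50 units
#'
#' Holds the (possibly incomplete) sensitivity panel: rows are drugs, columns
#' cell lines, entries pIC50 = -log10(IC50 in molar). Missing measurements are
#' carried in a logical `observed` mask of the same shape.
#'
#' @param values numeric matrix (drugs x cell lines); entries at unobserved
#'   positions may be `NA`.
#' @param observed logical mask, same shape; defaults to `!is.na(values)`.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, observed = NULL) {
  values <- as.matrix(values)
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(values))) {
    abort("`observed` mask must have the same shape as `values`.")
  }
  if (nrow(values) == 0L && is.null(rownames(values))) {
    dimnames(values) <- list(character(0), colnames(values))
    dimnames(observed) <- dimnames(values)
  }
  check_ids(rownames(values), "drug", nrow(values))
  check_ids(colnames(values), "cell line", ncol(values))
  if (any(!is.finite(values[observed]))) {
    abort("Response matrix has non-finite values at observed positions.")
  }
  values[!observed] <- NA_real_
  structure(list(values = values, observed = observed),
            class = "response_matrix")
}

#' Construct a drug fingerprint matrix
#'
#' Binary structural fingerprints (e.g. the 881-bit PubChem keys), drugs in
#' rows.
#'
#' @param bits binary matrix (drugs x n_bits) with drug rownames.
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(bits) {
  bits <- as.matrix(bits)
  check_ids(rownames(bits), "drug")
  if (ncol(bits) < 1L) abort("Fingerprint length must be positive.")
  if (!all(bits %in% c(0, 1))) {
    abort("Fingerprint entries must all be 0 or 1.")
  }
  storage.mode(bits) <- "double"
  structure(list(bits = bits, n_bits = ncol(bits)),
            class = "fingerprint_matrix")
}

#' Construct a mutation call table
#'
#' @param df data frame with columns `gene`, `cell_line`, `effect_class`
#'   (each `"silent"` or `"nonsilent"`).
#' @return A tibble of class `mutation_table`.
#' @export
mutation_table <- function(df) {
  need <- c("gene", "cell_line", "effect_class")
  if (!all(need %in% names(df))) {
    abort(paste0("Mutation table needs columns: ", paste(need, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)[need]
  bad <- setdiff(unique(df$effect_class), c("silent", "nonsilent"))
  if (length(bad)) {
    abort(paste0("Unknown effect_class value(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df)) abort("Duplicate (gene, cell_line, effect_class) records.")
  class(df) <- c("mutation_table", class(df))
  df
}

#' Construct a panel annotation
#'
#' Maps each cell line to its cancer type and each drug to its target gene
#' set; used to stratify signature selection and the resistance screen.
#'
#' @param cell_types named character vector: names are cell-line ids, values
#'   cancer-type labels.
#' @param drug_targets named list: names are drug ids, values character
#'   vectors of target genes. Optional.
#' @return An object of class `panel_annotation`.
#' @export
panel_annotation <- function(cell_types, drug_targets = list()) {
  if (anyDuplicated(names(cell_types))) {
    abort("A cell line is annotated more than once.")
  }
  structure(list(cell_types = cell_types, drug_targets = drug_targets),
            class = "panel_annotation")
}

check_ids <- function(ids, what, n = NULL) {
  if (is.null(ids)) {
    if (!is.null(n) && n == 0L) return(invisible(character(0)))
    abort(paste0("Missing ", what, " ids (dimnames)."))
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate ", what, " id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

check_id_matrix <- function(values, what) {
  check_ids(rownames(values), paste0(what, " gene"))
  check_ids(colnames(values), "cell line")
  if (any(!is.finite(values))) {
    abort(paste0("Non-finite values in ", what, " matrix."))
  }
  invisible(values)
}

# ---- readers ----------------------------------------------------------------

read_tsv_matrix <- function(path, allow_missing = FALSE) {
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               row.names = NULL, colClasses = "character",
               na.strings = character(0)),
    error = function(e) abort(paste0("Malformed TSV '", path, "': ", conditionMessage(e)))
  )
  if (ncol(df) < 2L) abort(paste0("Matrix TSV '", path, "' needs row ids plus >=1 data column."))
  row_ids <- df[[1]]
  check_ids(row_ids, "row")
  check_ids(colnames(df)[-1], "column")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "NA"] <- ""
  blank <- m == ""
  if (any(blank) && !allow_missing) {
    abort(paste0("Empty cells in '", path, "' are only allowed in response matrices."))
  }
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m), dimnames = list(row_ids, colnames(df)[-1])))
  bad <- !blank & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(paste0("Non-numeric cell at row '", row_ids[idx[1]], "', column '",
                 colnames(num)[idx[2]], "' in '", path, "'."))
  }
  num
}

#' Read a panel matrix from TSV
#'
#' Parses the standard panel TSV layout: a header row of column (cell-line)
#' ids and a first column of row ids. Empty cells and `"NA"` are permitted
#' only for response matrices, where they become unobserved entries.
#'
#' @param path TSV file path.
#' @param kind one of `"expression"`, `"cnv"`, `"response"`, `"fingerprint"`.
#' @param unit for response matrices: `"M"` (values are -log10 molar, the
#'   canonical unit) or `"nM"` (values are -log10 nanomolar; 9 is added).
#' @return An [omics_matrix()], [response_matrix()] or [fingerprint_matrix()].
#' @export
read_matrix <- function(path, kind = c("expression", "cnv", "response", "fingerprint"),
                        unit = c("M", "nM")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  if (kind == "response") {
    m <- read_tsv_matrix(path, allow_missing = TRUE)
    if (unit == "nM") m <- m + 9
    response_matrix(m)
  } else if (kind == "fingerprint") {
    fingerprint_matrix(read_tsv_matrix(path))
  } else {
    omics_matrix(read_tsv_matrix(path), kind = kind)
  }
}

#' Read mutation calls from TSV
#'
#' @param path TSV with columns `gene`, `cell_line`, `effect_class`.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  mutation_table(df)
}

#' Read a cancer-type annotation from TSV
#'
#' @param path TSV with columns `cell_line`, `cancer_type`.
#' @param targets_path optional TSV with columns `drug`, `target` (one gene
#'   per row).
#' @return A [panel_annotation()].
#' @export
read_annotation <- function(path, targets_path = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("cell_line", "cancer_type") %in% names(df))) {
    abort("Annotation TSV needs columns cell_line, cancer_type.")
  }
  targets <- list()
  if (!is.null(targets_path)) {
    td <- read.delim(targets_path, sep = "\t", header = TRUE, colClasses = "character")
    if (!all(c("drug", "target") %in% names(td))) {
      abort("Drug target TSV needs columns drug, target.")
    }
    targets <- split(td$target, td$drug)
    targets <- lapply(targets, unique)
  }
  panel_annotation(setNames(df$cancer_type, df$cell_line), targets)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Members are deduplicated per set.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort(paste0("GMT line ", which(short)[1], " has fewer than 3 fields."))
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort(paste0("Duplicate gene-set name(s): ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nms
  sets
}

# ---- writers ----------------------------------------------------------------

#' Write a panel matrix to TSV
#'
#' Inverse of [read_matrix()]; unobserved response entries are written as
#' empty cells so that read/write round-trips are identity.
#'
#' @param x an `omics_matrix`, `response_matrix` or `fingerprint_matrix`.
#' @param path output TSV path.
#' @param id_column header label for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "id") {
  m <- if (inherits(x, "response_matrix")) x$values
       else if (inherits(x, "fingerprint_matrix")) x$bits
       else if (inherits(x, "omics_matrix")) x$values
       else as.matrix(x)
  out <- cbind(rownames(m), apply(m, 2, function(col) {
    s <- format(col, trim = TRUE, digits = 15, scientific = FALSE)
    s[is.na(col)] <- ""
    s
  }))
  colnames(out) <- c(id_column, colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- pIC50 and filtering ----------------------------------------------------

#' Convert IC50 concentrations to pIC50
#'
#' pIC50 = -log10(IC50 in molar); higher values mean greater sensitivity.
#'
#' @param ic50 numeric vector of concentrations, strictly positive.
#' @param unit `"M"` (default) or `"nM"`.
#' @return Numeric vector of pIC50 values (molar scale).
#' @export
#' @examples
#' to_pic50(1e-6)        # 6
#' to_pic50(50, "nM")    # 7.30103
to_pic50 <- function(ic50, unit = c("M", "nM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("IC50 concentrations must be finite and positive.")
  }
  if (unit == "nM") ic50 <- ic50 * 1e-9
  -log10(ic50)
}

#' Drop drugs with too many missing responses
#'
#' Removes every drug whose unobserved fraction across the cell-line panel
#' exceeds `max_missing_fraction` (strictly greater than); the default 0.40
#' reproduces the usual ">40% missing" curation rule. The cell-line axis is
#' unchanged.
#'
#' @param r a [response_matrix()].
#' @param max_missing_fraction threshold in \[0, 1\].
#' @return A filtered `response_matrix`.
#' @export
filter_drugs_by_missingness <- function(r, max_missing_fraction = 0.40) {
  stopifnot(inherits(r, "response_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    abort("`max_missing_fraction` must be in [0, 1].")
  }
  miss <- 1 - rowMeans(r$observed)
  keep <- miss <= max_missing_fraction
  inform(paste0("Removed ", sum(!keep), " of ", length(keep),
                " drugs with missing fraction > ", max_missing_fraction, "."))
  response_matrix(r$values[keep, , drop = FALSE],
                  r$observed[keep, , drop = FALSE])
}

# ---- alignment --------------------------------------------------------------

panel_cell_lines <- function(x) {
  if (inherits(x, "omics_matrix")) colnames(x$values)
  else if (inherits(x, "response_matrix")) colnames(x$values)
  else if (inherits(x, "mutation_table")) unique(x$cell_line)
  else if (inherits(x, "panel_annotation")) names(x$cell_types)
  else abort("No cell-line axis for this object.")
}

restrict_cells <- function(x, cells) {
  if (inherits(x, "omics_matrix")) {
    omics_matrix(x$values[, cells, drop = FALSE], x$kind)
  } else if (inherits(x, "response_matrix")) {
    response_matrix(x$values[, cells, drop = FALSE],
                    x$observed[, cells, drop = FALSE])
  } else if (inherits(x, "mutation_table")) {
    mutation_table(x[x$cell_line %in% cells, ])
  } else if (inherits(x, "panel_annotation")) {
    panel_annotation(x$cell_types[cells], x$drug_targets)
  } else abort("Cannot restrict this object by cell line.")
}

#' Align panel containers to their common cell lines
#'
#' Restricts and reorders every container to the intersection of their
#' cell-line id sets, in lexicographic order (so alignment is deterministic),
#' and reports dropped ids.
#'
#' @param parts named list of containers (omics/response matrices, mutation
#'   tables, annotations).
#' @return The aligned list, with attribute `"dropped"`: a named list of the
#'   ids removed from each container.
#' @export
align_panels <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  sets <- lapply(parts, panel_cell_lines)
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) abort("Panels share no cell line ids.")
  common <- sort(common)
  dropped <- lapply(sets, function(s) sort(setdiff(s, common)))
  out <- lapply(parts, restrict_cells, cells = common)
  attr(out, "dropped") <- dropped
  attr(out, "cell_lines") <- common
  out
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix kind=%s: %d genes x %d cell lines>\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d drugs x %d cell lines, %.1f%% observed>\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  invisible(x)
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix: %d drugs x %d bits>\n",
              nrow(x$bits), x$n_bits))
  invisible(x)
}
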