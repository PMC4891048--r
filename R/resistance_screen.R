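# Primary-resistance gene screen: remove cell lines with aberrant CNV or
# mutation backgrounds (distance-to-center outliers, silent mutations
# excluded), discretize each drug's activity into sensitive / moderate /
# resistant, then keep signature genes whose expression AND copy number are
# both strongly Spearman-correlated with activity, with concordant signs.

#' Drop silent mutation records
#'
#' @param m a [mutation_table()].
#' @return The table restricted to nonsilent records (possibly empty).
#' @export
exclude_silent <- function(m) {
  stopifnot(inherits(m, "mutation_table"))
  out <- m[m$effect_class == "nonsilent", ]
  if (nrow(out) == 0L) warn("No nonsilent mutations remain after filtering.")
  mutation_table(out)
}

#' Binary nonsilent mutation matrix
#'
#' Builds the gene x cell-line 0/1 indicator of nonsilent mutation used as
#' the mutation profile for outlier detection.
#'
#' @param m a [mutation_table()] (silent records are ignored).
#' @param cell_lines column ids of the output (defaults to those present).
#' @param genes row ids of the output (defaults to those present).
#' @return Binary numeric matrix.
#' @export
mutation_matrix <- function(m, cell_lines = NULL, genes = NULL) {
  stopifnot(inherits(m, "mutation_table"))
  m <- m[m$effect_class == "nonsilent", ]
  genes <- genes %||% sort(unique(m$gene))
  cell_lines <- cell_lines %||% sort(unique(m$cell_line))
  out <- matrix(0, length(genes), length(cell_lines),
                dimnames = list(genes, cell_lines))
  keep <- m$gene %in% genes & m$cell_line %in% cell_lines
  out[cbind(m$gene[keep], m$cell_line[keep])] <- 1
  out
}

#' Detect cell-line outliers by distance to the panel center
#'
#' Computes each cell line's Euclidean distance to the componentwise mean of
#' all cell-line profile vectors and flags the `ceiling(fraction * n)`
#' furthest ones. Ties in distance are broken lexicographically by cell-line
#' id, so the result is deterministic.
#'
#' @param profile an [omics_matrix()] or a numeric matrix with cell lines in
#'   columns (e.g. from [mutation_matrix()]).
#' @param fraction removal fraction in (0, 1); default 0.10 (the "furthest
#'   10%" rule).
#' @return Character vector of outlier cell-line ids.
#' @export
detect_outliers <- function(profile, fraction = 0.10) {
  m <- if (inherits(profile, "omics_matrix")) profile$values else as.matrix(profile)
  n <- ncol(m)
  if (n < 2L) abort("Need at least 2 cell lines for outlier detection.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n_out <- ceiling(fraction * n)
  if (n_out >= n) abort("Requested outlier fraction would remove every cell line.")
  center <- rowMeans(m)
  d <- sqrt(colSums((m - center)^2))
  ids <- colnames(m) %||% as.character(seq_len(n))
  ids[order(-d, ids)][seq_len(n_out)]
}

#' Discretize one drug's cell-line activities
#'
#' Qualitative representation of a drug's pIC50 profile: cell lines are
#' sorted by activity and the distribution's tails are labelled, giving
#' sensitive (`+1`, high pIC50), resistant (`-1`, low pIC50) and moderate
#' (`0`) calls. Two methods: `"quantile"` labels the `floor(q * n)` lowest
#' values `-1` and highest `+1`; `"zscore"` labels standardized values
#' beyond `±z_cut`. Value ties are resolved by cell-line id, so calls are
#' deterministic.
#'
#' @param responses named numeric vector of observed pIC50 for one drug
#'   (>= 4 values).
#' @param method `"quantile"` (default) or `"zscore"`.
#' @param q tail fraction for the quantile method (default 0.25).
#' @param z_cut cut on standardized values for the z-score method
#'   (default 1).
#' @param drug drug id recorded in the result.
#' @return Object of class `activity_call` with the integer `labels`
#'   (named; values in \{-1, 0, 1\}).
#' @export
discretize_activity <- function(responses, method = c("quantile", "zscore"),
                                q = 0.25, z_cut = 1, drug = NA_character_) {
  method <- match.arg(method)
  responses <- responses[!is.na(responses)]
  n <- length(responses)
  if (n < 4L) abort("Need at least 4 observed responses to discretize.")
  ids <- names(responses) %||% as.character(seq_len(n))
  labels <- setNames(integer(n), ids)
  if (length(unique(responses)) == 1L) {
    warn("All responses identical; every cell line called moderate (0).")
  } else if (method == "quantile") {
    if (q <= 0 || q > 0.5) abort("`q` must be in (0, 0.5].")
    ord <- ids[order(responses, ids)]
    n_tail <- floor(q * n)
    if (n_tail < 1L) abort("Tail fraction selects zero cell lines.")
    labels[ord[seq_len(n_tail)]] <- -1L
    labels[ord[seq.int(n - n_tail + 1L, n)]] <- 1L
  } else {
    z <- (responses - mean(responses)) / sd(responses)
    labels[z > z_cut] <- 1L
    labels[z < -z_cut] <- -1L
  }
  structure(list(drug = drug, labels = labels, method = method,
                 params = list(q = q, z_cut = z_cut)),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(-1, 0, 1)))
  cat(sprintf("<activity_call drug=%s (%s): %d resistant / %d moderate / %d sensitive>\n",
              x$drug, x$method, tab[["-1"]], tab[["0"]], tab[["1"]]))
  invisible(x)
}

#' @method tidy activity_call
#' @export
tidy.activity_call <- function(x, ...) {
  tibble::tibble(drug = x$drug, cell_line = names(x$labels),
                 label = unname(x$labels))
}

#' Spearman concordance screen for resistance genes
#'
#' Restricts to the sensitive and resistant cell lines of an activity call
#' and, for every candidate gene, computes the Spearman correlation of its
#' expression with pIC50 and of its copy number with pIC50 over those lines.
#' A gene passes iff `|rho_expr| > expr_cutoff`, `|rho_cnv| > cnv_cutoff`,
#' and the two correlations have the same sign (both positive or both
#' negative). Absolute values are used because resistance markers can be
#' either up- or down-regulated; set `cnv_cutoff = 0` for a sign-only copy-
#' number criterion.
#'
#' @param expr expression [omics_matrix()].
#' @param cnv copy-number [omics_matrix()].
#' @param calls an [discretize_activity()] result.
#' @param responses named pIC50 vector covering the called cell lines.
#' @param candidate_genes genes to test (default: all genes shared by both
#'   matrices).
#' @param expr_cutoff,cnv_cutoff absolute Spearman thresholds (default 0.7).
#' @return A tibble of class `screen_hits`: one row per candidate with
#'   `rho_expr`, `rho_cnv`, `passed` and a failure `reason`.
#' @export
spearman_screen <- function(expr, cnv, calls, responses,
                            candidate_genes = NULL,
                            expr_cutoff = 0.7, cnv_cutoff = 0.7) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(cnv, "omics_matrix"),
            inherits(calls, "activity_call"))
  candidate_genes <- candidate_genes %||%
    intersect(rownames(expr$values), rownames(cnv$values))
  missing <- setdiff(candidate_genes,
                     intersect(rownames(expr$values), rownames(cnv$values)))
  if (length(missing)) {
    abort(paste0("Candidate gene(s) absent from expression or CNV: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  lines <- names(calls$labels)[calls$labels != 0L]
  lines <- lines[lines %in% names(responses) & !is.na(responses[lines])]
  lines <- intersect(intersect(lines, colnames(expr$values)), colnames(cnv$values))
  if (length(lines) < 4L) abort("Fewer than 4 sensitive/resistant cell lines retained.")
  if (sum(calls$labels[lines] == 1L) < 2L || sum(calls$labels[lines] == -1L) < 2L) {
    abort("Need at least 2 sensitive and 2 resistant cell lines.")
  }
  y <- responses[lines]
  out <- purrr::map_dfr(candidate_genes, function(g) {
    e <- expr$values[g, lines]
    c_ <- cnv$values[g, lines]
    re <- if (sd(e) == 0) NA_real_ else suppressWarnings(cor(e, y, method = "spearman"))
    rc <- if (sd(c_) == 0) NA_real_ else suppressWarnings(cor(c_, y, method = "spearman"))
    reason <- NA_character_
    passed <- FALSE
    if (is.na(re) || is.na(rc)) {
      reason <- "zero variance"
    } else if (abs(re) <= expr_cutoff) {
      reason <- "expression correlation below cutoff"
    } else if (abs(rc) <= cnv_cutoff) {
      reason <- "CNV correlation below cutoff"
    } else if (sign(re) != sign(rc)) {
      reason <- "discordant expression/CNV signs"
    } else {
      passed <- TRUE
    }
    tibble::tibble(drug = calls$drug, gene = g, rho_expr = re, rho_cnv = rc,
                   n_lines = length(lines), passed = passed, reason = reason)
  })
  class(out) <- c("screen_hits", class(out))
  out
}

#' Run the full primary-resistance screen for one drug
#'
#' Pipeline composition over one cancer type's cell lines: silent mutations
#' are excluded; distance-to-center outliers are detected separately on the
#' CNV matrix and on the binary nonsilent-mutation matrix and removed as a
#' union; the drug's observed activities on the remaining lines are
#' discretized; and the Spearman concordance screen is applied to the
#' drug's signature genes (resistance candidates are assumed to lie among
#' the drug-response signature genes). Deterministic given the
#' configuration.
#'
#' @param panel named list with elements `expression`, `cnv`, `mutations`
#'   ([mutation_table()], may be `NULL`), `response`
#'   ([response_matrix()]).
#' @param annotation a [panel_annotation()].
#' @param signatures a `signature_set` (or character vector of genes) for
#'   the drug's cancer type.
#' @param drug drug id to screen.
#' @param cancer_type cancer type; defaults to the signature set's.
#' @param outlier_fraction removal fraction per profile (0 disables the
#'   outlier stage).
#' @param expr_cutoff,cnv_cutoff Spearman cutoffs, see [spearman_screen()].
#' @param disc_method,disc_q discretization method and tail fraction, see
#'   [discretize_activity()].
#' @return A `screen_hits` tibble with attributes `removed_outliers` and
#'   `activity_call`.
#' @export
run_resistance_screen <- function(panel, annotation, signatures, drug,
                                  cancer_type = NULL, outlier_fraction = 0.10,
                                  expr_cutoff = 0.7, cnv_cutoff = 0.7,
                                  disc_method = "quantile", disc_q = 0.25) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  genes <- if (inherits(signatures, "signature_set")) signatures$genes
           else as.character(signatures)
  cancer_type <- cancer_type %||%
    (if (inherits(signatures, "signature_set")) signatures$cancer_type else NULL)
  if (is.null(cancer_type)) abort("`cancer_type` is required.")
  cells <- names(annotation$cell_types)[annotation$cell_types == cancer_type]
  cells <- sort(intersect(intersect(cells, colnames(panel$expression$values)),
                          colnames(panel$response$values)))
  if (length(cells) < 4L) abort("Fewer than 4 cell lines for this cancer type.")

  removed <- character(0)
  if (outlier_fraction > 0) {
    cnv_sub <- stage("cnv outliers",
                     panel$cnv$values[, cells, drop = FALSE])
    removed <- stage("cnv outliers", detect_outliers(cnv_sub, outlier_fraction))
    if (!is.null(panel$mutations)) {
      nonsilent <- stage("mutation filter", exclude_silent(panel$mutations))
      if (nrow(nonsilent) > 0L && length(unique(nonsilent$gene)) > 0L) {
        mm <- mutation_matrix(nonsilent, cell_lines = cells)
        mut_out <- stage("mutation outliers", detect_outliers(mm, outlier_fraction))
        removed <- union(removed, mut_out)
      } else {
        warn("Mutation outlier stage skipped: no nonsilent records.")
      }
    }
  }
  kept <- sort(setdiff(cells, removed))

  resp <- panel$response$values[drug, kept]
  resp <- resp[!is.na(resp)]
  calls <- stage("discretization",
                 discretize_activity(resp, method = disc_method, q = disc_q,
                                     drug = drug))
  hits <- stage("spearman screen",
                spearman_screen(panel$expression, panel$cnv, calls, resp,
                                candidate_genes = intersect(genes, rownames(panel$expression$values)),
                                expr_cutoff = expr_cutoff,
                                cnv_cutoff = cnv_cutoff))
  attr(hits, "removed_outliers") <- sort(removed)
  attr(hits, "activity_call") <- calls
  hits
}

#' Plot a resistance screen's correlation landscape
#'
#' Scatter of expression vs CNV Spearman correlations per candidate gene,
#' with the cutoff box; passing genes highlighted.
#'
#' @param object a `screen_hits` tibble.
#' @param expr_cutoff,cnv_cutoff cutoffs to draw (default 0.7).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot screen_hits
#' @export
autoplot.screen_hits <- function(object, expr_cutoff = 0.7, cnv_cutoff = 0.7, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho_expr, y = .data$rho_cnv,
                                       colour = .data$passed)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(-expr_cutoff, expr_cutoff), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-cnv_cutoff, cnv_cutoff), linetype = "dashed") +
    ggplot2::lims(x = c(-1, 1), y = c(-1, 1)) +
    ggplot2::labs(x = "Spearman rho (expression vs activity)",
                  y = "Spearman rho (CNV vs activity)",
                  colour = "Passed",
                  title = "Primary-resistance screen")
}
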