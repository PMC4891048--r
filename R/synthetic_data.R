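# Synthetic panel generator: a CCLE-like drug x cell-line panel with
# planted ground truth at every stage, so the collaborative filter, the
# signature selection, the outlier detector and the resistance screen each
# have a recoverable answer.

stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10000L + stage
}

#' Simulate a pharmacogenomic cell-line panel with planted truth
#'
#' Generates a full panel in the package's container types:
#' \itemize{
#' \item expression (genes x cell lines): normal in log2 space (mean 7,
#'   sd 2 across genes) with cancer-type block shifts, resembling array
#'   intensities;
#' \item a planted group-sparse map `Q` from `driver_count` driver genes per
#'   cancer type to the nonnegative cell-line factors `V_true`, and a
#'   nonnegative random `U_true`, giving the low-rank response
#'   `S = U_true V_true' + noise` rescaled to a realistic pIC50 level
#'   (mean ~6), with entries masked at `missing_fraction`;
#' \item CNV coupled to expression for a `cnv_coupling` fraction of genes
#'   (default 0.75, echoing reported lung-cancer CNV-expression
#'   concordance) and independent noise for the rest;
#' \item silent and nonsilent mutation calls, with `outlier_count` planted
#'   outlier cell lines given aberrant CNV shifts and mutation loads;
#' \item `resist_count` planted resistance genes per drug, disjoint from
#'   the driver genes, whose expression and CNV are both monotone in the
#'   drug's pIC50 with concordant signs (half planted positive, half
#'   negative);
#' \item binary fingerprints with per-cancer-type block structure so drug
#'   Tanimoto similarity is informative, plus one target gene per drug.
#' }
#' Reproducible bit-for-bit from `seed` via a fixed hierarchy of
#' stage seeds.
#'
#' @param n_drugs,n_cells,n_genes panel dimensions.
#' @param k_true planted factorization rank.
#' @param n_types number of cancer types (cell lines split about evenly).
#' @param driver_count planted driver genes per cancer type.
#' @param resist_count planted resistance genes per drug.
#' @param outlier_count planted outlier cell lines.
#' @param missing_fraction fraction of response entries masked.
#' @param noise_sd response noise standard deviation (pIC50 units).
#' @param cnv_coupling fraction of genes whose CNV tracks expression.
#' @param n_bits fingerprint length.
#' @param seed integer seed.
#' @return List with elements `expression`, `cnv`, `mutations`, `response`,
#'   `fingerprints`, `annotation`, and `truth` (class `synthetic_truth`:
#'   `U_true`, `V_true`, `Q_support` per type, `resistance_genes` per drug,
#'   `resistance_sign`, `outlier_ids`, `drug_types`, `noise_sd`, `seed`).
#' @export
simulate_panel <- function(n_drugs = 40, n_cells = 120, n_genes = 500,
                           k_true = 5, n_types = 3, driver_count = 10,
                           resist_count = 5, outlier_count = 3,
                           missing_fraction = 0.2, noise_sd = 0.1,
                           cnv_coupling = 0.75, n_bits = 128, seed = 1) {
  if (min(n_drugs, n_cells, n_genes, k_true, n_types) < 1) {
    abort("All panel dimensions must be positive.")
  }
  if (n_types * driver_count + n_drugs * resist_count > n_genes) {
    abort("Too many planted driver/resistance genes for `n_genes`.")
  }
  if (outlier_count >= n_cells / n_types) {
    abort("`outlier_count` must be smaller than the cells per cancer type.")
  }
  if (n_cells < n_types * 8) {
    abort("Need at least 8 cell lines per cancer type.")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("`missing_fraction` must be in [0, 1).")
  }

  drugs <- sprintf("D%03d", seq_len(n_drugs))
  cells <- sprintf("C%04d", seq_len(n_cells))
  genes <- sprintf("G%05d", seq_len(n_genes))
  types <- paste0("type", seq_len(n_types))
  cell_type <- setNames(rep_len(types, n_cells), cells)
  drug_type <- setNames(rep_len(types, n_drugs), drugs)

  # expression: log2-array-like marginals with per-type block shifts
  set.seed(stage_seed(seed, 1L))
  gene_mean <- rnorm(n_genes, 7, 2)
  expr <- matrix(rnorm(n_genes * n_cells, 0, 0.5), n_genes, n_cells,
                 dimnames = list(genes, cells)) + gene_mean
  shift_genes <- sample(genes, max(1L, round(0.1 * n_genes)))
  for (tp in types) {
    expr[shift_genes, cell_type == tp] <-
      expr[shift_genes, cell_type == tp] + rnorm(length(shift_genes), 0, 1)
  }

  # planted group-sparse drivers -> nonnegative cell-line factors
  set.seed(stage_seed(seed, 2L))
  free_genes <- genes
  q_support <- list()
  V_true <- matrix(0, n_cells, k_true, dimnames = list(cells, NULL))
  for (tp in types) {
    drv <- sort(sample(free_genes, driver_count))
    free_genes <- setdiff(free_genes, drv)
    q_support[[tp]] <- drv
    Q_tp <- matrix(runif(driver_count * k_true, 0.5, 1.5), driver_count, k_true)
    idx <- cell_type == tp
    # centred driver expression drives the factors around a unit baseline, so
    # within-type response variation (~0.2 sd per factor) dominates the
    # measurement noise and the planted drivers are recoverable downstream
    z <- expr[drv, idx, drop = FALSE] - gene_mean[match(drv, genes)]
    V_true[idx, ] <- 1 + t(z) %*% Q_tp / driver_count
  }
  V_true <- pmax(V_true, 0)
  U_true <- matrix(runif(n_drugs * k_true, 0.2, 2), n_drugs, k_true,
                   dimnames = list(drugs, NULL))
  S0 <- U_true %*% t(V_true)
  sc <- 6 / mean(S0)
  U_true <- U_true * sc
  S0 <- S0 * sc

  set.seed(stage_seed(seed, 3L))
  S <- S0 + matrix(rnorm(n_drugs * n_cells, 0, noise_sd), n_drugs, n_cells)
  dimnames(S) <- list(drugs, cells)
  observed <- matrix(TRUE, n_drugs, n_cells, dimnames = dimnames(S))
  if (missing_fraction > 0) {
    observed[sample(length(S), round(missing_fraction * length(S)))] <- FALSE
    # keep every drug and cell line observable
    for (i in which(rowSums(observed) == 0)) observed[i, sample(n_cells, 1)] <- TRUE
    for (j in which(colSums(observed) == 0)) observed[sample(n_drugs, 1), j] <- TRUE
  }

  # CNV: coupled to expression for most genes, independent for the rest
  set.seed(stage_seed(seed, 4L))
  coupled <- sample(genes, round(cnv_coupling * n_genes))
  cnv <- matrix(rnorm(n_genes * n_cells, 2, 0.3), n_genes, n_cells,
                dimnames = list(genes, cells))
  z <- (expr[coupled, , drop = FALSE] - rowMeans(expr[coupled, , drop = FALSE])) /
    apply(expr[coupled, , drop = FALSE], 1, sd)
  cnv[coupled, ] <- 2 + 0.5 * z +
    matrix(rnorm(length(coupled) * n_cells, 0, 0.2), length(coupled), n_cells)

  # mutations + planted outliers (aberrant CNV and mutation load)
  set.seed(stage_seed(seed, 5L))
  mut_records <- purrr::map_dfr(cells, function(cl) {
    tibble::tibble(
      gene = c(sample(genes, 20), sample(genes, 10)),
      cell_line = cl,
      effect_class = rep(c("nonsilent", "silent"), c(20, 10))
    )
  })
  outlier_ids <- if (outlier_count > 0) sort(sample(cells, outlier_count)) else character(0)
  if (length(outlier_ids)) {
    aberrant <- sample(genes, round(0.4 * n_genes))
    cnv[aberrant, outlier_ids] <- cnv[aberrant, outlier_ids] +
      sample(c(-2, 2), length(aberrant) * length(outlier_ids), replace = TRUE)
    extra <- purrr::map_dfr(outlier_ids, function(cl) {
      tibble::tibble(gene = sample(genes, round(0.6 * n_genes)),
                     cell_line = cl, effect_class = "nonsilent")
    })
    mut_records <- dplyr::bind_rows(mut_records, extra)
  }
  mut_records <- dplyr::distinct(mut_records)

  # planted resistance genes: expression AND CNV monotone in pIC50 with
  # concordant signs, among the drug's cancer-type cell lines
  set.seed(stage_seed(seed, 6L))
  resistance_genes <- list()
  resistance_sign <- list()
  for (d in drugs) {
    rg <- sort(sample(free_genes, resist_count))
    free_genes <- setdiff(free_genes, rg)
    resistance_genes[[d]] <- rg
    sgn <- rep_len(c(1, -1), resist_count)
    resistance_sign[[d]] <- setNames(sgn, rg)
    idx <- cells[cell_type == drug_type[[d]]]
    s_z <- as.numeric(scale(S[d, idx]))
    for (i in seq_along(rg)) {
      expr[rg[i], idx] <- 7 + sgn[i] * 1.5 * s_z + rnorm(length(idx), 0, 0.15)
      cnv[rg[i], idx] <- 2 + sgn[i] * 0.8 * s_z + rnorm(length(idx), 0, 0.08)
    }
  }

  # fingerprints: per-type templates with drug-level bit flips
  set.seed(stage_seed(seed, 7L))
  templates <- lapply(types, function(tp) rbinom(n_bits, 1, 0.3))
  names(templates) <- types
  bits <- t(vapply(drugs, function(d) {
    b <- templates[[drug_type[[d]]]]
    flip <- sample(n_bits, max(1L, round(0.08 * n_bits)))
    b[flip] <- 1 - b[flip]
    if (sum(b) == 0) b[sample(n_bits, 3)] <- 1
    b
  }, numeric(n_bits)))
  dimnames(bits) <- list(drugs, paste0("bit", seq_len(n_bits)))

  set.seed(stage_seed(seed, 8L))
  drug_targets <- setNames(as.list(sample(genes, n_drugs, replace = TRUE)), drugs)

  truth <- structure(list(
    U_true = U_true, V_true = V_true, Q_support = q_support,
    resistance_genes = resistance_genes, resistance_sign = resistance_sign,
    outlier_ids = outlier_ids, drug_types = drug_type,
    noise_sd = noise_sd, missing_fraction = missing_fraction, seed = seed
  ), class = "synthetic_truth")

  list(
    expression = omics_matrix(expr, "expression"),
    cnv = omics_matrix(cnv, "cnv"),
    mutations = mutation_table(mut_records),
    response = response_matrix(S, observed),
    fingerprints = fingerprint_matrix(bits),
    annotation = panel_annotation(cell_type, drug_targets),
    truth = truth
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: rank %d, %d cancer types, %d outliers, noise_sd %.3g, seed %s>\n",
              ncol(x$U_true), length(x$Q_support), length(x$outlier_ids),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Write a simulated panel to TSV files
#'
#' Emits the panel in the same formats the readers consume, plus a JSON
#' truth file, so a written panel round-trips through [read_matrix()] and
#' friends.
#'
#' @param panel result of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    response = file.path(dir, "response.tsv"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix(panel$expression, paths["expression"], id_column = "gene")
  write_matrix(panel$cnv, paths["cnv"], id_column = "gene")
  write_matrix(panel$response, paths["response"], id_column = "drug")
  write_matrix(panel$fingerprints, paths["fingerprints"], id_column = "drug")
  write.table(as.data.frame(panel$mutations), paths["mutations"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(cell_line = names(panel$annotation$cell_types),
               cancer_type = unname(panel$annotation$cell_types)),
    paths["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- panel$truth
  jsonlite::write_json(list(
    Q_support = truth$Q_support,
    resistance_genes = truth$resistance_genes,
    outlier_ids = truth$outlier_ids,
    drug_types = as.list(truth$drug_types),
    noise_sd = truth$noise_sd, seed = truth$seed
  ), paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
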