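# Downstream annotation of signature genes: synthetic-lethality pair
# mapping (drug targets as gene A, signature genes as gene B) and
# hypergeometric gene-set enrichment.

#' Map drug targets and signature genes onto SL/SDL pairs
#'
#' For each drug, keeps the gene pairs whose gene A is a target of the drug
#' and whose gene B is a signature gene. Pairs are ordered (A -> B),
#' matching the asymmetric definitions of synthetic lethality (inactivation
#' of A makes B essential) and synthetic dosage lethality (over-activity of
#' A makes B essential).
#'
#' @param targets named list: drug id -> character vector of target genes.
#' @param signatures a `signature_set`, character vector, or list of either;
#'   lists are pooled into one signature-gene universe.
#' @param pairs data frame with columns `gene_a`, `gene_b`, `interaction`
#'   (`"SL"` or `"SDL"`).
#' @return List with `matches` (tibble: drug, gene_a, gene_b, interaction)
#'   and `summary` (tibble per interaction type: non-redundant pair count
#'   and number of contributing drugs).
#' @export
map_sl_pairs <- function(targets, signatures, pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("gene_a", "gene_b", "interaction")
  if (!all(need %in% names(pairs))) {
    abort(paste0("Pairs need columns: ", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(pairs$interaction), c("SL", "SDL"))
  if (length(bad)) abort(paste0("Unknown interaction type(s): ", paste(bad, collapse = ", ")))
  if (any(pairs$gene_a == pairs$gene_b)) abort("A gene cannot pair with itself.")
  pairs <- dplyr::distinct(pairs)

  sig_genes <- unique(unlist(lapply(
    if (inherits(signatures, "signature_set") || is.character(signatures))
      list(signatures) else signatures,
    function(s) if (inherits(s, "signature_set")) s$genes else as.character(s)
  )))

  matches <- purrr::map_dfr(names(targets), function(d) {
    hit <- pairs$gene_a %in% targets[[d]] & pairs$gene_b %in% sig_genes
    if (!any(hit)) return(NULL)
    dplyr::mutate(pairs[hit, ], drug = d, .before = 1)
  })
  if (nrow(matches) == 0L) {
    matches <- tibble::tibble(drug = character(), gene_a = character(),
                              gene_b = character(), interaction = character())
  }
  summary <- matches |>
    dplyr::group_by(.data$interaction) |>
    dplyr::summarise(
      n_pairs = dplyr::n_distinct(paste(.data$gene_a, .data$gene_b)),
      n_drugs = dplyr::n_distinct(.data$drug),
      .groups = "drop"
    )
  list(matches = matches, summary = summary)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene set and each annotated set, within a stated gene universe (each set
#' is intersected with the universe before testing). A set is called
#' significant iff its p-value is below `p_cutoff` and its overlap strictly
#' exceeds `min_overlap` (defaults reproduce the common "p < 0.05 and more
#' than two genes" rule). No multiple-testing correction is applied by
#' default; set `fdr = TRUE` for Benjamini-Hochberg adjusted significance.
#'
#' @param query character vector of genes, a subset of `universe`, no
#'   duplicates.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background genes, no duplicates.
#' @param p_cutoff significance threshold on the (possibly adjusted)
#'   p-value.
#' @param min_overlap overlap must be strictly greater than this.
#' @param fdr use Benjamini-Hochberg adjusted p-values for the significance
#'   call.
#' @return Tibble sorted by p-value: `set_name`, `set_size`,
#'   `overlap_count`, `overlap_genes` (list column), `p_value`,
#'   (`p_adjusted`,) `significant`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe,
                                      p_cutoff = 0.05, min_overlap = 2,
                                      fdr = FALSE) {
  if (length(universe) == 0L) abort("Gene universe is empty.")
  if (anyDuplicated(universe)) abort("Duplicate ids in `universe`.")
  if (anyDuplicated(query)) abort("Duplicate ids in `query`.")
  if (!all(query %in% universe)) abort("`query` must be a subset of `universe`.")
  n_univ <- length(universe)
  n_query <- length(query)
  res <- purrr::map_dfr(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(query, s)
    p <- phyper(length(ov) - 1L, length(s), n_univ - length(s), n_query,
                lower.tail = FALSE)
    tibble::tibble(set_name = nm, set_size = length(s),
                   overlap_count = length(ov),
                   overlap_genes = list(sort(ov)), p_value = p)
  })
  if (fdr) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < p_cutoff & res$overlap_count > min_overlap
  } else {
    res$significant <- res$p_value < p_cutoff & res$overlap_count > min_overlap
  }
  dplyr::arrange(res, .data$p_value)
}
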