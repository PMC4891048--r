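# Scoring of predicted drug sensitivities: RMSE, concordance index,
# probabilistic concordance (Gaussian measurement-noise weighting), and the
# weighted probabilistic concordance index used for ranking evaluations.

#' Root-mean-square error
#'
#' @param predicted,observed equal-length finite numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L) {
    abort("`predicted` and `observed` must have equal nonzero length.")
  }
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    abort("rmse requires finite values.")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Concordance index
#'
#' Fraction of item pairs whose predicted ordering agrees with the observed
#' ordering. `predicted` is a score on the same orientation as `observed`
#' (higher predicted with higher observed counts as concordant); a best-first
#' rank list must therefore be negated before scoring. Pairs tied in the
#' observed values contribute 0.5, as do pairs tied in the predictions
#' (Harrell's convention).
#'
#' @param predicted numeric prediction scores.
#' @param observed numeric observed values; same length, >= 2 items, no
#'   missing values.
#' @return Scalar in \[0, 1\].
#' @export
c_index <- function(predicted, observed) {
  pair_concordance(predicted, observed, noise_sd = 0)
}

#' Probabilistic concordance index
#'
#' Like [c_index()], but each pair is weighted by how distinguishable its
#' observed values are under Gaussian measurement noise with standard
#' deviation `noise_sd`: a correctly ordered pair contributes
#' `pnorm(|o_i - o_j| / (sqrt(2) * noise_sd))`, an incorrectly ordered pair
#' one minus that, and prediction ties 0.5. With `noise_sd = 0` this reduces
#' exactly to the concordance index.
#'
#' @param predicted,observed as in [c_index()].
#' @param noise_sd per-item measurement standard deviation, >= 0.
#' @return Scalar in \[0, 1\].
#' @export
probabilistic_c_index <- function(predicted, observed, noise_sd = 0) {
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  pair_concordance(predicted, observed, noise_sd)
}

pair_concordance <- function(predicted, observed, noise_sd) {
  n <- length(observed)
  if (length(predicted) != n) abort("Length mismatch between predictions and observations.")
  if (n < 2L) abort("Need at least 2 items to score concordance.")
  if (any(is.na(predicted)) || any(is.na(observed))) abort("Missing values are not allowed.")
  ij <- utils::combn(n, 2L)
  do_ <- observed[ij[1, ]] - observed[ij[2, ]]
  dp <- predicted[ij[1, ]] - predicted[ij[2, ]]
  if (noise_sd == 0) {
    phi <- rep(1, length(do_))
  } else {
    phi <- pnorm(abs(do_) / (sqrt(2) * noise_sd))
  }
  contrib <- ifelse(dp == 0 | do_ == 0, 0.5,
                    ifelse(sign(dp) == sign(do_), phi, 1 - phi))
  mean(contrib)
}

#' Weighted probabilistic concordance index
#'
#' Aggregates per-drug probabilistic concordance scores into a panel-level
#' index by a weighted mean. Weights default to uniform; a resampling-derived
#' weight vector (e.g. reflecting per-drug measurement reliability) can be
#' supplied instead.
#'
#' @param per_drug_scores named numeric vector of per-drug pc-index values.
#' @param weights named nonnegative numeric vector over the same drugs, not
#'   all zero; `NULL` for uniform.
#' @return An object of class `ranking_evaluation` with elements
#'   `per_drug_pc`, `drug_weights` and the scalar `wpc`.
#' @export
wpc_index <- function(per_drug_scores, weights = NULL) {
  drugs <- names(per_drug_scores)
  if (is.null(drugs)) drugs <- as.character(seq_along(per_drug_scores))
  if (is.null(weights)) weights <- setNames(rep(1, length(drugs)), drugs)
  if (!setequal(names(weights), drugs)) {
    abort("`weights` must cover exactly the drugs of `per_drug_scores`.")
  }
  weights <- weights[drugs]
  if (any(weights < 0)) abort("Weights must be nonnegative.")
  if (sum(weights) == 0) abort("Weights must not all be zero.")
  structure(list(
    per_drug_pc = setNames(as.numeric(per_drug_scores), drugs),
    drug_weights = weights,
    wpc = sum(weights * per_drug_scores) / sum(weights)
  ), class = "ranking_evaluation")
}

#' Rank a prediction matrix against an observed response matrix
#'
#' Convenience wrapper for the DREAM-style ranking evaluation: computes the
#' probabilistic concordance index per drug over the cell lines observed for
#' that drug, then the weighted mean.
#'
#' @param predicted numeric matrix of predicted pIC50 (drugs x cell lines,
#'   same dimnames as `observed`).
#' @param observed a [response_matrix()].
#' @param noise_sd measurement noise sd for [probabilistic_c_index()].
#' @param weights optional per-drug weights for [wpc_index()].
#' @return A `ranking_evaluation`.
#' @export
evaluate_ranking <- function(predicted, observed, noise_sd = 0, weights = NULL) {
  stopifnot(inherits(observed, "response_matrix"))
  drugs <- rownames(observed$values)
  scores <- vapply(seq_along(drugs), function(i) {
    keep <- observed$observed[i, ]
    probabilistic_c_index(predicted[i, keep], observed$values[i, keep], noise_sd)
  }, numeric(1))
  wpc_index(setNames(scores, drugs), weights)
}

#' @export
print.ranking_evaluation <- function(x, ...) {
  cat(sprintf("<ranking_evaluation: %d drugs, wpc-index %.4f>\n",
              length(x$per_drug_pc), x$wpc))
  invisible(x)
}

#' Tidiers for ranking evaluations
#'
#' `tidy()` gives per-drug scores and weights; `glance()` the scalar
#' wpc-index.
#'
#' @param x a `ranking_evaluation`.
#' @param ... unused.
#' @name ranking_evaluation_tidiers
#' @method tidy ranking_evaluation
#' @export
tidy.ranking_evaluation <- function(x, ...) {
  tibble::tibble(drug = names(x$per_drug_pc),
                 pc_index = unname(x$per_drug_pc),
                 weight = unname(x$drug_weights))
}

#' @rdname ranking_evaluation_tidiers
#' @method glance ranking_evaluation
#' @export
glance.ranking_evaluation <- function(x, ...) {
  tibble::tibble(n_drugs = length(x$per_drug_pc), wpc = x$wpc)
}

#' Plot per-drug concordance scores
#'
#' @param object a `ranking_evaluation`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ranking_evaluation
#' @export
autoplot.ranking_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$drug, .data$pc_index),
                                   y = .data$pc_index)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$wpc, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Probabilistic concordance index",
                  title = sprintf("wpc-index = %.3f", object$wpc))
}
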