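# Group-sparse-lasso selection of signature genes: regress the cell-line
# factor matrix V onto gene-expression features; whole zero rows of the
# feature-weight matrix Q mark genes not associated with drug response.

soft_threshold <- function(v, lambda) sign(v) * pmax(abs(v) - lambda, 0)

group_shrink <- function(v, lambda, q = c("2", "inf")) {
  q <- match.arg(q)
  if (q == "2") {
    nv <- sqrt(sum(v^2))
    if (nv <= lambda) return(v * 0)
    v * (1 - lambda / nv)
  } else {
    # prox of lambda * ||.||_inf via Moreau: v - projection onto lambda l1-ball
    v - proj_l1_ball(v, lambda)
  }
}

proj_l1_ball <- function(v, radius) {
  if (sum(abs(v)) <= radius) return(v)
  u <- sort(abs(v), decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - radius) / seq_along(u)))
  theta <- (css[rho] - radius) / rho
  sign(v) * pmax(abs(v) - theta, 0)
}

gsl_objective <- function(Y, X, W, lambda_group, lambda_l1, q) {
  rn <- if (q == "2") sqrt(rowSums(W^2)) else apply(abs(W), 1, max)
  sum((Y - X %*% W)^2) + lambda_group * sum(rn) + lambda_l1 * sum(abs(W))
}

#' Smallest group penalty that zeroes every feature row
#'
#' The exact kill threshold from the row-wise proximal operator of the
#' group-sparse-lasso objective `||Y - XW||^2 + lambda_group * sum_j
#' ||W_j||_q + lambda_l1 * ||W||_1`: starting from `W = 0`, row `j` stays
#' zero iff the dual norm of the softthresholded gradient,
#' `||soft(2 X_j' Y, lambda_l1)||`, does not exceed `lambda_group`. The
#' returned value is the maximum of that quantity over rows, so any
#' `lambda_group >=` it yields the all-zero solution.
#'
#' @param targets numeric matrix Y (n x k).
#' @param features numeric matrix X (n x h).
#' @param lambda_l1 elementwise l1 weight.
#' @param q group norm: `"2"` (dual l2) or `"inf"` (dual l1).
#' @return Scalar threshold.
#' @export
gsl_lambda_max <- function(targets, features, lambda_l1 = 0, q = c("2", "inf")) {
  q <- match.arg(q)
  g <- soft_threshold(2 * crossprod(features, targets), lambda_l1)
  if (q == "2") max(sqrt(rowSums(g^2))) else max(rowSums(abs(g)))
}

#' Fit a group-sparse-lasso regression of factors onto features
#'
#' Minimizes
#' \deqn{\|Y - XW\|_F^2 + \lambda_{group} \sum_j \|W_{j\cdot}\|_q
#'   + \lambda_{l1} \|W\|_1}
#' over the feature-weight matrix `W` (features x k), where each group is
#' the row of all `k` coefficients of one feature, by exact block-coordinate
#' descent: every row subproblem is solved in closed form by componentwise
#' soft thresholding followed by the group proximal shrinkage, so the
#' objective never increases. Rows whose l2 norm falls at or below
#' `zero_tol` are reported as unselected.
#'
#' @param targets matrix Y (n x k), e.g. the cell-line factor matrix V.
#' @param features matrix X (n x h), e.g. cell lines x genes expression.
#' @param lambda_group group penalty weight (>= 0).
#' @param lambda_l1 elementwise l1 weight (>= 0; 0 gives the pure group
#'   lasso).
#' @param q group norm, `"2"` (standard) or `"inf"`.
#' @param max_iter maximum full sweeps over the rows.
#' @param tol relative objective-change stopping tolerance.
#' @param zero_tol row-norm threshold below which a row counts as zero.
#' @return Object of class `feature_weight_matrix`: `weights` (h x k),
#'   logical `selected`, `objective_trace`, `converged`, and the final
#'   relative gap when not converged.
#' @export
fit_group_sparse_lasso <- function(targets, features, lambda_group,
                                   lambda_l1 = 0, q = c("2", "inf"),
                                   max_iter = 200, tol = 1e-9,
                                   zero_tol = 1e-8) {
  q <- match.arg(q)
  Y <- as.matrix(targets); X <- as.matrix(features)
  if (nrow(Y) != nrow(X)) abort("targets and features must have aligned rows.")
  if (lambda_group < 0 || lambda_l1 < 0) abort("Penalty weights must be nonnegative.")
  h <- ncol(X); k <- ncol(Y)
  W <- matrix(0, h, k, dimnames = list(colnames(X), colnames(Y)))
  a <- colSums(X^2)
  G <- crossprod(X)                # h x h gram
  B <- crossprod(X, Y)             # running b_j = X_j' (Y - X W) + a_j w_j
  E <- Y                           # running residual Y - X W
  penalty <- function(W) {
    rn <- if (q == "2") sqrt(rowSums(W^2)) else apply(abs(W), 1, max)
    lambda_group * sum(rn) + lambda_l1 * sum(abs(W))
  }
  sweep_rows <- function(rows) {
    changed <- FALSE
    for (j in rows) {
      if (a[j] == 0) next
      w_old <- W[j, ]
      b <- B[j, ]                   # X_j'(Y - X_{-j} W_{-j})
      v <- soft_threshold(2 * b, lambda_l1)
      w_new <- group_shrink(v, lambda_group, q) / (2 * a[j])
      dw <- w_new - w_old
      if (any(dw != 0)) {
        W[j, ] <<- w_new
        # maintain B = X'(Y - XW) + diag(a) W and the residual E
        B <<- B - outer(G[, j], dw)
        B[j, ] <<- B[j, ] + a[j] * dw
        E <<- E - outer(X[, j], dw)
        changed <- TRUE
      }
    }
    changed
  }
  obj <- sum(E^2) + penalty(W)
  trace <- obj
  converged <- FALSE
  gap <- NA_real_
  it <- 0L
  while (it < max_iter) {
    # one full sweep guarantees the zero-row optimality conditions ...
    it <- it + 1L
    sweep_rows(seq_len(h))
    obj_new <- sum(E^2) + penalty(W)
    trace <- c(trace, obj_new)
    gap <- abs(obj - obj_new) / max(abs(obj), 1e-12)
    obj <- obj_new
    if (gap <= tol) { converged <- TRUE; break }
    # ... then cheap sweeps over the active rows only
    active <- which(rowSums(W != 0) > 0)
    while (it < max_iter && length(active) > 0) {
      it <- it + 1L
      sweep_rows(active)
      obj_new <- sum(E^2) + penalty(W)
      trace <- c(trace, obj_new)
      gap_a <- abs(obj - obj_new) / max(abs(obj), 1e-12)
      obj <- obj_new
      if (gap_a <= tol) break   # active set settled; verify with a full sweep
    }
  }
  if (!converged) {
    warn(sprintf("Group-sparse-lasso did not converge in %d sweeps (relative gap %.3g).",
                 max_iter, gap))
  }
  rn <- sqrt(rowSums(W^2))
  structure(list(
    weights = W, feature_ids = colnames(X) %||% as.character(seq_len(h)),
    selected = rn > zero_tol, zero_tol = zero_tol,
    lambda_group = lambda_group, lambda_l1 = lambda_l1, q = q,
    objective_trace = trace, converged = converged, final_gap = gap
  ), class = "feature_weight_matrix")
}

#' @export
print.feature_weight_matrix <- function(x, ...) {
  cat(sprintf("<feature_weight_matrix: %d features x %d, %d selected (lambda_group=%.4g, lambda_l1=%.4g)>\n",
              nrow(x$weights), ncol(x$weights), sum(x$selected),
              x$lambda_group, x$lambda_l1))
  invisible(x)
}

#' Tidiers for group-sparse-lasso fits
#'
#' `tidy()` returns one row per feature with its row norm and selection
#' flag; `glance()` a one-row fit summary.
#'
#' @param x a `feature_weight_matrix`.
#' @param ... unused.
#' @name feature_weight_tidiers
#' @method tidy feature_weight_matrix
#' @export
tidy.feature_weight_matrix <- function(x, ...) {
  tibble::tibble(feature = x$feature_ids,
                 row_norm = sqrt(rowSums(x$weights^2)),
                 selected = x$selected)
}

#' @rdname feature_weight_tidiers
#' @method glance feature_weight_matrix
#' @export
glance.feature_weight_matrix <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$weights), n_selected = sum(x$selected),
                 lambda_group = x$lambda_group, lambda_l1 = x$lambda_l1,
                 converged = x$converged,
                 objective = x$objective_trace[length(x$objective_trace)])
}

#' Select per-cancer-type signature genes
#'
#' Restricts the cell-line factor matrix `V` and the expression features to
#' the cell lines of one cancer type, fits [fit_group_sparse_lasso()] along
#' a penalty path, chooses the penalty either by row-wise cross-validation
#' of the reconstruction error or by a target support size, and returns the
#' genes with nonzero weight rows.
#'
#' @param v a `cf_model` or a cell-lines x k factor matrix with rownames.
#' @param features an [omics_matrix()] of expression (genes x cell lines).
#' @param annotation a [panel_annotation()]; may be `NULL` if
#'   `cell_lines` is given directly.
#' @param cancer_type cancer-type label to restrict to.
#' @param cell_lines explicit cell-line ids (overrides annotation lookup).
#' @param lambda_grid decreasing vector of `lambda_group` values; default a
#'   10-point geometric path from just below the all-kill threshold down to
#'   1% of it.
#' @param lambda_l1 elementwise l1 weight (default 0: pure group lasso).
#' @param target_size if given, pick the penalty whose support size is
#'   closest to this (ties to the larger penalty); otherwise use
#'   cross-validation.
#' @param cv_folds folds for row-wise CV.
#' @param standardize centre and unit-scale the feature columns (and centre
#'   the targets) before fitting.
#' @param zero_tol row-norm threshold for selection.
#' @param gsl_max_iter,gsl_tol solver budget per path point (the small-
#'   penalty end of an underdetermined path converges slowly).
#' @param seed RNG seed (CV fold assignment).
#' @return Object of class `signature_set`: `cancer_type`, character
#'   `genes`, and a `provenance` list (chosen lambda, path, k, seed, cells).
#' @export
select_signatures <- function(v, features, annotation = NULL,
                              cancer_type = NULL, cell_lines = NULL,
                              lambda_grid = NULL, lambda_l1 = 0,
                              target_size = NULL, cv_folds = 5,
                              standardize = TRUE, zero_tol = 1e-8,
                              gsl_max_iter = 2000, gsl_tol = 1e-6, seed = 1) {
  V <- if (inherits(v, "cf_model")) v$V else as.matrix(v)
  stopifnot(inherits(features, "omics_matrix"))
  if (is.null(cell_lines)) {
    if (is.null(annotation) || is.null(cancer_type)) {
      abort("Give either `cell_lines` or both `annotation` and `cancer_type`.")
    }
    cell_lines <- names(annotation$cell_types)[annotation$cell_types == cancer_type]
  }
  cell_lines <- intersect(intersect(cell_lines, rownames(V)),
                          colnames(features$values))
  if (length(cell_lines) < 3L) {
    abort(paste0("Cancer type '", cancer_type %||% "?",
                 "' has fewer than 3 usable cell lines."))
  }
  cell_lines <- sort(cell_lines)
  Y <- V[cell_lines, , drop = FALSE]
  X <- t(features$values[, cell_lines, drop = FALSE])
  if (standardize) {
    X <- scale(X)
    keep <- !is.na(colSums(X))   # zero-variance genes can never be selected
    X <- X[, keep, drop = FALSE]
    Y <- scale(Y, scale = FALSE)
  }
  if (is.null(lambda_grid)) {
    lmax <- gsl_lambda_max(Y, X, lambda_l1)
    lambda_grid <- lmax * exp(seq(log(0.9), log(0.01), length.out = 10))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fits <- lapply(lambda_grid, function(l) {
    fit_group_sparse_lasso(Y, X, lambda_group = l, lambda_l1 = lambda_l1,
                           zero_tol = zero_tol, max_iter = gsl_max_iter,
                           tol = gsl_tol)
  })
  sizes <- vapply(fits, function(f) sum(f$selected), integer(1))

  if (!is.null(target_size)) {
    pick <- which.min(abs(sizes - target_size))  # grid is decreasing: ties -> larger lambda
  } else {
    set.seed(seed)
    n <- nrow(Y)
    folds <- max(2L, min(cv_folds, n))
    fold_of <- sample(rep_len(seq_len(folds), n))
    cv_err <- vapply(lambda_grid, function(l) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold_of != f
        fit <- fit_group_sparse_lasso(Y[tr, , drop = FALSE], X[tr, , drop = FALSE],
                                      lambda_group = l, lambda_l1 = lambda_l1,
                                      zero_tol = zero_tol,
                                      max_iter = gsl_max_iter, tol = gsl_tol)
        sum((Y[!tr, , drop = FALSE] - X[!tr, , drop = FALSE] %*% fit$weights)^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    pick <- which.min(cv_err)
  }
  fit <- fits[[pick]]
  genes <- fit$feature_ids[fit$selected]
  if (length(genes) == 0L) {
    warn("Selected signature is empty at the chosen penalty.")
  }
  structure(list(
    cancer_type = cancer_type %||% "all",
    genes = genes,
    fit = fit,
    provenance = list(lambda_group = lambda_grid[pick], lambda_l1 = lambda_l1,
                      lambda_grid = lambda_grid, support_sizes = sizes,
                      k = ncol(Y), seed = seed, cell_lines = cell_lines)
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set %s: %d genes (lambda_group=%.4g)>\n",
              x$cancer_type, length(x$genes), x$provenance$lambda_group))
  invisible(x)
}

#' Overlap and specificity statistics for signature sets
#'
#' For each cancer type reports the signature size, the number of genes
#' found in no other set, and the unique percentage (100 * unique / total,
#' rounded to 2 decimals; `NA` for empty sets), plus the full pairwise
#' intersection-count matrix.
#'
#' @param sets named list of `signature_set` objects or character vectors
#'   (at least 2).
#' @return List of class `signature_overlap` with a tibble `summary` and a
#'   matrix `pairwise`.
#' @export
signature_overlap_stats <- function(sets) {
  if (length(sets) < 2L) abort("Need at least 2 signature sets.")
  genes <- lapply(sets, function(s) {
    unique(if (inherits(s, "signature_set")) s$genes else as.character(s))
  })
  nms <- names(genes)
  if (is.null(nms)) {
    nms <- vapply(sets, function(s)
      if (inherits(s, "signature_set")) s$cancer_type else NA_character_,
      character(1))
  }
  names(genes) <- nms
  summary <- purrr::map_dfr(nms, function(nm) {
    others <- unique(unlist(genes[setdiff(nms, nm)]))
    total <- length(genes[[nm]])
    uniq <- length(setdiff(genes[[nm]], others))
    tibble::tibble(
      cancer_type = nm, total = total, unique = uniq,
      unique_pct = if (total > 0) round(100 * uniq / total, 2) else NA_real_
    )
  })
  pairwise <- outer(nms, nms, Vectorize(function(i, j) {
    length(intersect(genes[[i]], genes[[j]]))
  }))
  dimnames(pairwise) <- list(nms, nms)
  structure(list(summary = summary, pairwise = pairwise),
            class = "signature_overlap")
}

#' @export
print.signature_overlap <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
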