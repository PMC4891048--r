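# Collaborative-filtering drug-sensitivity model: masked nonnegative matrix
# factorization S ~= U V' with graph-Laplacian regularization from the drug
# and cell-line similarity matrices, solved by multiplicative updates.

cf_objective <- function(S0, M, U, V, AD, DDdiag, AC, DCdiag,
                         alpha_drug, alpha_cell, gamma) {
  R <- U %*% t(V)
  loss <- sum((M * (S0 - R))^2)
  lap_d <- if (alpha_drug > 0) sum(U * (DDdiag * U)) - sum(U * (AD %*% U)) else 0
  lap_c <- if (alpha_cell > 0) sum(V * (DCdiag * V)) - sum(V * (AC %*% V)) else 0
  loss + alpha_drug * lap_d + alpha_cell * lap_c +
    gamma * (sum(U^2) + sum(V^2))
}

#' Fit the similarity-regularized collaborative filter
#'
#' Factorizes the observed part of a drug x cell-line pIC50 matrix as
#' `S ~= U V'` with nonnegative factors of rank `k`, minimizing
#' \deqn{\sum_{(i,j)\ observed} (S_{ij} - (UV')_{ij})^2
#'   + \alpha_D\, tr(U' L_D U) + \alpha_C\, tr(V' L_C V)
#'   + \gamma (\|U\|_F^2 + \|V\|_F^2)}
#' where `L_D`, `L_C` are unnormalized graph Laplacians of the drug and
#' cell-line similarity matrices (negative similarities clipped to zero).
#' The Laplacian terms pull the factor rows of similar drugs / cell lines
#' together, which is what lets the model share information across the panel
#' and predict unmeasured entries. Optimization is by multiplicative updates,
#' which preserve nonnegativity and never increase the objective.
#'
#' @param s a [response_matrix()].
#' @param wd drug `similarity_matrix` (or `NULL` for no drug regularization).
#' @param wc cell-line `similarity_matrix` (or `NULL`).
#' @param k factorization rank (latent dimensionality).
#' @param alpha_drug,alpha_cell similarity-regularization weights.
#' @param gamma ridge weight on both factors.
#' @param max_iter,tol stopping rule: relative objective change below `tol`
#'   or `max_iter` iterations.
#' @param seed RNG seed for the nonnegative random initialization.
#' @param init optional list with nonnegative starting matrices `U`
#'   (drugs x k) and `V` (cell lines x k), overriding the random
#'   initialization.
#' @return An object of class `cf_model`: factors `U` (drugs x k), `V`
#'   (cell lines x k), the hyperparameters, and `objective_trace`.
#' @export
fit_cf <- function(s, wd = NULL, wc = NULL, k = 10,
                   alpha_drug = 0.1, alpha_cell = 0.1, gamma = 0.01,
                   max_iter = 500, tol = 1e-6, seed = 1, init = NULL) {
  stopifnot(inherits(s, "response_matrix"), k >= 1)
  M <- s$observed * 1
  S0 <- s$values
  S0[!s$observed] <- 0
  nd <- nrow(S0); nc <- ncol(S0)
  if (any(rowSums(M) == 0)) {
    abort(paste0("Drug(s) with no observed response: ",
                 paste(rownames(S0)[rowSums(M) == 0], collapse = ", ")))
  }
  if (any(colSums(M) == 0)) {
    abort(paste0("Cell line(s) with no observed response: ",
                 paste(colnames(S0)[colSums(M) == 0], collapse = ", ")))
  }
  align_sim <- function(w, ids, axis) {
    if (is.null(w)) return(matrix(0, length(ids), length(ids)))
    stopifnot(inherits(w, "similarity_matrix"))
    if (!identical(w$ids, ids)) {
      if (!all(ids %in% w$ids)) abort(paste0("Similarity matrix missing ", axis, " ids."))
      w$values <- w$values[ids, ids]
    }
    a <- pmax(w$values, 0)  # Laplacian needs nonnegative weights
    diag(a) <- 0
    a
  }
  AD <- align_sim(wd, rownames(S0), "drug")
  AC <- align_sim(wc, colnames(S0), "cell-line")
  DDdiag <- rowSums(AD)
  DCdiag <- rowSums(AC)

  if (!is.null(init)) {
    U <- as.matrix(init$U); V <- as.matrix(init$V)
    stopifnot(identical(dim(U), c(nd, as.integer(k))),
              identical(dim(V), c(nc, as.integer(k))),
              all(U >= 0), all(V >= 0))
  } else {
    set.seed(seed)
    mean_obs <- mean(S0[s$observed])
    scale0 <- max(abs(mean_obs), 1e-3) / sqrt(k)
    U <- matrix(runif(nd * k, 0, scale0), nd, k)
    V <- matrix(runif(nc * k, 0, scale0), nc, k)
  }
  eps <- 1e-12

  obj <- cf_objective(S0, M, U, V, AD, DDdiag, AC, DCdiag,
                      alpha_drug, alpha_cell, gamma)
  trace <- obj
  MS <- M * S0
  for (it in seq_len(max_iter)) {
    R <- M * (U %*% t(V))
    num_u <- MS %*% V + alpha_drug * (AD %*% U)
    den_u <- R %*% V + alpha_drug * (DDdiag * U) + gamma * U + eps
    U <- U * num_u / den_u

    R <- M * (U %*% t(V))
    num_v <- t(MS) %*% U + alpha_cell * (AC %*% V)
    den_v <- t(R) %*% U + alpha_cell * (DCdiag * V) + gamma * V + eps
    V <- V * num_v / den_v

    obj_new <- cf_objective(S0, M, U, V, AD, DDdiag, AC, DCdiag,
                            alpha_drug, alpha_cell, gamma)
    if (!is.finite(obj_new)) {
      abort(paste0("Objective diverged (non-finite) at iteration ", it, "."))
    }
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(obj, eps)) { obj <- obj_new; break }
    obj <- obj_new
  }
  dimnames(U) <- list(rownames(S0), paste0("k", seq_len(k)))
  dimnames(V) <- list(colnames(S0), paste0("k", seq_len(k)))
  structure(list(
    U = U, V = V, k = k,
    hyper = list(alpha_drug = alpha_drug, alpha_cell = alpha_cell,
                 gamma = gamma, max_iter = max_iter, tol = tol, seed = seed),
    objective_trace = trace,
    converged = length(trace) - 1L < max_iter
  ), class = "cf_model")
}

#' Predict pIC50 values from a fitted collaborative filter
#'
#' Returns `(U V')` at the requested positions; defined for unobserved
#' entries, which is the point of the model.
#'
#' @param object a `cf_model`.
#' @param drug_idx,cell_idx integer or character indices. Both `NULL`
#'   returns the full predicted matrix; equal-length vectors return the
#'   elementwise predictions at those (drug, cell) pairs.
#' @param ... unused.
#' @return Numeric matrix, or a vector for paired indices.
#' @export
predict.cf_model <- function(object, drug_idx = NULL, cell_idx = NULL, ...) {
  U <- object$U; V <- object$V
  resolve <- function(idx, ids, what) {
    if (is.character(idx)) idx <- match(idx, ids)
    if (any(is.na(idx)) || any(idx < 1) || any(idx > length(ids))) {
      abort(paste0("Out-of-range ", what, " index."))
    }
    idx
  }
  if (is.null(drug_idx) && is.null(cell_idx)) return(U %*% t(V))
  di <- resolve(drug_idx %||% seq_len(nrow(U)), rownames(U), "drug")
  ci <- resolve(cell_idx %||% seq_len(nrow(V)), rownames(V), "cell-line")
  if (length(di) == length(ci) && !is.null(drug_idx) && !is.null(cell_idx)) {
    unname(rowSums(U[di, , drop = FALSE] * V[ci, , drop = FALSE]))
  } else {
    U[di, , drop = FALSE] %*% t(V[ci, , drop = FALSE])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Entry-wise cross-validation for the collaborative filter
#'
#' Splits the observed entries into `folds` folds, stratified by drug (each
#' drug's observed entries are spread across folds), fits on the training
#' entries of each fold and scores RMSE on the held-out entries, for every
#' row of a hyperparameter grid. Deterministic given `seed`; ties in mean
#' RMSE resolve to the earliest grid row.
#'
#' @param s a [response_matrix()].
#' @param wd,wc similarity matrices passed to [fit_cf()].
#' @param grid data frame of hyperparameter combinations; recognized columns
#'   `k`, `alpha_drug`, `alpha_cell`, `gamma` (missing columns take
#'   [fit_cf()] defaults).
#' @param folds number of folds (>= 2).
#' @param seed RNG seed for fold assignment and fits.
#' @param ... further arguments passed to [fit_cf()] (e.g. `max_iter`).
#' @return List with `best` (the selected grid row as a tibble), `table`
#'   (per-grid-point, per-fold RMSE tibble), `summary` (mean RMSE per grid
#'   point).
#' @export
cross_validate_cf <- function(s, wd = NULL, wc = NULL, grid, folds = 5,
                              seed = 1, ...) {
  stopifnot(inherits(s, "response_matrix"), folds >= 2)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) abort("Hyperparameter grid is empty.")
  obs_idx <- which(s$observed, arr.ind = TRUE)
  set.seed(seed)
  fold_of <- integer(nrow(obs_idx))
  for (d in unique(obs_idx[, 1])) {
    rows <- which(obs_idx[, 1] == d)
    fold_of[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  if (any(tabulate(fold_of, folds) == 0L)) {
    abort("A fold received zero held-out entries; reduce `folds`.")
  }
  defaults <- list(k = 10, alpha_drug = 0.1, alpha_cell = 0.1, gamma = 0.01)
  dots <- list(...)
  hyper_names <- intersect(names(dots), names(defaults))
  defaults <- utils::modifyList(defaults, dots[hyper_names])
  extra <- dots[setdiff(names(dots), hyper_names)]
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    hp <- utils::modifyList(defaults, as.list(grid[g, , drop = FALSE]))
    purrr::map_dfr(seq_len(folds), function(f) {
      test <- obs_idx[fold_of == f, , drop = FALSE]
      train_obs <- s$observed
      train_obs[test] <- FALSE
      if (any(rowSums(train_obs) == 0) || any(colSums(train_obs) == 0)) {
        abort("A training fold left a drug or cell line with no observations.")
      }
      fit <- do.call(fit_cf, c(
        list(response_matrix(s$values, train_obs), wd, wc,
             k = hp$k, alpha_drug = hp$alpha_drug,
             alpha_cell = hp$alpha_cell, gamma = hp$gamma, seed = seed),
        extra))
      pred <- predict(fit)[test]
      tibble::tibble(grid_row = g, fold = f,
                     rmse = rmse(pred, s$values[test]))
    })
  })
  summary <- res |>
    dplyr::group_by(.data$grid_row) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse), .groups = "drop")
  best_row <- summary$grid_row[which.min(summary$mean_rmse)]  # first argmin
  list(best = grid[best_row, , drop = FALSE], table = res, summary = summary)
}

#' @export
print.cf_model <- function(x, ...) {
  cat(sprintf("<cf_model: %d drugs x %d cell lines, rank %d, %d iterations, objective %.4g>\n",
              nrow(x$U), nrow(x$V), x$k, length(x$objective_trace) - 1L,
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' @rdname cf_model_tidiers
#' @method tidy cf_model
#' @export
tidy.cf_model <- function(x, ...) {
  u <- tibble::as_tibble(x$U, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "factor", values_to = "loading") |>
    dplyr::mutate(matrix = "U", .before = 1)
  v <- tibble::as_tibble(x$V, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "factor", values_to = "loading") |>
    dplyr::mutate(matrix = "V", .before = 1)
  dplyr::bind_rows(u, v)
}

#' Tidiers for fitted collaborative-filter models
#'
#' `tidy()` returns the factor loadings in long form; `glance()` a one-row
#' model summary.
#'
#' @param x a `cf_model`.
#' @param ... unused.
#' @name cf_model_tidiers
#' @method glance cf_model
#' @export
glance.cf_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_drugs = nrow(x$U), n_cell_lines = nrow(x$V),
    iterations = length(x$objective_trace) - 1L,
    objective = x$objective_trace[length(x$objective_trace)],
    converged = x$converged
  )
}

#' Plot the optimization trace of a collaborative-filter fit
#'
#' @param object a `cf_model`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cf_model
#' @export
autoplot.cf_model <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Objective (log scale)",
                  title = "Collaborative-filter optimization trace")
}
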