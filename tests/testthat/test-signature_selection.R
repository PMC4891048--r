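gsl_instance <- function(n = 30, h = 12, k = 3, support = 3, seed = 1,
                         noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * h), n, h, dimnames = list(NULL, paste0("f", 1:h)))
  W <- matrix(0, h, k)
  W[seq_len(support), ] <- rnorm(support * k, sd = 1)
  Y <- X %*% W + matrix(rnorm(n * k, 0, noise), n, k)
  list(X = X, Y = Y, W = W, support = paste0("f", seq_len(support)))
}

test_that("the analytic kill threshold zeroes every row exactly", {
  inst <- gsl_instance(seed = 2)
  lmax <- gsl_lambda_max(inst$Y, inst$X)
  dead <- fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = lmax)
  expect_true(all(dead$weights == 0))
  alive <- fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = 0.95 * lmax)
  expect_gt(sum(alive$selected), 0)
  # with an l1 term the threshold shifts accordingly
  lmax1 <- gsl_lambda_max(inst$Y, inst$X, lambda_l1 = 0.5)
  dead1 <- fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = lmax1,
                                  lambda_l1 = 0.5)
  expect_true(all(dead1$weights == 0))
})

test_that("the penalty-free limit is ordinary least squares", {
  set.seed(3)
  X <- diag(8) * 3 + matrix(rnorm(64, 0, 0.3), 8, 8)   # well-conditioned
  W <- matrix(rnorm(16), 8, 2)
  Y <- X %*% W
  fit <- fit_group_sparse_lasso(Y, X, lambda_group = 0, max_iter = 2000,
                                tol = 1e-15)
  ols <- solve(crossprod(X), crossprod(X, Y))
  expect_lt(max(abs(fit$weights - ols)), 1e-6)
})

test_that("planted support is recovered along the penalty path", {
  inst <- gsl_instance(n = 40, h = 100, k = 3, support = 5, seed = 4,
                       noise = 0.2)
  lmax <- gsl_lambda_max(inst$Y, inst$X)
  path <- lmax * exp(seq(log(0.9), log(0.01), length.out = 10))
  recalls <- vapply(path, function(l) {
    fit <- fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = l)
    sel <- fit$feature_ids[fit$selected]
    length(intersect(sel, inst$support)) / length(inst$support)
  }, numeric(1))
  expect_gte(max(recalls), 0.9)
})

test_that("support size is non-increasing in the group penalty", {
  inst <- gsl_instance(seed = 5, noise = 0.3)
  lmax <- gsl_lambda_max(inst$Y, inst$X)
  path <- lmax * exp(seq(log(1), log(0.005), length.out = 10))
  sizes <- vapply(path, function(l)
    sum(fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = l)$selected),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))   # path is decreasing in lambda
})

test_that("KKT conditions hold at convergence", {
  inst <- gsl_instance(n = 25, h = 10, k = 2, support = 3, seed = 6)
  for (l1 in c(0, 0.3)) {
    lmax <- gsl_lambda_max(inst$Y, inst$X, lambda_l1 = l1)
    lg <- 0.3 * lmax
    fit <- fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = lg,
                                  lambda_l1 = l1, tol = 1e-13, max_iter = 500)
    R <- inst$Y - inst$X %*% fit$weights
    G <- 2 * crossprod(inst$X, R)   # negative gradient of the squared loss
    for (j in seq_len(nrow(fit$weights))) {
      if (!fit$selected[j]) {
        # zero rows: subgradient condition on the softthresholded correlation
        expect_lte(sqrt(sum(soft_test(G[j, ], l1)^2)), lg * (1 + 1e-6))
      } else {
        # active rows: stationarity of the smooth + group + l1 subdifferential
        w <- fit$weights[j, ]
        grad <- -G[j, ] + lg * w / sqrt(sum(w^2)) + l1 * sign(w)
        expect_lt(max(abs(grad[w != 0])), 1e-4 * max(1, max(abs(G))))
      }
    }
  }
})

test_that("solver objective agrees with a lattice brute-force oracle", {
  set.seed(7)
  X <- matrix(rnorm(12 * 2), 12, 2)
  Y <- matrix(X %*% c(0.8, -0.4) + rnorm(12, 0, 0.1), ncol = 1)
  lg <- 2; l1 <- 0.5
  fit <- fit_group_sparse_lasso(Y, X, lambda_group = lg, lambda_l1 = l1,
                                tol = 1e-15, max_iter = 1000)
  obj <- function(w1, w2) {
    W <- rbind(w1, w2)
    sum((Y - X %*% W)^2) + lg * (abs(w1) + abs(w2)) + l1 * (abs(w1) + abs(w2))
  }
  grid <- seq(-1.5, 1.5, by = 0.005)
  lattice_min <- min(outer(grid, grid, Vectorize(obj)))
  solver_obj <- fit$objective_trace[length(fit$objective_trace)]
  expect_lte(solver_obj, lattice_min + 1e-9)     # exact solver beats the lattice
  expect_lt(lattice_min - solver_obj, 1e-3)      # and agrees to lattice resolution
})

test_that("negative penalties are rejected and non-convergence warns", {
  inst <- gsl_instance(seed = 8)
  expect_error(fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = -1),
               "nonnegative")
  expect_warning(fit_group_sparse_lasso(inst$Y, inst$X, lambda_group = 0.01,
                                        max_iter = 1, tol = 1e-16),
                 "converge")
})

test_that("the infinity group norm variant solves its own objective", {
  set.seed(9)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  Y <- X[, 1:2] %*% matrix(c(1, 0.5, -0.5, 1), 2, 2) + rnorm(40, 0, 0.05)
  lmax <- gsl_lambda_max(Y, X, q = "inf")
  dead <- fit_group_sparse_lasso(Y, X, lambda_group = lmax, q = "inf")
  expect_true(all(dead$weights == 0))
  fit <- fit_group_sparse_lasso(Y, X, lambda_group = 0.2 * lmax, q = "inf")
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1)))
  expect_true(all(fit$selected[1:2]))
})

test_that("per-type signatures recover planted driver genes", {
  panel <- tiny_panel()
  truth <- panel$truth
  for (tp in names(truth$Q_support)[1:2]) {
    drivers <- truth$Q_support[[tp]]
    # planted resistance genes of this type's drugs are response-correlated
    # by construction, so they legitimately compete for signature slots; the
    # target size accommodates both planted sets
    resist <- unlist(truth$resistance_genes[truth$drug_types == tp])
    sig <- select_signatures(truth$V_true, panel$expression, panel$annotation,
                             tp, target_size = length(drivers) + length(resist),
                             seed = 1)
    expect_gte(length(intersect(sig$genes, drivers)) / length(drivers), 0.8)
  }
})

test_that("signature selection is deterministic and can return empty sets", {
  panel <- tiny_panel()
  tp <- "type1"
  s1 <- select_signatures(panel$truth$V_true, panel$expression,
                          panel$annotation, tp, target_size = 5, seed = 3)
  s2 <- select_signatures(panel$truth$V_true, panel$expression,
                          panel$annotation, tp, target_size = 5, seed = 3)
  expect_identical(s1$genes, s2$genes)

  cells <- names(panel$annotation$cell_types)[panel$annotation$cell_types == tp]
  Y <- panel$truth$V_true[sort(cells), ]
  X <- scale(t(panel$expression$values[, sort(cells)]))
  X <- X[, !is.na(colSums(X)), drop = FALSE]
  lmax <- gsl_lambda_max(scale(Y, scale = FALSE), X)
  expect_warning(
    empty <- select_signatures(panel$truth$V_true, panel$expression,
                               panel$annotation, tp,
                               lambda_grid = 2 * lmax, seed = 3),
    "empty")
  expect_length(empty$genes, 0)
  expect_error(select_signatures(panel$truth$V_true, panel$expression,
                                 panel$annotation, "absent-type"),
               "fewer than 3")
})

test_that("overlap statistics report totals, uniques and percentages", {
  st <- signature_overlap_stats(list(a = c("g1", "g2", "g3"),
                                     b = c("g3", "g4"),
                                     c = c("g5")))
  expect_equal(st$summary$total, c(3, 2, 1))
  expect_equal(st$summary$unique, c(2, 1, 1))
  expect_equal(st$summary$unique_pct, c(66.67, 50, 100))
  expect_equal(st$pairwise["a", "b"], 1)
  # disjoint sets are fully specific
  dj <- signature_overlap_stats(list(x = c("g1"), y = c("g2")))
  expect_equal(dj$summary$unique_pct, c(100, 100))
  # empty set: percentage not available
  em <- signature_overlap_stats(list(x = character(0), y = c("g2")))
  expect_true(is.na(em$summary$unique_pct[1]))
})
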