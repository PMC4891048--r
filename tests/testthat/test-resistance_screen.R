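test_that("outlier detection applies the ceiling rule and lexicographic ties", {
  # 10 identical points plus one distant: ceiling(0.10 * 11) = 2, so the
  # distant point plus the lexicographically first identical one
  m <- matrix(0, 2, 11, dimnames = list(NULL, c(paste0("c", 10:19), "zfar")))
  m[, "zfar"] <- c(100, 0)
  out <- detect_outliers(m, 0.10)
  expect_setequal(out, c("zfar", "c10"))
  expect_identical(out[1], "zfar")

  # distances to the center (10/3, 0): one third removed is the far point
  m2 <- matrix(c(0, 0, 0, 0, 10, 0), 2, 3,
               dimnames = list(NULL, c("a", "b", "far")))
  expect_identical(detect_outliers(m2, 1 / 3), "far")

  # all identical: purely tie-broken, exact size
  m3 <- matrix(1, 3, 10, dimnames = list(NULL, paste0("c", 10:19)))
  expect_identical(detect_outliers(m3, 0.25), c("c10", "c11", "c12"))

  expect_error(detect_outliers(m3, 0.999), "every cell line")
  expect_error(detect_outliers(m3[, 1, drop = FALSE], 0.5), "at least 2")
})

test_that("outlier set size is always ceiling(fraction * n)", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    fr <- runif(1, 0.05, 0.5)
    m <- matrix(rnorm(3 * n), 3, n, dimnames = list(NULL, paste0("c", seq_len(n))))
    if (ceiling(fr * n) >= n) next
    expect_length(detect_outliers(m, fr), ceiling(fr * n))
  }
})

test_that("silent mutations are excluded and the binary matrix built from the rest", {
  mt <- mutation_table(tibble::tibble(
    gene = c("g1", "g1", "g2", "g3", "g3"),
    cell_line = c("a", "b", "a", "b", "c"),
    effect_class = c("silent", "nonsilent", "silent", "silent", "nonsilent")
  ))
  ns <- exclude_silent(mt)
  expect_equal(nrow(ns), 2)
  expect_true(all(ns$effect_class == "nonsilent"))
  expect_identical(exclude_silent(ns), ns)   # no silent: identity
  expect_warning(
    empty <- exclude_silent(mutation_table(tibble::tibble(
      gene = "g1", cell_line = "a", effect_class = "silent"))),
    "nonsilent")
  expect_equal(nrow(empty), 0)

  mm <- mutation_matrix(mt, cell_lines = c("a", "b", "c"))
  expect_equal(mm["g1", ], c(a = 0, b = 1, c = 0))
  expect_equal(mm["g3", "c"], 1)
})

test_that("quantile discretization labels the distribution tails", {
  resp <- setNames(1:8, paste0("c", 1:8))
  call <- discretize_activity(resp, q = 0.25)
  expect_equal(unname(call$labels[paste0("c", 1:8)]),
               c(-1L, -1L, 0L, 0L, 0L, 0L, 1L, 1L))

  # constant vector: all moderate, with a warning
  expect_warning(flat <- discretize_activity(setNames(rep(2, 5), letters[1:5])),
                 "identical")
  expect_true(all(flat$labels == 0L))

  # median split at q = 0.5: odd n leaves exactly the middle value moderate
  odd <- discretize_activity(setNames(c(3, 1, 5, 2, 4), letters[1:5]), q = 0.5)
  expect_equal(sum(odd$labels == 0L), 1)
  expect_equal(names(odd$labels)[odd$labels == 0L], "a")   # middle value 3
  even <- discretize_activity(setNames(1:6, letters[1:6]), q = 0.5)
  expect_equal(sum(even$labels == 0L), 0)

  expect_error(discretize_activity(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("z-score discretization cuts at the stated threshold", {
  resp <- setNames(c(-10, 0, 0, 0, 0, 10), letters[1:6])
  call <- discretize_activity(resp, method = "zscore", z_cut = 1)
  expect_equal(unname(call$labels[c("a", "f")]), c(-1L, 1L))
  expect_true(all(call$labels[c("b", "c", "d", "e")] == 0L))
})

test_that("spearman screen computes rho and applies the pass rules", {
  lines <- paste0("c", 1:5)
  y <- setNames(1:5, lines)
  expr <- matrix(0, 4, 5, dimnames = list(c("mono", "swap", "anti", "flat"), lines))
  expr["mono", ] <- exp(1:5)                  # strictly increasing in pIC50
  expr["swap", ] <- c(1, 2, 3, 5, 4)          # one adjacent swap: rho = 0.9
  expr["anti", ] <- 5:1
  expr["flat", ] <- 3
  cnv <- expr; cnv["anti", ] <- 5:1           # CNV decreasing too for 'anti'
  cnv["swap", ] <- 1:5
  calls <- make_activity_call(setNames(c(-1L, -1L, 0L, 1L, 1L), lines))
  calls$labels[] <- c(-1L, -1L, 1L, 1L, 1L)   # keep all 5 lines in the screen
  hits <- spearman_screen(omics_matrix(expr), omics_matrix(cnv, "cnv"),
                          calls, y)
  h <- function(g) hits[hits$gene == g, ]
  expect_equal(h("mono")$rho_expr, 1)
  expect_equal(h("mono")$rho_cnv, 1)
  expect_true(h("mono")$passed)
  expect_equal(h("swap")$rho_expr, 0.9)
  expect_true(h("swap")$passed)               # 0.9 > 0.7 with concordant CNV
  expect_true(h("anti")$passed)               # both negative: concordant
  expect_equal(h("anti")$rho_expr, -1)
  expect_false(h("flat")$passed)
  expect_match(h("flat")$reason, "variance")

  # discordant signs fail even with perfect correlations
  cnv2 <- cnv; cnv2["mono", ] <- 5:1
  hits2 <- spearman_screen(omics_matrix(expr), omics_matrix(cnv2, "cnv"),
                           calls, y)
  expect_false(hits2[hits2$gene == "mono", ]$passed)
  expect_match(hits2[hits2$gene == "mono", ]$reason, "discordant")
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  lines <- paste0("c", 1:6)
  y <- setNames(c(2, 4, 1, 6, 3, 5), lines)
  e <- matrix(runif(6, 1, 2), 1, 6, dimnames = list("g", lines))
  calls <- make_activity_call(setNames(rep(c(-1L, 1L), 3), lines))
  base <- spearman_screen(omics_matrix(e), omics_matrix(e, "cnv"), calls, y)
  for (f in list(exp, log, function(x) x^3)) {
    tr <- spearman_screen(omics_matrix(f(e)), omics_matrix(f(e), "cnv"),
                          calls, y)
    expect_equal(tr$rho_expr, base$rho_expr)
  }
})

test_that("the full screen recovers planted resistance genes with no false positives", {
  panel <- tiny_panel(seed = 7)
  truth <- panel$truth
  drug <- "D001"
  tp <- truth$drug_types[[drug]]
  planted <- truth$resistance_genes[[drug]]
  # negatives are genes with no planted coupling to any response
  clean <- setdiff(rownames(panel$expression$values),
                   c(unlist(truth$Q_support), unlist(truth$resistance_genes)))
  set.seed(1)
  sig <- c(planted, sample(clean, 50))
  hits <- run_resistance_screen(panel, panel$annotation, sig, drug,
                                cancer_type = tp)
  expect_setequal(hits$gene[hits$passed], planted)
  # planted signs are recovered with concordant expression/CNV directions
  got <- hits[hits$gene %in% planted, ]
  expect_equal(sign(got$rho_expr), sign(got$rho_cnv))
})

test_that("the screen is invariant to cell-line ordering", {
  panel <- tiny_panel(seed = 8)
  truth <- panel$truth
  drug <- "D002"
  tp <- truth$drug_types[[drug]]
  sig <- union(truth$Q_support[[tp]], truth$resistance_genes[[drug]])
  hits1 <- run_resistance_screen(panel, panel$annotation, sig, drug,
                                 cancer_type = tp)
  perm <- sample(colnames(panel$expression$values))
  panel2 <- panel
  panel2$expression <- omics_matrix(panel$expression$values[, perm], "expression")
  panel2$cnv <- omics_matrix(panel$cnv$values[, perm], "cnv")
  panel2$response <- response_matrix(panel$response$values[, perm],
                                     panel$response$observed[, perm])
  panel2$annotation <- panel_annotation(panel$annotation$cell_types[perm],
                                        panel$annotation$drug_targets)
  hits2 <- run_resistance_screen(panel2, panel2$annotation, sig, drug,
                                 cancer_type = tp)
  expect_equal(hits1[order(hits1$gene), ], hits2[order(hits2$gene), ],
               ignore_attr = TRUE)
})

test_that("outlier fraction zero is a no-op stage", {
  panel <- tiny_panel(seed = 9, outlier_count = 0)
  truth <- panel$truth
  drug <- "D003"
  tp <- truth$drug_types[[drug]]
  sig <- union(truth$Q_support[[tp]], truth$resistance_genes[[drug]])
  auto <- run_resistance_screen(panel, panel$annotation, sig, drug,
                                cancer_type = tp, outlier_fraction = 0)
  expect_length(attr(auto, "removed_outliers"), 0)
  # manual composition without the outlier stage gives identical hits
  cells <- sort(names(panel$annotation$cell_types)[panel$annotation$cell_types == tp])
  resp <- panel$response$values[drug, cells]
  resp <- resp[!is.na(resp)]
  calls <- discretize_activity(resp, drug = drug)
  manual <- spearman_screen(panel$expression, panel$cnv, calls, resp,
                            candidate_genes = intersect(sig, rownames(panel$expression$values)))
  expect_equal(tibble::as_tibble(auto), tibble::as_tibble(manual),
               ignore_attr = TRUE)
})

test_that("planted discordant-CNV genes yield no hits", {
  panel <- tiny_panel(seed = 10)
  truth <- panel$truth
  drug <- "D001"
  tp <- truth$drug_types[[drug]]
  planted <- truth$resistance_genes[[drug]]
  # flip the CNV direction of every planted gene within the drug's type
  cells <- names(panel$annotation$cell_types)[panel$annotation$cell_types == tp]
  cnv2 <- panel$cnv$values
  cnv2[planted, cells] <- 4 - cnv2[planted, cells]
  panel$cnv <- omics_matrix(cnv2, "cnv")
  hits <- run_resistance_screen(panel, panel$annotation, planted, drug,
                                cancer_type = tp)
  expect_equal(sum(hits$passed), 0)
})
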