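# Shared fixtures, generated in code: a small simulated panel and a couple
# of TSV writers for reader tests.

tiny_panel <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_drugs = 12, n_cells = 90, n_genes = 120, k_true = 3, n_types = 3,
         driver_count = 5, resist_count = 3, outlier_count = 2,
         missing_fraction = 0.2, noise_sd = 0.1, seed = seed),
    list(...))
  do.call(simulate_panel, args)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# planted low-rank response for collaborative-filter tests
planted_response <- function(n_drugs = 20, n_cells = 30, k = 2, seed = 7,
                             noise_sd = 0, missing_fraction = 0) {
  set.seed(seed)
  U <- matrix(runif(n_drugs * k, 0.5, 2), n_drugs, k)
  V <- matrix(runif(n_cells * k, 0.5, 2), n_cells, k)
  S <- U %*% t(V) + matrix(rnorm(n_drugs * n_cells, 0, noise_sd), n_drugs, n_cells)
  dimnames(S) <- list(sprintf("D%02d", 1:n_drugs), sprintf("C%02d", 1:n_cells))
  obs <- matrix(TRUE, n_drugs, n_cells, dimnames = dimnames(S))
  if (missing_fraction > 0) {
    obs[sample(length(S), round(missing_fraction * length(S)))] <- FALSE
    for (i in which(rowSums(obs) == 0)) obs[i, sample(n_cells, 1)] <- TRUE
    for (j in which(colSums(obs) == 0)) obs[sample(n_drugs, 1), j] <- TRUE
  }
  list(s = response_matrix(S, obs), U = U, V = V)
}

soft_test <- function(v, l) sign(v) * pmax(abs(v) - l, 0)

similarity_from_random <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  w <- (a + t(a)) / 2
  diag(w) <- 1
  structure(list(values = w, metric = "cosine",
                 ids = as.character(seq_len(n))),
            class = "similarity_matrix")
}

make_activity_call <- function(labels, drug = "D1") {
  structure(list(drug = drug, labels = labels, method = "manual",
                 params = list()), class = "activity_call")
}
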