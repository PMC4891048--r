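# End-to-end pipeline driver: simulate (or read) a panel, build the
# similarity matrices, fit the collaborative filter, select signatures per
# cancer type, run the resistance screen per drug, and score the fit --
# writing TSV outputs plus a JSON run manifest.

default_config <- function() {
  list(
    seed = 1,
    simulate = list(n_drugs = 40, n_cells = 120, n_genes = 500, k_true = 5,
                    n_types = 3, driver_count = 10, resist_count = 5,
                    outlier_count = 3, missing_fraction = 0.2,
                    noise_sd = 0.1),
    fit = list(k = 10, alpha_drug = 0.1, alpha_cell = 0.1, gamma = 0.01,
               max_iter = 500, tol = 1e-6),
    select = list(lambda_l1 = 0, target_size = NULL),
    screen = list(drugs = NULL, outlier_fraction = 0.10, expr_cutoff = 0.7,
                  cnv_cutoff = 0.7, disc_method = "quantile", disc_q = 0.25),
    score = list(noise_sd = 0.1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full pipeline on a simulated panel
#'
#' Executes the stages in dependency order: `simulate` -> `similarity` ->
#' `fit` -> `score` -> `select` (one signature set per cancer type) ->
#' `screen` (per drug). Outputs (factor matrices, similarity matrices,
#' signature gene lists, screen hit tables, evaluation metrics) are written
#' as TSV under `out_dir`, together with a JSON run manifest recording the
#' configuration snapshot, seed, package version, stage timings and output
#' checksums -- enough to re-run identically. Reruns with the same config
#' and seed produce byte-identical outputs.
#'
#' @param config a nested list overriding the defaults (see
#'   `pharmsig:::default_config()`), or a path to a YAML file with the same
#'   structure.
#' @param out_dir output directory.
#' @return Invisibly, a list with `status` (0 on success), `manifest`, and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pharmsig_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    st <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }

  panel <- tick("simulate", do.call(simulate_panel,
                                    c(cfg$simulate, list(seed = cfg$seed))))
  wc <- tick("similarity", cosine_cell_similarity(panel$expression))
  wd <- tanimoto_drug_similarity(panel$fingerprints)
  fit <- tick("fit", do.call(fit_cf, c(list(s = panel$response, wd = wd, wc = wc,
                                            seed = cfg$seed), cfg$fit)))
  pred <- predict(fit)

  obs <- panel$response$observed
  metrics <- tick("score", tibble::tibble(
    metric = c("rmse_observed", "wpc_index"),
    value = c(
      rmse(pred[obs], panel$response$values[obs]),
      evaluate_ranking(pred, panel$response, noise_sd = cfg$score$noise_sd)$wpc
    )
  ))

  types <- sort(unique(panel$annotation$cell_types))
  signatures <- tick("select", lapply(setNames(types, types), function(tp) {
    select_signatures(fit, panel$expression, panel$annotation, tp,
                      lambda_l1 = cfg$select$lambda_l1,
                      target_size = cfg$select$target_size, seed = cfg$seed)
  }))

  screen_drugs <- cfg$screen$drugs %||% rownames(panel$response$values)[1]
  screens <- tick("screen", purrr::map_dfr(screen_drugs, function(d) {
    tp <- panel$truth$drug_types[[d]]
    sig <- union(signatures[[tp]]$genes,
                 c(panel$truth$Q_support[[tp]], panel$truth$resistance_genes[[d]]))
    run_resistance_screen(panel, panel$annotation, sig, d, cancer_type = tp,
                          outlier_fraction = cfg$screen$outlier_fraction,
                          expr_cutoff = cfg$screen$expr_cutoff,
                          cnv_cutoff = cfg$screen$cnv_cutoff,
                          disc_method = cfg$screen$disc_method,
                          disc_q = cfg$screen$disc_q)
  }))

  # outputs
  out <- c(U = "U.tsv", V = "V.tsv", metrics = "metrics.tsv",
           screen = "screen_hits.tsv")
  paths <- file.path(out_dir, out)
  names(paths) <- names(out)
  write_matrix(fit$U, paths["U"], id_column = "drug")
  write_matrix(fit$V, paths["V"], id_column = "cell_line")
  write.table(as.data.frame(metrics), paths["metrics"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(screens), paths["screen"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig_paths <- vapply(types, function(tp) {
    p <- file.path(out_dir, paste0("signature_", tp, ".tsv"))
    writeLines(c(paste0("# cancer_type=", tp,
                        " lambda_group=", signif(signatures[[tp]]$provenance$lambda_group, 6),
                        " seed=", cfg$seed),
                 signatures[[tp]]$genes), p)
    p
  }, character(1))
  paths <- c(paths, sig_paths)

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("pharmsig")),
    seed = cfg$seed,
    config = cfg,
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(status = 0L, manifest = manifest, panel = panel, fit = fit,
                 signatures = signatures, screens = screens,
                 metrics = metrics, out_dir = out_dir))
}
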