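#' Assemble an end-to-end run configuration
#'
#' Either a synthetic-data configuration (`synth`) or paths to an
#' existing panel CSV and adjacency edge list must be supplied.
#'
#' @param out_dir Output directory (created if absent).
#' @param synth Optional [synth_config()]; when given, the pipeline
#'   starts by simulating its panel and adjacency.
#' @param panel_path,adjacency_path Input files used when `synth` is
#'   `NULL`.
#' @param selection A [screening_config()], or `NULL` to skip selection
#'   and model every factor column.
#' @param mcmc An [mcmc_config()].
#' @param scenarios Scenario ids to project.
#' @param meta Factor metadata table ([default_factor_meta()] layout).
#' @param sdg An [sdg_config()].
#' @param prune Drop factors whose 95% credible interval straddles zero
#'   before prediction.
#' @param seed Master seed recorded in the manifest.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       synth = NULL,
                       panel_path = NULL, adjacency_path = NULL,
                       selection = NULL,
                       mcmc = mcmc_config_test(),
                       scenarios = c("S1", "S2", "S3", "S4"),
                       meta = default_factor_meta(),
                       sdg = sdg_config(),
                       prune = FALSE,
                       seed = 1L) {
  if (is.null(synth) && (is.null(panel_path) || is.null(adjacency_path))) {
    stop("supply either `synth` or both `panel_path` and `adjacency_path`",
         call. = FALSE)
  }
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stop("panel file not found: ", panel_path, call. = FALSE)
  }
  if (!is.null(adjacency_path) && !file.exists(adjacency_path)) {
    stop("adjacency file not found: ", adjacency_path, call. = FALSE)
  }
  structure(list(out_dir = out_dir, synth = synth, panel_path = panel_path,
                 adjacency_path = adjacency_path, selection = selection,
                 mcmc = mcmc, scenarios = scenarios, meta = meta, sdg = sdg,
                 prune = isTRUE(prune), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full projection pipeline
#'
#' Simulate (or load) the county panel, optionally select factors,
#' fit the spatio-temporal model, optionally prune non-significant
#' factors, project coverage under every requested scenario, predict
#' counterfactual U5M, and write all artifacts plus a manifest of
#' seeds and input checksums to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory artifacts: `panel`,
#'   `adjacency`, `selection`, `draws`, `summary`, `convergence`,
#'   `result`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("data", {
    if (!is.null(config$synth)) {
      adj <- make_adjacency(config$synth$n_counties, seed = config$synth$seed)
      sim <- simulate_panel(config$synth, adj)
      write_truth(sim$truth, p("truth.json"))
      list(panel = sim$panel, adjacency = adj)
    } else {
      list(panel = read_panel(config$panel_path),
           adjacency = read_adjacency(config$adjacency_path))
    }
  })
  write_panel(inputs$panel, p("panel.csv"))
  write_adjacency(inputs$adjacency, p("adjacency.txt"))

  all_factors <- setdiff(names(inputs$panel), c("county_id", "year", "u5m"))
  selection <- NULL
  factors <- all_factors
  if (!is.null(config$selection)) {
    selection <- stage("selection", run_model_pair(inputs$panel, config$selection))
    factors <- intersect(selection$retained, all_factors)
    jsonlite::write_json(
      selection[c("screened", "excluded_redundant", "chosen_model",
                  "retained", "cv_mse")],
      p("selection.json"), auto_unbox = TRUE, digits = NA)
  }

  spec <- model_spec(factors)
  draws <- stage("fit", fit_st_model(inputs$panel, inputs$adjacency, spec,
                                     config$mcmc, store_delta = FALSE))
  if (config$prune) {
    pruned <- stage("prune", prune_nonsignificant(draws, inputs$panel,
                                                  inputs$adjacency, config$mcmc))
    draws <- pruned$draws
    factors <- pruned$factors
  }
  summ <- summarize_posterior(draws)
  conv <- check_convergence(summ)
  write_csv_schema(summ, p("posterior_summary.csv"), "posterior_summary")

  coef <- coefficient_set(draws)
  result <- stage("report", projection_result(
    inputs$panel, coef, factors = factors,
    scenarios = config$scenarios, meta = config$meta, sdg = config$sdg))
  write_csv_schema(result$u5m, p("u5m_projections.csv"), "u5m_projections")
  write_csv_schema(result$attainment, p("sdg_attainment.csv"), "sdg_attainment")
  write_csv_schema(result$single_factor_pct_change,
                   p("single_factor_impacts.csv"), "single_factor_impacts")

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "u5mproj",
    version = as.character(utils::packageVersion("u5mproj")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    mcmc_seed = config$mcmc$seed,
    convergence_pass = conv$overall,
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(panel = inputs$panel, adjacency = inputs$adjacency,
                 selection = selection, draws = draws, summary = summ,
                 convergence = conv, result = result, manifest = manifest))
}

# CSV writer with the schema-version comment line all artifacts carry
write_csv_schema <- function(df, path, name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema: u5mproj/%s v1", name), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
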