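#' Run configuration for the fit/validate/simulate pipeline
#'
#' Exactly one of `data` (path to a trait CSV) or `synthetic` (a
#' [synthetic_spec()], or `TRUE` for the default spec) must be supplied.
#'
#' @param data Optional path to a wetland-trait CSV.
#' @param synthetic Optional [synthetic_spec()] or `TRUE`.
#' @param structure Path to a structure file, or a [network_structure()];
#'   default [default_structure()].
#' @param scenarios `"builtin"` (default) for [scenario_catalog()], or a
#'   path to a scenario JSON/YAML file.
#' @param n_samples Monte Carlo draws per scenario.
#' @param n_sims Simulated datasets for validation.
#' @param seed Integer seed recorded in every output artifact.
#' @param out_dir Output directory (created if absent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(data = NULL, synthetic = NULL,
                       structure = default_structure(),
                       scenarios = "builtin", n_samples = 1e5,
                       n_sims = 1e4, seed = 1L, out_dir = "wetlandbn-out") {
  if (is.null(data) == is.null(synthetic)) {
    stop("config error: supply exactly one of `data` or `synthetic`",
         call. = FALSE)
  }
  if (isTRUE(synthetic)) synthetic <- default_synthetic_spec()
  if (is.character(structure)) structure <- load_structure(structure)
  stopifnot(inherits(structure, "network_structure"))
  structure(
    list(data = data, synthetic = synthetic, structure = structure,
         scenarios = scenarios, n_samples = n_samples, n_sims = n_sims,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

# Polynomial rolling hash over the serialized config; identifies a run in
# output manifests (not cryptographic).
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config[setdiff(
    names(config), "out_dir")])), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

config_table <- function(config) {
  if (!is.null(config$data)) {
    load_trait_table(config$data)
  } else {
    generate_wetlands(config$synthetic, seed = config$seed)
  }
}

manifest <- function(config, stage, extra = list()) {
  c(list(stage = stage, seed = config$seed,
         config_hash = config_hash(config),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
}

#' Fit stage: calibrate the network and write the model artifacts
#'
#' Writes `model.json` (margins and z-space matrix), `arc_partials.csv`
#' and a run manifest to the output directory.
#'
#' @param config A [run_config()].
#' @return The fitted model, invisibly.
#' @export
cmd_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- config_table(config)
  model <- fit_network(tab, config$structure)
  write_fitted_model(model, file.path(config$out_dir, "model.json"),
                     seed = config$seed,
                     config_hash = config_hash(config))
  at <- arc_partial_table(model)
  at$seed <- config$seed
  at$config_hash <- config_hash(config)
  utils::write.csv(at, file.path(config$out_dir, "arc_partials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest(config, "fit", list(n = model$n)),
                       file.path(config$out_dir, "manifest_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

#' Validation stage: determinant test and report
#'
#' Writes `validation.json` and a band figure to the output directory.
#'
#' @param config A [run_config()].
#' @param model Optional fitted model; fitted from the config when absent.
#' @return The [validate_model()] report, invisibly.
#' @export
cmd_validate <- function(config, model = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- config_table(config)
  if (is.null(model)) model <- fit_network(tab, config$structure)
  rep <- validate_model(model, tab, n_sims = config$n_sims,
                        seed = config$seed)
  write_validation_report(rep, file.path(config$out_dir, "validation.json"))
  p <- plot_validation(rep)
  ggplot2::ggsave(file.path(config$out_dir, "validation_band.png"), p,
                  width = 6, height = 4, dpi = 150)
  jsonlite::write_json(
    manifest(config, "validate",
             list(passed = rep$passed,
                  quantile_position = rep$quantile_position)),
    file.path(config$out_dir, "manifest_validate.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Simulation stage: run the scenario catalog and write results
#'
#' Writes `scenario_results.csv` (one row per scenario: code, mu, sigma,
#' delta vs baseline, 10 bin proportions, 10 wetland counts) and one
#' histogram figure per scenario.
#'
#' @param config A [run_config()].
#' @param model Optional fitted model; fitted from the config when absent.
#' @param plots If `TRUE` (default), write per-scenario histogram figures.
#' @return Named list of [run_scenario()] results, invisibly.
#' @export
cmd_simulate <- function(config, model = NULL, plots = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(model)) model <- fit_network(config_table(config),
                                           config$structure)
  catalog <- if (identical(config$scenarios, "builtin")) {
    scenario_catalog()
  } else {
    load_scenarios(config$scenarios)
  }
  results <- run_catalog(model, catalog, n_samples = config$n_samples,
                         seed = config$seed)
  tab <- scenario_result_table(results)
  tab$config_hash <- config_hash(config)
  utils::write.csv(tab, file.path(config$out_dir, "scenario_results.csv"),
                   row.names = FALSE)
  if (plots) {
    for (r in results) {
      ggplot2::ggsave(
        file.path(config$out_dir, sprintf("scenario_%s.png", r$code)),
        plot_scenario_result(r), width = 5, height = 4, dpi = 150)
    }
  }
  jsonlite::write_json(manifest(config, "simulate",
                                list(n_scenarios = length(results))),
                       file.path(config$out_dir, "manifest_simulate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

# ---- serialization ---------------------------------------------------------

#' Serialize a fitted model to JSON
#'
#' Margins are stored as order-statistic arrays and the z-space matrix as a
#' nested list, so the model round-trips through [read_fitted_model()].
#'
#' @param model A [fit_network()] result.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields embedded in the file.
#' @return `path`, invisibly.
#' @export
write_fitted_model <- function(model, path, seed = NULL,
                               config_hash = NULL) {
  stopifnot(inherits(model, "fitted_model"))
  payload <- list(
    nodes = model$structure$nodes, arcs = model$structure$arcs,
    fit_mode = model$fit_mode, n = model$n,
    margins = lapply(model$margins, `[[`, "sorted_values"),
    R = model$copula$R,
    arc_partials = as.list(model$arc_partials),
    seed = seed, config_hash = config_hash)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path Path written by [write_fitted_model()].
#' @return A `fitted_model`.
#' @export
read_fitted_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  st <- network_structure(raw$nodes, raw$arcs)
  R <- as.matrix(raw$R)
  dimnames(R) <- list(st$nodes$name, st$nodes$name)
  model <- structure(
    list(structure = st,
         margins = lapply(raw$margins, empirical_margin),
         copula = gaussian_copula(R),
         arc_partials = unlist(raw$arc_partials),
         fit_mode = raw$fit_mode, n = raw$n),
    class = "fitted_model")
  model
}

# ---- figures ---------------------------------------------------------------

#' Histogram figure for one scenario result
#'
#' Bars give the expected proportion of wetlands (%) per species-richness
#' interval; the subtitle reports the conditional mean and SD.
#'
#' @param result A [run_scenario()] result.
#' @return A ggplot object.
#' @export
plot_scenario_result <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  b <- result$bin_breaks
  df <- data.frame(
    interval = factor(sprintf("%g-%g", b[-11], b[-1]),
                      levels = sprintf("%g-%g", b[-11], b[-1])),
    pct = 100 * result$histogram)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interval, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("Scenario %s (%s)", result$code, result$label),
      subtitle = sprintf("μ = %.1f, σ = %.2f", result$mu,
                         result$sigma),
      x = "Number of bird species", y = "Wetlands (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Band figure for a validation report
#'
#' Histogram of the simulated determinants with the confidence band and the
#' observed determinant marked.
#'
#' @param report A [validate_model()] result.
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  df <- data.frame(d = report$d_nr_samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = unname(report$band),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = report$d_er, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      title = "Normal-copula validation",
      subtitle = sprintf(
        "D_ER = %.4f at quantile %.2f of simulated D_NR (%.0f%% band)",
        report$d_er, report$quantile_position, 100 * report$band_level),
      x = "Determinant of simulated normal rank correlation matrix",
      y = "Simulations") +
    ggplot2::theme_minimal()
}
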