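#' Build a scenario
#'
#' @param code Single letter identifying the scenario.
#' @param label One of `"baseline"`, `"worst-case"`, `"best-case"`,
#'   `"mixed"`.
#' @param evidence Named numeric vector/list mapping driver nodes to the
#'   values they are fixed at (data scale). The target node may not appear.
#' @param schema Schema used to range-check the evidence values.
#' @return An object of class `scenario`.
#' @export
scenario <- function(code, label = c("baseline", "worst-case", "best-case",
                                     "mixed"),
                     evidence = numeric(0), schema = default_schema()) {
  label <- match.arg(label)
  evidence <- unlist(evidence)
  if (length(evidence) && is.null(names(evidence))) {
    stop("evidence must be named by node", call. = FALSE)
  }
  if (target_node() %in% names(evidence)) {
    stop("evidence may not include the target node", call. = FALSE)
  }
  for (nm in names(evidence)) {
    s <- schema[[nm]]
    if (is.null(s)) stop("evidence on unknown node '", nm, "'",
                         call. = FALSE)
    v <- evidence[[nm]]
    if (v < s$allowed_range[1] || v > s$allowed_range[2]) {
      stop(sprintf("evidence value %s for '%s' outside [%s, %s]",
                   format(v), nm, format(s$allowed_range[1]),
                   format(s$allowed_range[2])), call. = FALSE)
    }
  }
  structure(list(code = code, label = label, evidence = evidence),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  ev <- if (length(x$evidence)) {
    paste(names(x$evidence), "=", x$evidence, collapse = ", ")
  } else "none"
  cat(sprintf("<scenario %s> (%s) %s\n", x$code, x$label, ev))
  invisible(x)
}

#' The built-in 18-scenario catalog
#'
#' Scenarios a-r: the 2016 baseline (a); six single-driver worst cases in
#' which tourism pressure, water salinity, water discharges, anthropization
#' and mean water level are pushed to their worst level and water diversions
#' removed (b-g); their union, the worst possible scenario (h); the six
#' mirror-image management scenarios (i-n) and their union, the best
#' possible scenario (o); and three mixed scenarios (p-r) in which all
#' drivers deteriorate except one that a conservation measure neutralizes.
#'
#' @param schema Schema used to range-check evidence; defaults to
#'   [default_schema()].
#' @return Named list of 18 [scenario()] objects, `a` through `r`.
#' @export
scenario_catalog <- function(schema = default_schema()) {
  worst <- c("Tourism pressure" = 3, "Water salinity" = 3,
             "Water discharges" = 2, "Anthropization" = 2,
             "Mean water level" = 11, "Water diversions" = 0)
  best <- c("Tourism pressure" = 0, "Water salinity" = 0,
            "Water discharges" = 0, "Anthropization" = 0,
            "Mean water level" = 3, "Water diversions" = 3)
  override <- function(base, nm) { base[nm] <- best[nm]; base }
  sc <- list(
    a = scenario("a", "baseline", numeric(0), schema),
    b = scenario("b", "worst-case", worst[1], schema),
    c = scenario("c", "worst-case", worst[2], schema),
    d = scenario("d", "worst-case", worst[3], schema),
    e = scenario("e", "worst-case", worst[4], schema),
    f = scenario("f", "worst-case", worst[5], schema),
    g = scenario("g", "worst-case", worst[6], schema),
    h = scenario("h", "worst-case", worst, schema),
    i = scenario("i", "best-case", best[1], schema),
    j = scenario("j", "best-case", best[2], schema),
    k = scenario("k", "best-case", best[3], schema),
    l = scenario("l", "best-case", best[4], schema),
    m = scenario("m", "best-case", best[5], schema),
    n = scenario("n", "best-case", best[6], schema),
    o = scenario("o", "best-case", best, schema),
    p = scenario("p", "mixed", override(worst, "Tourism pressure"), schema),
    q = scenario("q", "mixed", override(worst, "Water salinity"), schema),
    r = scenario("r", "mixed", override(worst, "Water discharges"), schema)
  )
  sc
}

#' Load scenarios from JSON or YAML
#'
#' The file holds a list of `{code, label, evidence}` entries, `evidence`
#' being a map node -> value.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param schema Schema for range checks.
#' @return Named list of [scenario()] objects.
#' @export
load_scenarios <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(raw, function(e) {
    scenario(e$code, e$label, unlist(e$evidence), schema)
  })
  stats::setNames(out, vapply(out, `[[`, "", "code"))
}

# ---- conditionalization ----------------------------------------------------

#' Conditionalize a fitted network on evidence
#'
#' Evidence values are mapped to z-space through each node's empirical CDF
#' (midrank convention) and the standard-normal quantile; the remaining
#' nodes are drawn from the exact conditional multivariate normal
#' (conditional mean via the cross-covariance and inverse evidence
#' covariance, conditional covariance via the Schur complement) and
#' back-transformed through each node's empirical quantile.
#'
#' @param model A [fit_network()] result.
#' @param evidence Named numeric vector (possibly empty) of data-scale
#'   values; must not include the target node.
#' @param n_samples Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param return_z If `TRUE`, attach the raw z-space draws as attribute
#'   `"z_samples"` (used by diagnostics and tests).
#' @return Data frame of `n_samples` draws of all non-evidence nodes, on the
#'   data scale.
#' @export
conditionalize <- function(model, evidence = numeric(0), n_samples = 1e5,
                           seed = 1L, return_z = FALSE) {
  stopifnot(inherits(model, "fitted_model"), n_samples >= 1)
  evidence <- unlist(evidence)
  nodes <- model$structure$nodes$name
  if (length(evidence)) {
    unknown <- setdiff(names(evidence), nodes)
    if (length(unknown)) stop("evidence on unknown node(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    if (model$structure$target %in% names(evidence)) {
      stop("evidence may not include the target node", call. = FALSE)
    }
  }
  R <- model$copula$R[nodes, nodes]
  ev_nodes <- names(evidence)
  free <- setdiff(nodes, ev_nodes)

  if (!length(ev_nodes)) {
    mu_c <- rep(0, length(free))
    S_c <- R
  } else {
    z_e <- vapply(ev_nodes, function(nm) {
      stats::qnorm(empirical_cdf_u(model$margins[[nm]], evidence[[nm]]))
    }, numeric(1))
    Ree <- R[ev_nodes, ev_nodes, drop = FALSE]
    Rfe <- R[free, ev_nodes, drop = FALSE]
    W <- solve(Ree)
    mu_c <- drop(Rfe %*% W %*% z_e)
    S_c <- R[free, free, drop = FALSE] - Rfe %*% W %*% t(Rfe)
    S_c <- (S_c + t(S_c)) / 2
  }

  d <- length(free)
  # Schur complement can be numerically semi-definite when evidence pins
  # near-deterministic relations; a tiny ridge keeps the factorization valid
  ch <- tryCatch(chol(S_c), error = function(e) chol(S_c + diag(1e-10, d)))
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_samples * d), n_samples, d) %*% ch
  Z <- sweep(Z, 2L, mu_c, "+")
  colnames(Z) <- free

  out <- as.data.frame(lapply(free, function(nm) {
    empirical_quantile(model$margins[[nm]], stats::pnorm(Z[, nm]))
  }), check.names = FALSE)
  names(out) <- free
  if (return_z) attr(out, "z_samples") <- Z
  out
}

# ---- scenario results ------------------------------------------------------

#' Largest-remainder rounding of proportions to integer counts
#'
#' @param p Numeric vector of proportions summing to 1.
#' @param n Total count to distribute.
#' @return Integer vector summing to `n`; ties broken by position.
#' @export
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    frac <- raw - base
    give <- order(-frac, seq_along(p))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Run one scenario
#'
#' Conditionalizes on the scenario's evidence and summarizes the target
#' node's conditional distribution: mean (alpha diversity), standard
#' deviation, a 10-bin histogram of proportions over equal-width intervals
#' of the species range, and rounded per-bin wetland counts.
#'
#' @param model A [fit_network()] result with target "Number of species".
#' @param scen A [scenario()].
#' @param n_samples Monte Carlo draws (default 1e5; mean standard error
#'   about sigma/sqrt(n_samples), i.e. ~0.03 species at sigma = 8).
#' @param seed Integer seed.
#' @param bin_range Closed range split into 10 equal bins; defaults to the
#'   target's schema range `c(2, 32)` so all scenarios share one axis.
#' @return An object of class `scenario_result`.
#' @export
run_scenario <- function(model, scen, n_samples = 1e5, seed = 1L,
                         bin_range = c(2, 32)) {
  stopifnot(inherits(model, "fitted_model"), inherits(scen, "scenario"))
  tgt <- model$structure$target
  draws <- conditionalize(model, scen$evidence, n_samples, seed)[[tgt]]
  breaks <- seq(bin_range[1], bin_range[2], length.out = 11L)
  # half-open bins [b_k, b_{k+1}), last bin closed
  bin <- findInterval(draws, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  hist <- tabulate(bin, nbins = 10L) / length(draws)
  n_wet <- model$n
  structure(
    list(code = scen$code, label = scen$label, evidence = scen$evidence,
         mu = mean(draws), sigma = stats::sd(draws),
         histogram = hist, wetland_counts = largest_remainder(hist, n_wet),
         bin_breaks = breaks, n_samples = n_samples, seed = seed,
         n_wetlands = n_wet),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s> mu = %.2f, sigma = %.2f (%d draws)\n",
              x$code, x$mu, x$sigma, x$n_samples))
  invisible(x)
}

#' Run every scenario of a catalog
#'
#' @inheritParams run_scenario
#' @param catalog Named list of scenarios (default [scenario_catalog()]).
#' @param seed Base seed; scenario k uses `seed + k - 1` so results are
#'   independent across scenarios yet fully reproducible.
#' @return Named list of [run_scenario()] results.
#' @export
run_catalog <- function(model, catalog = scenario_catalog(),
                        n_samples = 1e5, seed = 1L, bin_range = c(2, 32)) {
  out <- vector("list", length(catalog))
  for (k in seq_along(catalog)) {
    out[[k]] <- run_scenario(model, catalog[[k]], n_samples,
                             seed + k - 1L, bin_range)
  }
  stats::setNames(out, names(catalog))
}

#' Change in alpha diversity relative to baseline
#'
#' @param result,baseline Two [run_scenario()] results computed on the same
#'   model and binning.
#' @return Signed difference `result$mu - baseline$mu` (species).
#' @export
delta_vs_baseline <- function(result, baseline) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(baseline, "scenario_result"))
  if (!isTRUE(all.equal(result$bin_breaks, baseline$bin_breaks))) {
    stop("mismatched bin ranges", call. = FALSE)
  }
  result$mu - baseline$mu
}

#' Tabulate scenario results
#'
#' @param results Named list of [run_scenario()] results.
#' @return Data frame: code, label, mu, sigma, delta vs the first (baseline)
#'   row, 10 bin-proportion columns and 10 wetland-count columns.
#' @export
scenario_result_table <- function(results) {
  base_mu <- results[[1]]$mu
  rows <- lapply(results, function(r) {
    h <- stats::setNames(as.list(r$histogram), paste0("bin", 1:10))
    cnt <- stats::setNames(as.list(r$wetland_counts), paste0("count", 1:10))
    c(list(code = r$code, label = r$label, mu = r$mu, sigma = r$sigma,
           delta = r$mu - base_mu), h, cnt,
      list(n_samples = r$n_samples, seed = r$seed))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
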