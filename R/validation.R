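#' Determinant of a dependence structure from its arc correlations
#'
#' `D = prod(1 - rho^2)` over the supplied (partial) correlations. `D` lies
#' in `[0, 1]`: it is 1 when all variables are independent and approaches 0
#' under multivariate linear dependence. For a complete partial-correlation
#' specification along one ordering, `D` equals the determinant of the
#' implied correlation matrix exactly (the standard determinant
#' factorization).
#'
#' @param arc_partials Numeric vector of correlations, all `|rho| < 1`.
#' @return `D` in `[0, 1]`.
#' @export
determinant_product <- function(arc_partials) {
  rho <- as.numeric(arc_partials)
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  prod(1 - rho^2)
}

#' Validate the normal-copula assumption of a fitted model
#'
#' Compares the determinant of the data's empirical rank (Spearman)
#' correlation matrix, `D_ER`, with the sampling distribution of the
#' determinant of the empirical normal rank correlation matrix, `D_NR`,
#' computed on datasets of the same size simulated from the fitted copula.
#' The copula assumption is not rejected when `D_ER` falls inside the
#' equal-tailed confidence band of the simulated `D_NR` at the stated
#' level (90% band, i.e. a 10% significance level, by default).
#'
#' @param model A [fit_network()] result.
#' @param table The [wetland_table()] the model was fitted on.
#' @param n_sims Number of simulated datasets (default 1e4; minimum 100,
#'   below which the band quantiles are unstable).
#' @param band_level Two-sided band coverage (default 0.90).
#' @param seed Integer seed.
#' @param d_er_from `"spearman"` (default) computes `D_ER` from the
#'   Spearman matrix of the raw data; `"normal_scores"` uses the
#'   normal-scores matrix instead. The two conventions differ only in the
#'   third decimal for ordinal data; both are provided because the naming
#'   of the empirical matrix is ambiguous in parts of the literature.
#' @return An object of class `validation_report`: `d_er`, `d_nr_samples`,
#'   `band` (lower/upper), `quantile_position` (fraction of simulated
#'   determinants below `d_er`), `passed`, `n_sims`, `seed`.
#' @export
validate_model <- function(model, table, n_sims = 1e4, band_level = 0.90,
                           seed = 1L,
                           d_er_from = c("spearman", "normal_scores")) {
  stopifnot(inherits(model, "fitted_model"))
  d_er_from <- match.arg(d_er_from)
  if (n_sims < 100) stop("n_sims must be >= 100 (band unstable below)",
                         call. = FALSE)
  df <- as.data.frame(table, check.names = FALSE)[model$structure$nodes$name]
  n <- nrow(df)

  ER <- if (d_er_from == "spearman") {
    empirical_rank_corr_matrix(df)
  } else {
    normal_rank_corr_matrix(df, repair = FALSE)
  }
  if (!is_positive_definite(ER)) {
    message("empirical rank matrix was indefinite; applying PD repair")
    ER <- nearest_pd(ER)
  }
  d_er <- det(ER)

  nodes <- model$structure$nodes$name
  U <- chol(model$copula$R[nodes, nodes])
  d <- length(nodes)
  margins <- model$margins[nodes]
  set.seed(as.integer(seed))
  d_nr <- vapply(seq_len(n_sims), function(s) {
    z <- matrix(stats::rnorm(n * d), n, d) %*% U
    u <- stats::pnorm(z)
    # back-transform through the fitted margins so simulated data carry the
    # same ordinal ties as the real table, then take normal scores
    x <- vapply(seq_len(d), function(j) {
      empirical_quantile(margins[[j]], u[, j])
    }, numeric(n))
    zs <- apply(x, 2L, normal_scores)
    C <- suppressWarnings(stats::cor(zs))
    # a simulated ordinal column can occasionally collapse onto one level;
    # treat such a degenerate column as independent of the rest
    C[is.na(C)] <- 0
    diag(C) <- 1
    det(C)
  }, numeric(1))
  d_nr <- pmin(pmax(d_nr, 0), 1)

  alpha <- (1 - band_level) / 2
  band <- stats::quantile(d_nr, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(d_er = d_er, d_nr_samples = d_nr,
         band = c(lower = band[1], upper = band[2]),
         quantile_position = mean(d_nr < d_er),
         passed = d_er >= band[1] && d_er <= band[2],
         band_level = band_level, n_sims = n_sims, n = n, seed = seed,
         d_er_from = d_er_from),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> D_ER = %.4f; %.0f%% band of D_NR = [%.4f, %.4f]\n",
    x$d_er, 100 * x$band_level, x$band["lower"], x$band["upper"]))
  cat(sprintf("  quantile position %.3f; normal-copula assumption %s\n",
              x$quantile_position,
              if (x$passed) "not rejected" else "REJECTED"))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A [validate_model()] result.
#' @param path Output path.
#' @param keep_samples If `FALSE` (default) the simulated determinants are
#'   summarized by deciles rather than stored in full.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path, keep_samples = FALSE) {
  stopifnot(inherits(report, "validation_report"))
  out <- report
  class(out) <- NULL
  if (!keep_samples) {
    out$d_nr_deciles <- unname(stats::quantile(out$d_nr_samples,
                                               seq(0, 1, 0.1)))
    out$d_nr_samples <- NULL
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
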