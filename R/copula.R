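#' Midranks of a numeric vector
#'
#' Average ranks; ties receive the mean of the ranks they span, so the rank
#' sum n(n+1)/2 is preserved.
#'
#' @param x Numeric vector.
#' @return Numeric vector of midranks.
#' @export
midranks <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Computed as the product-moment correlation of midranks, which for
#' tie-free data reduces to the classical 1 - 6*sum(d_i^2)/(n^3 - n) with
#' d_i the per-observation rank difference. Midranks are the standard tie
#' correction and matter here because most wetland traits are ordinal.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  for (v in list(x, y)) {
    if (length(unique(v)) < 2L) {
      stop("undefined correlation: constant vector", call. = FALSE)
    }
  }
  stats::cor(midranks(x), midranks(y))
}

#' Normal-scores transform
#'
#' Maps observations to z-space via the standard-normal quantile of the
#' midrank plotting position r/(n+1). The transform depends on the data only
#' through ranks, so it is invariant under strictly increasing maps of `x`.
#'
#' @param x Numeric vector.
#' @return Numeric z vector, same length as `x`.
#' @export
normal_scores <- function(x) {
  n <- length(x)
  if (n < 1L) stop("need n >= 1", call. = FALSE)
  stats::qnorm(midranks(x) / (n + 1))
}

#' Empirical rank (Spearman) correlation matrix
#'
#' @param table A [wetland_table()] or numeric data frame/matrix.
#' @return Symmetric matrix of pairwise Spearman correlations with unit
#'   diagonal, dimnames set to column names.
#' @export
empirical_rank_corr_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table, check.names = FALSE))
  storage.mode(m) <- "double"
  p <- ncol(m)
  if (p < 1L) stop("need at least one variable", call. = FALSE)
  const <- apply(m, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stop("undefined correlation: constant variable(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(apply(m, 2L, midranks))
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  dimnames(R) <- list(colnames(m), colnames(m))
  diag(R) <- 1
  R
}

#' Empirical normal rank correlation matrix
#'
#' Product-moment correlation of per-column normal scores — the z-space
#' dependence structure induced by the data under a normal copula. The
#' result is repaired to positive definiteness when small-sample rank
#' matrices come out indefinite (repair is reported via a message).
#'
#' @inheritParams empirical_rank_corr_matrix
#' @param repair If `TRUE` (default), apply [nearest_pd()] when needed.
#' @return Symmetric positive-definite correlation matrix.
#' @export
normal_rank_corr_matrix <- function(table, repair = TRUE) {
  m <- as.matrix(as.data.frame(table, check.names = FALSE))
  storage.mode(m) <- "double"
  const <- apply(m, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    stop("undefined correlation: constant variable(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(apply(m, 2L, normal_scores))
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  dimnames(R) <- list(colnames(m), colnames(m))
  diag(R) <- 1
  if (repair && !is_positive_definite(R)) {
    message("normal rank correlation matrix was indefinite; applying PD repair")
    R <- nearest_pd(R)
  }
  R
}

#' Test positive definiteness of a symmetric matrix
#'
#' @param R Symmetric matrix.
#' @param tol Minimum eigenvalue required (default 1e-8).
#' @return Logical scalar.
#' @export
is_positive_definite <- function(R, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= tol
}

#' Nearest positive-definite correlation matrix
#'
#' Repairs an indefinite correlation matrix by clipping eigenvalues at a
#' floor and renormalizing to unit diagonal, iterating until the minimum
#' eigenvalue reaches the floor. Inputs that are already positive definite
#' are returned unchanged, which makes the operation idempotent.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Eigenvalue floor (default 1e-8).
#' @return A positive-definite correlation matrix with the same dimnames.
#' @export
nearest_pd <- function(R, tol = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-10)) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-10)) {
    stop("matrix must have unit diagonal", call. = FALSE)
  }
  if (is_positive_definite(R, tol)) return(R)
  dn <- dimnames(R)
  X <- unname(R)
  for (it in 1:200) {
    e <- eigen(X, symmetric = TRUE)
    vals <- pmax(e$values, tol)
    X <- e$vectors %*% (vals * t(e$vectors))
    X <- stats::cov2cor(X)
    X <- (X + t(X)) / 2
    if (is_positive_definite(X, tol)) break
  }
  diag(X) <- 1
  dimnames(X) <- dn
  X
}

#' Gaussian copula model
#'
#' A correlation matrix in z-space together with node names. Samples from
#' the copula are uniform margins coupled by the multivariate normal with
#' correlation `R` through the probit transform pair (standard-normal CDF
#' and its inverse).
#'
#' @param R Symmetric positive-definite correlation matrix.
#' @param node_names Optional character vector of node labels (defaults to
#'   the dimnames of `R`).
#' @return An object of class `gaussian_copula`.
#' @export
gaussian_copula <- function(R, node_names = NULL) {
  R <- as.matrix(R)
  if (is.null(node_names)) node_names <- colnames(R)
  if (is.null(node_names)) node_names <- paste0("V", seq_len(ncol(R)))
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    stop("R must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-8)) {
    stop("R must have unit diagonal", call. = FALSE)
  }
  if (any(abs(R) > 1 + 1e-12)) stop("|R[i,j]| must be <= 1", call. = FALSE)
  dimnames(R) <- list(node_names, node_names)
  structure(list(R = R, node_names = node_names), class = "gaussian_copula")
}

#' @export
print.gaussian_copula <- function(x, ...) {
  cat(sprintf("<gaussian_copula> %d nodes\n", length(x$node_names)))
  print(round(x$R, 3))
  invisible(x)
}

#' Sample uniform margins from a Gaussian copula
#'
#' Draws i.i.d. standard-normal rows, correlates them by the Cholesky factor
#' of `R`, and maps to uniforms through the standard-normal CDF. Each column
#' is marginally uniform on (0, 1); the pairwise Spearman correlation of the
#' output converges to `6/pi * asin(rho/2)` for z-space correlation `rho`.
#'
#' @param model A [gaussian_copula()] (or a bare correlation matrix).
#' @param n_samples Number of rows to draw.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return `n_samples` x d matrix of uniforms with node-name columns.
#' @export
sample_gaussian_copula <- function(model, n_samples, seed) {
  if (!inherits(model, "gaussian_copula")) model <- gaussian_copula(model)
  if (!is_positive_definite(model$R, tol = 1e-12)) {
    stop("R is not positive definite; repair with nearest_pd() first",
         call. = FALSE)
  }
  stopifnot(n_samples >= 1)
  d <- ncol(model$R)
  U <- chol(model$R)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_samples * d), nrow = n_samples, ncol = d)
  u <- stats::pnorm(Z %*% U)
  colnames(u) <- model$node_names
  u
}

# ---- empirical margins -----------------------------------------------------

#' Empirical margin of one variable
#'
#' Stores the order statistics of an observed column together with midrank
#' plotting positions r/(n+1). The margin supplies both directions of the
#' probability integral transform: data value -> uniform (CDF, midrank
#' convention) and uniform -> data value (quantile, piecewise linear).
#'
#' @param x Numeric vector of observations (n >= 2).
#' @return An object of class `empirical_margin`.
#' @export
empirical_margin <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("margin needs >= 2 observations", call. = FALSE)
  if (anyNA(x)) stop("margin cannot contain missing values", call. = FALSE)
  n <- length(x)
  sorted <- sort(x)
  structure(
    list(sorted_values = sorted, plotting_positions = seq_len(n) / (n + 1),
         n = n),
    class = "empirical_margin"
  )
}

#' Empirical quantile (inverse CDF) of a margin
#'
#' Piecewise-linear interpolation of the order statistics at their plotting
#' positions; `u` outside the plotting grid is clamped to the observed
#' minimum/maximum, so back-transformed samples never leave the data range.
#'
#' @param margin An [empirical_margin()].
#' @param u Numeric vector of probabilities strictly inside (0, 1).
#' @return Data-scale values, same length as `u`.
#' @export
empirical_quantile <- function(margin, u) {
  stopifnot(inherits(margin, "empirical_margin"))
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)",
                                 call. = FALSE)
  stats::approx(x = margin$plotting_positions, y = margin$sorted_values,
                xout = u, rule = 2, ties = "ordered")$y
}

#' Empirical CDF value (midrank convention) of a margin
#'
#' For an observed value, returns midrank/(n+1) computed against the stored
#' sample. Unobserved values interior to the data range are linearly
#' interpolated between the neighbouring observed levels; values beyond the
#' range map to half-rank positions 0.5/(n+1) and (n+0.5)/(n+1).
#'
#' @param margin An [empirical_margin()].
#' @param value Numeric vector of data-scale values.
#' @return Uniform-scale values in (0, 1).
#' @export
empirical_cdf_u <- function(margin, value) {
  stopifnot(inherits(margin, "empirical_margin"))
  s <- margin$sorted_values
  n <- margin$n
  lev <- unique(s)
  u_lev <- vapply(lev, function(v) {
    (sum(s < v) + (sum(s == v) + 1) / 2) / (n + 1)
  }, numeric(1))
  vapply(as.numeric(value), function(v) {
    if (v < lev[1]) return(0.5 / (n + 1))
    if (v > lev[length(lev)]) return((n + 0.5) / (n + 1))
    hit <- which(lev == v)
    if (length(hit)) return(u_lev[hit])
    stats::approx(lev, u_lev, xout = v, ties = "ordered")$y
  }, numeric(1))
}
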