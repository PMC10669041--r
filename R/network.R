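#' Network structure (directed acyclic graph)
#'
#' Nodes carry a role (`spatial`, `anthropic`, `hydrological` or `target`);
#' arcs carry an expected sign used only for diagnostics. Exactly one target
#' node is required and it may not have outgoing arcs. A topological ordering
#' is computed at construction (ties broken by the given node order, so the
#' canonical trait-table order is deterministic).
#'
#' @param nodes Data frame with columns `name`, `role`.
#' @param arcs Data frame with columns `from`, `to` and optionally `sign`
#'   (`"+"`, `"-"` or `"unconstrained"`).
#' @return An object of class `network_structure` with fields `nodes`,
#'   `arcs`, `ordering`.
#' @export
network_structure <- function(nodes, arcs) {
  nodes <- as.data.frame(nodes, check.names = FALSE)
  arcs <- as.data.frame(arcs, check.names = FALSE)
  stopifnot(all(c("name", "role") %in% names(nodes)),
            all(c("from", "to") %in% names(arcs)) || nrow(arcs) == 0L)
  nodes$name <- as.character(nodes$name)
  nodes$role <- as.character(nodes$role)
  if (anyDuplicated(nodes$name)) stop("duplicate node names", call. = FALSE)
  ok_roles <- c("spatial", "anthropic", "hydrological", "target")
  bad <- setdiff(nodes$role, ok_roles)
  if (length(bad)) stop("invalid node role(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tgt <- nodes$name[nodes$role == "target"]
  if (length(tgt) != 1L) {
    stop("exactly one target node required (got ", length(tgt), ")",
         call. = FALSE)
  }
  if (nrow(arcs)) {
    if (!"sign" %in% names(arcs)) arcs$sign <- "unconstrained"
    arcs$sign[is.na(arcs$sign) | arcs$sign == ""] <- "unconstrained"
    bad_sign <- setdiff(arcs$sign, c("+", "-", "unconstrained"))
    if (length(bad_sign)) stop("invalid arc sign(s): ",
                               paste(bad_sign, collapse = ", "),
                               call. = FALSE)
    unknown <- setdiff(c(arcs$from, arcs$to), nodes$name)
    if (length(unknown)) {
      stop("unknown node in arc: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(arcs$from == tgt)) {
      stop("target node may not have outgoing arcs", call. = FALSE)
    }
    if (any(arcs$from == arcs$to)) stop("self-loop arc", call. = FALSE)
    if (anyDuplicated(arcs[c("from", "to")])) {
      stop("duplicate arc", call. = FALSE)
    }
  } else {
    arcs <- data.frame(from = character(), to = character(),
                       sign = character())
  }
  ordering <- topological_order(nodes$name, arcs)
  structure(list(nodes = nodes, arcs = arcs, ordering = ordering,
                 target = tgt),
            class = "network_structure")
}

# Kahn's algorithm; among ready nodes, the one earliest in `names` is
# emitted first, so the input node order breaks ties deterministically.
topological_order <- function(names, arcs) {
  indeg <- stats::setNames(integer(length(names)), names)
  for (to in arcs$to) indeg[[to]] <- indeg[[to]] + 1L
  remaining <- names
  out <- character(0)
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) {
      stop("cycle detected involving: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    }
    v <- ready[1]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    for (k in arcs$to[arcs$from == v]) indeg[[k]] <- indeg[[k]] - 1L
  }
  out
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("<network_structure> %d nodes, %d arcs; target: %s\n",
              nrow(x$nodes), nrow(x$arcs), x$target))
  invisible(x)
}

#' Default network structure
#'
#' The shipped reconstruction of the conceptual model: every spatial,
#' anthropic and hydrological trait is a parent of the target node (number
#' of species), with the hypothesized effect signs — negative for tourism
#' pressure, anthropization, water discharges, water salinity, mean water
#' level and isolation; positive for water diversions and wetland size.
#' Inter-driver arcs are deliberately not included by default because the
#' exact set is expert knowledge; supply them via [load_structure()].
#'
#' @return A [network_structure()] with 10 nodes and 9 arcs.
#' @export
default_structure <- function() {
  sch <- default_schema()
  roles <- c("Wetland size" = "spatial", "Isolation" = "spatial",
             "Distance to the coastline" = "spatial",
             "Mean water level" = "hydrological",
             "Water salinity" = "hydrological",
             "Water diversions" = "hydrological",
             "Water discharges" = "hydrological",
             "Tourism pressure" = "anthropic",
             "Anthropization" = "anthropic",
             "Number of species" = "target")
  nodes <- data.frame(name = names(sch), role = unname(roles[names(sch)]))
  signs <- c("Wetland size" = "+", "Isolation" = "-",
             "Distance to the coastline" = "unconstrained",
             "Mean water level" = "-", "Water salinity" = "-",
             "Water diversions" = "+", "Water discharges" = "-",
             "Tourism pressure" = "-", "Anthropization" = "-")
  arcs <- data.frame(from = names(signs), to = target_node(),
                     sign = unname(signs))
  network_structure(nodes, arcs)
}

#' Load a network structure from JSON or YAML
#'
#' The file holds `nodes: [{name, role}]` and `arcs: [{from, to, sign}]`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [network_structure()].
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  to_df <- function(x, cols) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(row) {
      as.data.frame(row[intersect(names(row), cols)], check.names = FALSE)
    }))
  }
  nodes <- to_df(spec$nodes, c("name", "role"))
  arcs <- if (is.null(spec$arcs) || length(spec$arcs) == 0L) {
    data.frame(from = character(), to = character(), sign = character())
  } else {
    to_df(spec$arcs, c("from", "to", "sign"))
  }
  network_structure(nodes, arcs)
}

#' Write a network structure to JSON
#' @param structure A [network_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "network_structure"))
  jsonlite::write_json(list(nodes = structure$nodes, arcs = structure$arcs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- partial correlations --------------------------------------------------

#' Partial correlation from a correlation matrix
#'
#' Correlation between `i` and `j` with the linear effect of the `given`
#' set removed, via the precision matrix of the submatrix on
#' `{i, j} union given`. With an empty conditioning set this is the raw
#' correlation `R[i, j]`.
#'
#' @param R Correlation matrix with dimnames.
#' @param i,j Node names or indices.
#' @param given Character/integer vector of conditioning nodes (may be
#'   empty).
#' @return Partial correlation in `(-1, 1)`.
#' @export
partial_correlation <- function(R, i, j, given = character(0)) {
  nm <- colnames(R)
  as_idx <- function(k) if (is.character(k)) match(k, nm) else as.integer(k)
  ii <- as_idx(i); jj <- as_idx(j); gg <- vapply(given, as_idx, 0L)
  if (anyNA(c(ii, jj, gg))) stop("unknown node name", call. = FALSE)
  if (ii %in% gg || jj %in% gg) {
    stop("conditioning set must exclude i and j", call. = FALSE)
  }
  if (!length(gg)) return(R[ii, jj])
  idx <- c(ii, jj, gg)
  sub <- R[idx, idx, drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e) {
    stop("singular submatrix in partial correlation", call. = FALSE)
  })
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Conditioning set assigned to an arc: the destination's parents that come
# earlier than the source in the topological parent ordering.
arc_conditioning_sets <- function(structure) {
  ord <- structure$ordering
  out <- vector("list", nrow(structure$arcs))
  for (a in seq_len(nrow(structure$arcs))) {
    to <- structure$arcs$to[a]
    from <- structure$arcs$from[a]
    parents <- structure$arcs$from[structure$arcs$to == to]
    parents <- parents[order(match(parents, ord))]
    k <- match(from, parents)
    out[[a]] <- if (k > 1L) parents[seq_len(k - 1L)] else character(0)
  }
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit a non-parametric Bayesian network to a wetland table
#'
#' Calibration has two parts: each node's margin is its empirical
#' distribution, and the z-space dependence is a correlation matrix over
#' normal scores. In `"saturated"` mode the matrix is the (PD-repaired)
#' normal rank correlation matrix of the data. In `"bn_constrained"` mode
#' (the default) each node's dependence on its predecessors is restricted to
#' its parents: in topological order, the node's normal scores are projected
#' (least squares) onto its parents' scores, and the partial correlation
#' with every non-parent predecessor given the parents is zero. The partial
#' correlation assigned to each arc is then extracted from the constrained
#' matrix, conditioning on the destination's earlier-ordered parents.
#'
#' @param table A [wetland_table()] (or numeric data frame) whose columns
#'   cover the structure's nodes.
#' @param structure A [network_structure()]; defaults to
#'   [default_structure()].
#' @param mode `"bn_constrained"` or `"saturated"`.
#' @return An object of class `fitted_model` with fields `structure`,
#'   `margins`, `copula` (a [gaussian_copula()] holding the implied z-space
#'   matrix), `arc_partials` (named per `"from -> to"`), `fit_mode`, `n`.
#' @export
fit_network <- function(table, structure = default_structure(),
                        mode = c("bn_constrained", "saturated")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table, check.names = FALSE)
  missing_cols <- setdiff(structure$nodes$name, names(df))
  if (length(missing_cols)) {
    stop("table lacks node column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[structure$nodes$name]
  if (nrow(df) < 5L) stop("need at least 5 rows to fit", call. = FALSE)
  const <- vapply(df, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) {
    stop("degenerate (constant) node column(s): ",
         paste(names(df)[const], collapse = ", "), call. = FALSE)
  }

  margins <- lapply(df, empirical_margin)
  S <- normal_rank_corr_matrix(df)  # saturated z-space matrix, PD-repaired

  R <- if (mode == "saturated") S else constrain_to_dag(S, structure)
  copula <- gaussian_copula(R)

  model <- structure(
    list(structure = structure, margins = margins, copula = copula,
         arc_partials = numeric(0), fit_mode = mode, n = nrow(df)),
    class = "fitted_model")
  model$arc_partials <- extract_arc_partials(model)
  model
}

# Impose the DAG factorization on a saturated z-space matrix: process nodes
# in topological order; a node's joint with its predecessors is determined
# by the least-squares projection onto its parents (coefficients taken from
# the saturated matrix), which zeroes the partial correlation with every
# non-parent predecessor given the parents.
constrain_to_dag <- function(S, structure) {
  ord <- structure$ordering
  p <- length(ord)
  R <- diag(p)
  dimnames(R) <- list(ord, ord)
  for (k in seq_len(p)[-1]) {
    node <- ord[k]
    pred <- ord[seq_len(k - 1L)]
    parents <- structure$arcs$from[structure$arcs$to == node]
    parents <- parents[order(match(parents, ord))]
    if (!length(parents)) next
    b <- solve(S[parents, parents, drop = FALSE],
               S[parents, node, drop = FALSE])
    # keep the implied variance of the projection below 1 under the
    # constrained joint (can exceed it when parent dependence differs
    # between S and R); shrink uniformly if needed
    v <- drop(t(b) %*% R[parents, parents, drop = FALSE] %*% b)
    if (v >= 1 - 1e-8) b <- b * sqrt((1 - 1e-6) / v)
    R[node, pred] <- drop(t(b) %*% R[parents, pred, drop = FALSE])
    R[pred, node] <- R[node, pred]
  }
  R[colnames(S), colnames(S), drop = FALSE]
}

extract_arc_partials <- function(model) {
  st <- model$structure
  if (!nrow(st$arcs)) return(numeric(0))
  R <- model$copula$R
  cond <- arc_conditioning_sets(st)
  vals <- vapply(seq_len(nrow(st$arcs)), function(a) {
    partial_correlation(R, st$arcs$from[a], st$arcs$to[a], cond[[a]])
  }, numeric(1))
  stats::setNames(vals, paste(st$arcs$from, "->", st$arcs$to))
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %d nodes, %d arcs, mode = %s, n = %d\n",
              nrow(x$structure$nodes), nrow(x$structure$arcs), x$fit_mode,
              x$n))
  if (length(x$arc_partials)) {
    print(round(x$arc_partials, 3))
  }
  invisible(x)
}

#' Arc table of a fitted model
#'
#' @param model A [fit_network()] result.
#' @return Data frame with columns `from`, `to`, `sign`, `partial`.
#' @export
arc_partial_table <- function(model) {
  stopifnot(inherits(model, "fitted_model"))
  st <- model$structure
  data.frame(from = st$arcs$from, to = st$arcs$to, sign = st$arcs$sign,
             partial = unname(model$arc_partials))
}

#' Implied z-space correlation matrix of a fitted model
#'
#' In saturated mode this is the fitted matrix itself. In constrained mode
#' the matrix is reconstructed from the arc partial correlations alone by
#' inverting the partial-correlation recursion along the topological
#' ordering — a round trip that must reproduce the stored matrix, which is
#' used as an internal consistency check.
#'
#' @param model A [fit_network()] result.
#' @return Positive-definite correlation matrix over all nodes.
#' @export
implied_correlation_matrix <- function(model) {
  stopifnot(inherits(model, "fitted_model"))
  if (model$fit_mode == "saturated") return(model$copula$R)
  reconstruct_from_partials(model$structure, model$arc_partials)
}

# Rebuild the joint correlation matrix from arc partials: for each node in
# topological order, peel the conditioning set of each arc partial one
# variable at a time with the recursive partial-correlation identity
#   rho(i,j | C) = (rho(i,j | C\w) - rho(i,w | C\w) rho(j,w | C\w)) /
#                  sqrt((1 - rho(i,w|C\w)^2)(1 - rho(j,w|C\w)^2))
# solved for rho(i,j | C\w); non-parent predecessors then get the
# correlation implied by zero partials given the parents (projection).
reconstruct_from_partials <- function(structure, arc_partials) {
  ord <- structure$ordering
  p <- length(ord)
  R <- diag(p)
  dimnames(R) <- list(ord, ord)
  for (k in seq_len(p)[-1]) {
    node <- ord[k]
    pred <- ord[seq_len(k - 1L)]
    parents <- structure$arcs$from[structure$arcs$to == node]
    parents <- parents[order(match(parents, ord))]
    for (m in seq_along(parents)) {
      pa <- parents[m]
      cond <- if (m > 1L) parents[seq_len(m - 1L)] else character(0)
      val <- arc_partials[[paste(pa, "->", node)]]
      while (length(cond)) {
        w <- cond[length(cond)]
        cond <- cond[-length(cond)]
        a <- partial_correlation(R, node, w, cond)
        b <- partial_correlation(R, pa, w, cond)
        val <- val * sqrt((1 - a^2) * (1 - b^2)) + a * b
      }
      R[node, pa] <- R[pa, node] <- val
    }
    if (length(parents)) {
      others <- setdiff(pred, parents)
      if (length(others)) {
        bb <- solve(R[parents, parents, drop = FALSE],
                    R[parents, node, drop = FALSE])
        R[node, others] <- drop(t(bb) %*% R[parents, others, drop = FALSE])
        R[others, node] <- R[node, others]
      }
    }
  }
  R[structure$nodes$name, structure$nodes$name, drop = FALSE]
}

#' Sample a data-scale table from a fitted model
#'
#' Draws copula uniforms from the model's z-space matrix and back-transforms
#' them through the fitted empirical margins, producing a dataset with the
#' same margins and dependence the model encodes — the resampling step the
#' determinant validation relies on.
#'
#' @param model A [fit_network()] result.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return Data frame with one column per node.
#' @export
sample_from_model <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "fitted_model"))
  u <- sample_gaussian_copula(model$copula, n, seed)
  out <- as.data.frame(lapply(colnames(u), function(nm) {
    empirical_quantile(model$margins[[nm]], u[, nm])
  }), check.names = FALSE)
  names(out) <- colnames(u)
  out
}
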