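# Shared fixtures, all built in code.

# random correlation matrix via a Wishart-style construction
rand_corr <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * (d + 2)), d + 2, d)
  R <- stats::cov2cor(crossprod(A))
  dimnames(R) <- list(paste0("v", seq_len(d)), paste0("v", seq_len(d)))
  R
}

# DAG in which every node is a parent of every later node (no constraint)
saturated_structure <- function(node_names) {
  d <- length(node_names)
  nodes <- data.frame(name = node_names,
                      role = c(rep("anthropic", d - 1), "target"))
  arcs <- do.call(rbind, lapply(2:d, function(j) {
    data.frame(from = node_names[seq_len(j - 1)], to = node_names[j])
  }))
  network_structure(nodes, arcs)
}

chain_structure <- function(node_names = c("a", "b", "c")) {
  d <- length(node_names)
  nodes <- data.frame(name = node_names,
                      role = c(rep("hydrological", d - 1), "target"))
  arcs <- data.frame(from = node_names[-d], to = node_names[-1])
  network_structure(nodes, arcs)
}

# fitted model with an exact z-space matrix and near-standard-normal
# margins (data scale ~ z scale), for closed-form conditioning checks
make_model <- function(R, n_margin = 400L, structure = NULL) {
  nodes <- colnames(R)
  d <- length(nodes)
  if (is.null(structure)) {
    st_nodes <- data.frame(name = nodes,
                           role = c(rep("anthropic", d - 1), "target"))
    st_arcs <- data.frame(from = nodes[-d], to = nodes[d])
    structure <- network_structure(st_nodes, st_arcs)
  }
  grid <- stats::qnorm(seq_len(n_margin) / (n_margin + 1))
  margins <- stats::setNames(
    lapply(nodes, function(nm) empirical_margin(grid)), nodes)
  m <- structure(
    list(structure = structure, margins = margins,
         copula = gaussian_copula(R), arc_partials = numeric(0),
         fit_mode = "saturated", n = n_margin),
    class = "fitted_model")
  m$arc_partials <- wetlandbn:::extract_arc_partials(m)
  m
}

# small valid trait data frame for loader tests
small_table_df <- function(seed = 42, n = 22) {
  as.data.frame(generate_wetlands(default_synthetic_spec(),
                                  n_wetlands = n, seed = seed),
                check.names = FALSE)
}
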