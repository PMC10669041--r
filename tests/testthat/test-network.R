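test_that("structure validation catches cycles, unknown nodes, bad targets", {
  nodes <- data.frame(name = c("salinity", "species"),
                      role = c("hydrological", "target"))
  expect_error(network_structure(
    nodes, data.frame(from = c("species", "salinity"),
                      to = c("salinity", "species"))),
    "target node may not have outgoing arcs")
  nodes3 <- data.frame(name = c("a", "b", "c"),
                       role = c("anthropic", "anthropic", "target"))
  expect_error(network_structure(
    nodes3, data.frame(from = c("a", "b"), to = c("b", "a"))), "cycle")
  expect_error(network_structure(
    nodes, data.frame(from = "Water colour", to = "species")),
    "unknown node")
  expect_error(network_structure(
    data.frame(name = c("a", "b"), role = c("target", "target")),
    data.frame(from = "a", to = "b")[0, ]), "exactly one target")
  expect_error(network_structure(
    data.frame(name = "a", role = "wrong"), data.frame()[0, ]),
    "invalid node role")
})

test_that("the default structure has ten nodes and one target", {
  st <- default_structure()
  expect_equal(nrow(st$nodes), 10L)
  expect_identical(st$target, "Number of species")
  expect_equal(sum(st$nodes$role == "target"), 1L)
  expect_true(all(st$arcs$to == "Number of species"))
  # topological ordering puts every parent before the target
  expect_equal(st$ordering[10], "Number of species")
})

test_that("structures round-trip through JSON and YAML files", {
  st <- default_structure()
  jpath <- withr::local_tempfile(fileext = ".json")
  write_structure(st, jpath)
  back <- load_structure(jpath)
  expect_equal(back$nodes, st$nodes)
  expect_equal(back$arcs, st$arcs)
  expect_equal(back$ordering, st$ordering)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    nodes = lapply(seq_len(nrow(st$nodes)), function(i)
      as.list(st$nodes[i, ])),
    arcs = lapply(seq_len(nrow(st$arcs)), function(i)
      as.list(st$arcs[i, ]))), ypath)
  expect_equal(load_structure(ypath)$ordering, st$ordering)

  expect_error(load_structure("missing.yaml"), "not found")
})

test_that("partial_correlation agrees with the residual-regression oracle", {
  R <- rand_corr(5, seed = 21)
  # empty conditioning set: the raw correlation
  expect_equal(partial_correlation(R, "v1", "v2"), R["v1", "v2"])
  # conditional-independence construction: rho_ij = rho_ik * rho_jk
  Rci <- diag(3)
  Rci[1, 3] <- Rci[3, 1] <- 0.6
  Rci[2, 3] <- Rci[3, 2] <- 0.5
  Rci[1, 2] <- Rci[2, 1] <- 0.3
  dimnames(Rci) <- list(c("i", "j", "k"), c("i", "j", "k"))
  expect_equal(partial_correlation(Rci, "i", "j", "k"), 0, tolerance = 1e-12)
  # oracle: correlation of residuals after projecting out `given` in z-space
  for (seed in 22:25) {
    Rr <- rand_corr(5, seed = seed)
    set.seed(seed)
    Z <- matrix(rnorm(4e4 * 5), 4e4, 5) %*% chol(Rr)
    colnames(Z) <- colnames(Rr)
    giv <- c("v3", "v4")
    r1 <- stats::residuals(stats::lm(Z[, "v1"] ~ Z[, giv]))
    r2 <- stats::residuals(stats::lm(Z[, "v2"] ~ Z[, giv]))
    expect_lt(abs(partial_correlation(Rr, "v1", "v2", giv) -
                    stats::cor(r1, r2)), 0.03)
  }
  expect_error(partial_correlation(R, "v1", "v2", c("v1", "v3")),
               "exclude")
})

test_that("saturated fit on two nodes equals the normal rank matrix", {
  set.seed(30)
  df <- data.frame(a = rnorm(200), b = rnorm(200))
  df$b <- df$b + df$a
  st <- chain_structure(c("a", "b"))
  m <- fit_network(df, st, mode = "saturated")
  expect_equal(m$copula$R, normal_rank_corr_matrix(df))
})

test_that("constrained fit recovers a known three-node chain", {
  # chain a -> b -> c with rho_ab = 0.6, rho_bc = 0.5, Markov: rho_ac = 0.3
  Rtrue <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.5, 0.3, 0.5, 1), 3, 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  u <- sample_gaussian_copula(gaussian_copula(Rtrue), 1e4, seed = 31)
  m <- fit_network(as.data.frame(u), chain_structure())
  expect_lt(max(abs(m$arc_partials - c(0.6, 0.5))), 0.05)
  # implied correlation between the chain ends is the product of the links
  imp <- implied_correlation_matrix(m)
  expect_lt(abs(imp["a", "c"] - imp["a", "b"] * imp["b", "c"]), 1e-10)

  # independent columns: arc partials within sampling error of zero
  u0 <- sample_gaussian_copula(diag(3), 5e3, seed = 32)
  colnames(u0) <- c("a", "b", "c")
  m0 <- fit_network(as.data.frame(u0), chain_structure())
  expect_lt(max(abs(m0$arc_partials)), 0.05)
})

test_that("fit rejects degenerate inputs", {
  df <- small_table_df(seed = 33)
  expect_error(fit_network(df[1:4, ]), "at least 5 rows")
  dfc <- df
  dfc[["Water salinity"]] <- 2
  expect_error(fit_network(dfc), "Water salinity")
  expect_error(fit_network(df[-1]), "Wetland size")
})

test_that("arc partials round-trip through the implied matrix", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 34)
  m <- fit_network(tab)
  imp <- implied_correlation_matrix(m)
  expect_equal(imp, m$copula$R, tolerance = 1e-10)
  # re-extract partials from the implied matrix: identical to stored
  m2 <- m
  m2$copula <- gaussian_copula(imp)
  expect_equal(wetlandbn:::extract_arc_partials(m2), m$arc_partials,
               tolerance = 1e-10)

  # also for a structure with inter-driver arcs (deeper DAG)
  st <- saturated_structure(c("a", "b", "c", "d"))
  Rr <- rand_corr(4, seed = 35)
  dimnames(Rr) <- list(st$nodes$name, st$nodes$name)
  u <- sample_gaussian_copula(gaussian_copula(Rr), 800, seed = 36)
  ms <- fit_network(as.data.frame(u), st)
  imp2 <- implied_correlation_matrix(ms)
  expect_equal(imp2, ms$copula$R, tolerance = 1e-10)
})

test_that("fitted matrix determinant lies in (0, 1]", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 37)
  m <- fit_network(tab)
  d <- det(m$copula$R)
  expect_gt(d, 0)
  expect_lte(d, 1 + 1e-12)
  # independence: determinant 1 exactly
  m_ind <- make_model(diag(3) |>
    (\(R) { dimnames(R) <- list(c("a","b","t"), c("a","b","t")); R })())
  expect_equal(det(implied_correlation_matrix(m_ind)), 1)
})

test_that("fitted arc partials into the target carry the expected signs", {
  # large-n synthetic data generated with the documented effect signs
  tab <- generate_wetlands(default_synthetic_spec(), n_wetlands = 4000,
                           seed = 38)
  m <- fit_network(tab)
  at <- arc_partial_table(m)
  neg <- c("Tourism pressure", "Anthropization", "Water discharges",
           "Water salinity", "Mean water level")
  pos <- c("Water diversions", "Wetland size")
  expect_true(all(at$partial[at$from %in% neg] < 0))
  expect_true(all(at$partial[at$from %in% pos] > 0))
})

test_that("a fitted model survives JSON serialization", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 39)
  m <- fit_network(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_fitted_model(m, path, seed = 39)
  back <- read_fitted_model(path)
  expect_equal(back$copula$R, m$copula$R, tolerance = 1e-9)
  expect_equal(back$arc_partials, m$arc_partials, tolerance = 1e-9)
  expect_equal(back$margins[["Number of species"]]$sorted_values,
               m$margins[["Number of species"]]$sorted_values)
})
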