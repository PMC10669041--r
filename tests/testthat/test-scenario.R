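test_that("the built-in catalog reproduces the 18 documented scenarios", {
  cat18 <- scenario_catalog()
  expect_length(cat18, 18L)
  expect_identical(names(cat18), letters[1:18])

  expect_length(cat18$a$evidence, 0L)
  expect_equal(cat18$m$evidence, c("Mean water level" = 3))
  expect_equal(cat18$f$evidence, c("Mean water level" = 11))
  expect_equal(cat18$b$evidence, c("Tourism pressure" = 3))

  # h is exactly the union of b-g
  union_bg <- unlist(lapply(cat18[c("b", "c", "d", "e", "f", "g")],
                            `[[`, "evidence"))
  names(union_bg) <- sub("^[b-g]\\.", "", names(union_bg))
  expect_equal(cat18$h$evidence[names(union_bg)], union_bg)
  # o is exactly the union of i-n
  union_in <- unlist(lapply(cat18[c("i", "j", "k", "l", "m", "n")],
                            `[[`, "evidence"))
  names(union_in) <- sub("^[i-n]\\.", "", names(union_in))
  expect_equal(cat18$o$evidence[names(union_in)], union_in)
  # p/q/r override one driver of h with its management value
  expect_equal(cat18$p$evidence[["Tourism pressure"]], 0)
  expect_equal(cat18$q$evidence[["Water salinity"]], 0)
  expect_equal(cat18$r$evidence[["Water discharges"]], 0)
  for (code in c("p", "q", "r")) {
    diff_nodes <- names(which(cat18$h$evidence !=
                                cat18[[code]]$evidence[names(cat18$h$evidence)]))
    expect_length(diff_nodes, 1L)
  }
})

test_that("scenario construction validates evidence", {
  expect_error(scenario("x", "worst-case", c("Number of species" = 10)),
               "target")
  expect_error(scenario("x", "worst-case", c("Water salinity" = 9)),
               "outside")
  expect_error(scenario("x", "worst-case", c("No such" = 1)), "unknown")
})

test_that("scenarios round-trip through a JSON file", {
  cat3 <- scenario_catalog()[c("a", "c", "m")]
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lapply(cat3, function(s) {
    list(code = s$code, label = s$label, evidence = as.list(s$evidence))
  }), path, auto_unbox = TRUE)
  back <- load_scenarios(path)
  expect_equal(back$c$evidence, cat3$c$evidence)
  expect_equal(back$m$label, "best-case")
})

test_that("conditioning on nothing reproduces the observed baseline", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 50)
  m <- fit_network(tab)
  draws <- conditionalize(m, n_samples = 2e4, seed = 51)
  tgt <- "Number of species"
  expect_lt(abs(mean(draws[[tgt]]) - mean(tab[[tgt]])),
            3 * stats::sd(tab[[tgt]]) / sqrt(22) + 0.5)
  expect_setequal(names(draws), names(tab))
})

test_that("z-space conditioning matches the closed-form Gaussian formulas", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("driver", "target"),
                              c("driver", "target")))
  m <- make_model(R)
  # evidence at the driver's median maps to z = 0
  draws <- conditionalize(m, c(driver = 0), n_samples = 1e5, seed = 52,
                          return_z = TRUE)
  z <- attr(draws, "z_samples")[, "target"]
  expect_lt(abs(mean(z) - 0), 3 * sqrt(0.75 / 1e5))
  expect_lt(abs(stats::var(z) - 0.75), 3 * 0.75 * sqrt(2 / 1e5))
})

test_that("independence model is unchanged by any evidence", {
  R <- diag(3)
  dimnames(R) <- list(c("a", "b", "t"), c("a", "b", "t"))
  m <- make_model(R)
  free <- conditionalize(m, n_samples = 5e4, seed = 53)$t
  cond <- conditionalize(m, c(a = 1.5, b = -0.5), n_samples = 5e4,
                         seed = 53)$t
  expect_lt(abs(mean(free) - mean(cond)), 0.02)
  expect_lt(abs(stats::sd(free) - stats::sd(cond)), 0.02)
})

test_that("conditionalize rejects evidence on the target or unknown nodes", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 54)
  m <- fit_network(tab)
  expect_error(conditionalize(m, c("Number of species" = 5), 100, 1),
               "target")
  expect_error(conditionalize(m, c("Nope" = 1), 100, 1), "unknown")
})

test_that("largest-remainder rounding conserves the total", {
  expect_equal(largest_remainder(c(0.5, 0.5), 22), c(11L, 11L))
  expect_equal(sum(largest_remainder(c(0.61, 0.29, 0.10), 22)), 22L)
  for (seed in 1:10) {
    set.seed(seed)
    p <- stats::runif(10); p <- p / sum(p)
    cnt <- largest_remainder(p, 22)
    expect_equal(sum(cnt), 22L)
    expect_true(all(abs(cnt - p * 22) < 1))
  }
})

test_that("scenario results conserve mass and stay inside the margin span", {
  tab <- generate_wetlands(default_synthetic_spec(), seed = 55)
  m <- fit_network(tab)
  cat18 <- scenario_catalog()
  for (code in c("a", "c", "h", "o")) {
    r <- run_scenario(m, cat18[[code]], n_samples = 2e4, seed = 56)
    expect_equal(sum(r$histogram), 1, tolerance = 1e-12)
    expect_equal(sum(r$wetland_counts), 22L)
    expect_gte(r$mu, min(tab[["Number of species"]]))
    expect_lte(r$mu, max(tab[["Number of species"]]))
  }
})

test_that("delta_vs_baseline is zero against itself and signed correctly", {
  tab <- generate_wetlands(default_synthetic_spec(), n_wetlands = 300,
                           seed = 57)
  m <- fit_network(tab)
  cat18 <- scenario_catalog()
  base <- run_scenario(m, cat18$a, n_samples = 3e4, seed = 58)
  expect_equal(delta_vs_baseline(base, base), 0)
  # widespread salinity must lower diversity under the generating signs
  worst_sal <- run_scenario(m, cat18$c, n_samples = 3e4, seed = 58)
  expect_lt(delta_vs_baseline(worst_sal, base), 0)
  other <- run_scenario(m, cat18$a, n_samples = 3e4, seed = 58,
                        bin_range = c(0, 40))
  expect_error(delta_vs_baseline(other, base), "bin ranges")
})

test_that("target mean is monotone in a negatively linked driver's level", {
  R <- matrix(c(1, -0.6, -0.6, 1), 2, 2,
              dimnames = list(c("Water salinity", "Number of species"),
                              c("Water salinity", "Number of species")))
  st <- network_structure(
    data.frame(name = colnames(R), role = c("hydrological", "target")),
    data.frame(from = "Water salinity", to = "Number of species",
               sign = "-"))
  set.seed(59)
  df <- as.data.frame(sample_gaussian_copula(gaussian_copula(R), 600, 59))
  df[["Water salinity"]] <- findInterval(df[["Water salinity"]],
                                         c(0.25, 0.5, 0.75))
  df[["Number of species"]] <- round(2 + 30 * df[["Number of species"]])
  m <- fit_network(df, st)
  mus <- vapply(0:3, function(lev) {
    run_scenario(m, scenario("x", "worst-case",
                             c("Water salinity" = lev)),
                 n_samples = 1e5, seed = 60)$mu
  }, numeric(1))
  expect_true(all(diff(mus) <= 0))
})

test_that("rejection sampling confirms conditionalization on a chain", {
  Rtrue <- matrix(c(1, 0.6, 0.3, 0.6, 1, 0.5, 0.3, 0.5, 1), 3, 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  u <- sample_gaussian_copula(gaussian_copula(Rtrue), 2e4, seed = 61)
  m <- fit_network(as.data.frame(u), chain_structure())
  pool <- sample_gaussian_copula(m$copula, 4e5, seed = 62)
  pool_c <- empirical_quantile(m$margins$c, pool[, "c"])
  keep <- abs(pool[, "a"] - 0.8) < 0.01
  oracle <- mean(pool_c[keep])
  got <- mean(conditionalize(m, c(a = 0.8), n_samples = 1e5,
                             seed = 63)$c)
  expect_lt(abs(got - oracle), 0.05)
})
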