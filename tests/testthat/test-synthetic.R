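test_that("the pear-like preset meets its contract", {
  s <- make_truth_surface("pear-like", seed = 7)
  expect_named(s, c("PR", "SL", "QI", "STN", "Vitri"))
  for (surf in s) {
    expect_gte(sum(surf$quadratic != 0), 1)
    expect_gte(sum(surf$interactions != 0), 1)
  }
  expect_identical(make_truth_surface("pear-like", seed = 7), s)
  expect_false(identical(make_truth_surface("pear-like", seed = 8), s))
})

test_that("declared-irrelevant factors have exactly zero effect", {
  spec <- list(intercept = 5, linear = c(1, -2, 0.5, 0, 0, 3),
               quadratic = c(-1, 0, 0, 0, 0, 2),
               interactions = NULL, clip = NULL, irrelevant = 6)
  surf <- make_truth_surface(spec = spec)
  x1 <- matrix(c(0.2, -0.4, 0.8, 0.1, 0, -1), nrow = 1)
  x2 <- x1; x2[6] <- 1
  expect_equal(surface_values(surf, x1), surface_values(surf, x2))
})

test_that("clipping keeps percentage outputs in range", {
  s <- make_truth_surface("pear-like", seed = 3)
  d <- generate_bbd(6)
  for (nm in c("STN", "Vitri")) {
    v <- surface_values(s[[nm]], d)
    expect_true(all(v >= 0 & v <= 100))
  }
})

test_that("zero noise reproduces the surface exactly; seeds are reproducible", {
  d <- generate_bbd(6)
  s <- make_truth_surface("pear-like", seed = 1)[["PR"]]
  ds <- simulate_responses(d, s, noise_sd = 0, replicates = 3, seed = 9)
  expect_equal(unname(ds$means[, 1]), unname(surface_values(s, d)))
  ds2 <- simulate_responses(d, s, noise_sd = 0.7, replicates = 5, seed = 9)
  ds3 <- simulate_responses(d, s, noise_sd = 0.7, replicates = 5, seed = 9)
  expect_identical(ds2, ds3)
  ds4 <- simulate_responses(d, s, noise_sd = 0.7, replicates = 5, seed = 10)
  expect_false(identical(ds2$means, ds4$means))
})

test_that("treatment means concentrate as sqrt(replicates) (normal theory)", {
  d <- generate_bbd(6)
  s <- make_truth_surface("pear-like", seed = 2)[["SL"]]
  truth <- surface_values(s, d)
  ds <- simulate_responses(d, s, noise_sd = 1, replicates = 10, seed = 4)
  dev <- abs(ds$means[, 1] - truth)
  expect_gte(mean(dev <= 3 / sqrt(10)), 0.95)
})

test_that("datasets share the design CSV schema", {
  d <- generate_bbd(6)
  s <- make_truth_surface("pear-like", seed = 1)
  ds <- simulate_responses(d, s, noise_sd = 0.2, replicates = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_true(all(c("run_id", "KNO3", "KNO3_actual", "PR", "Vitri") %in%
                    names(df)))
  expect_equal(nrow(df), 48)
})

test_that("surrogates, rankings and optima recover a known truth end to end", {
  d <- generate_bbd(6)
  X <- design_actual(d)
  surf <- make_truth_surface("pear-like", seed = 7)[["QI"]]
  y <- surface_values(surf, d)

  # GEP recovery on the noise-free surface
  fit <- NULL
  for (s in 1:2) {
    fit <- fit_gep(X, y, gep_config(population = 100, generations = 400,
                                    selection = "tournament",
                                    gene_ols = TRUE), seed = s)
    if (fit$rrse < 0.05) break
  }
  expect_lt(fit$rrse, 0.05)

  # M5' recovery on the same surface
  tree <- build_m5(X, y)
  expect_lt(rrse(predict_m5(tree, X), y), 0.05)

  # the GA optimum of the fitted surrogate sits near the true optimum
  prob <- optimization_problem(fit$model, "max", pear_bounds(),
                               names = colnames(X))
  ga <- ga_optimize(prob, pop_size = 60, generations = 80, seed = 1)
  grid <- as.matrix(expand.grid(lapply(1:6, function(j)
    seq(pear_bounds()[1, j], pear_bounds()[2, j], length.out = 7))))
  codes <- sapply(1:6, function(j) actual_to_code(grid[, j],
                                                  pear_factors()[[j]]))
  # pear_bounds order is NH4NO3 first but pear_factors is KNO3 first; both
  # share ranges for the first two, so map by name
  true_best <- max(surface_values(surf, codes))
  truth_at_ga <- surface_values(surf, matrix(sapply(1:6, function(j)
    actual_to_code(ga$par[j], pear_factors()[[j]])), nrow = 1))
  expect_gte(truth_at_ga, true_best - 0.05 * abs(true_best))
})
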