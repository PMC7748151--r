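test_that("standard deviation reduction matches hand computation", {
  expect_equal(sdr(c(5, 5, 5, 5), list(c(5, 5), c(5, 5))), 0)
  expect_equal(sdr(c(0, 0, 10, 10), list(c(0, 0), c(10, 10))), 5)
  expect_equal(sdr(c(1, 4, 2, 8), list(c(1, 4, 2, 8))), 0)
  expect_error(sdr(numeric(0), list()), "empty")
  expect_error(sdr(c(1, 2, 3), list(c(1, 2))), "cover")
})

test_that("a globally linear response yields a single exact leaf", {
  set.seed(10)
  X <- cbind(x1 = runif(100, -2, 2), x2 = runif(100, -2, 2))
  y <- 1 + 2 * X[, 1] - X[, 2]
  tree <- build_m5(X, y)
  expect_equal(tree$type, "leaf")
  expect_equal(unname(tree$model$intercept), 1, tolerance = 1e-6)
  expect_equal(unname(tree$model$coefs), c(2, -1), tolerance = 1e-6)
  expect_equal(predict_m5(tree, X), unname(y), tolerance = 1e-6)
})

test_that("a piecewise-linear response splits near the true breakpoint", {
  x1 <- seq(-1, 1, length.out = 200)
  X <- cbind(x1 = x1, x2 = runif(200))
  # two linear regimes with a level shift at the break so the standard
  # deviation criterion can see it (a symmetric hinge has zero SDR there)
  y <- ifelse(x1 <= 0, -x1, x1 + 2)
  tree <- build_m5(X, y, m5_config(pruning = FALSE))
  expect_equal(tree$type, "split")
  expect_equal(tree$attr_name, "x1")
  expect_lt(abs(tree$threshold), diff(x1)[1] + 1e-9)
})

test_that("a constant response collapses to a single constant leaf", {
  X <- cbind(a = runif(30), b = runif(30))
  tree <- build_m5(X, rep(4.2, 30))
  expect_equal(tree$type, "leaf")
  expect_equal(predict_m5(tree, X), rep(4.2, 30))
})

test_that("pruning never increases the leaf count", {
  set.seed(11)
  X <- cbind(a = runif(120), b = runif(120))
  y <- sin(4 * X[, 1]) + rnorm(120, 0, 0.3)
  full <- build_m5(X, y, m5_config(pruning = FALSE))
  pruned <- build_m5(X, y, m5_config(pruning = TRUE))
  expect_lte(m5_leaf_count(pruned), m5_leaf_count(full))
})

test_that("the chosen split maximizes SDR over all candidates", {
  set.seed(12)
  X <- cbind(a = runif(60), b = runif(60))
  y <- ifelse(X[, 1] > 0.5, 3, 0) + X[, 2]
  tree <- build_m5(X, y, m5_config(pruning = FALSE))
  expect_equal(tree$type, "split")
  best <- -Inf
  for (j in 1:2) {
    u <- sort(unique(X[, j]))
    for (t in (u[-1] + u[-length(u)]) / 2) {
      l <- X[, j] <= t
      if (sum(l) < 4 || sum(!l) < 4) next
      best <- max(best, sdr(y, list(y[l], y[!l])))
    }
  }
  got <- sdr(y, split(y, X[, tree$attribute] <= tree$threshold))
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("insufficient rows raise an error", {
  expect_error(build_m5(cbind(a = 1:5), 1:5), "insufficient")
})

test_that("published vitrification rules evaluate as printed", {
  rs <- get_model("OHF", "Vitri", "M5")
  # default rule region (D <= 1.375)
  x <- c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 0.1)
  expect_equal(predict_m5(rs, x), 4.544 + 2.8493 + 19.091, tolerance = 1e-9)
  # rule 1 (D > 1.375); value recomputed by hand from the printed coefficients
  x["D"] <- 2
  expect_equal(predict_m5(rs, x),
               4.1865 + 0.9834 - 0.6441 + 5.5661 * 2 + 2.1536 - 18.0036,
               tolerance = 1e-9)
  expect_equal(predict_m5(rs, x), -0.192, tolerance = 1e-4)
})

test_that("rule evaluation is strictly first-match", {
  rs <- m5_ruleset(list(
    list(conditions = list(list(attr = "A", op = ">", threshold = 1)),
         model = list(intercept = 100, coefs = c(A = 0))),
    list(conditions = list(list(attr = "A", op = ">", threshold = 0)),
         model = list(intercept = 7, coefs = c(A = 0))),
    list(conditions = list(), model = list(intercept = -1, coefs = c(A = 0)))))
  expect_equal(predict_m5(rs, c(A = 2)), 100)   # rule 1 wins although 2 matches
  expect_equal(predict_m5(rs, c(A = 0.5)), 7)
  expect_equal(predict_m5(rs, c(A = -3)), -1)
})

test_that("tree export to a rule set preserves predictions", {
  set.seed(13)
  X <- cbind(a = runif(80), b = runif(80))
  y <- ifelse(X[, 1] > 0.5, 2 + X[, 2], -1 + 2 * X[, 2])
  tree <- build_m5(X, y, m5_config(pruning = FALSE))
  rs <- m5_to_ruleset(tree)
  expect_equal(predict_m5(rs, X), predict_m5(tree, X), tolerance = 1e-9)
})

test_that("rule sets round-trip through the If/Then text format", {
  rs <- get_model("Pyrodwarf", "PR", "M5")
  path <- withr::local_tempfile(fileext = ".txt")
  write_ruleset_text(rs, path)
  rs2 <- read_ruleset_text(path)
  set.seed(14)
  for (i in 1:20) {
    x <- c(A = runif(1, 0.5, 2), B = runif(1, 0.5, 2), C = runif(1, 0.5, 2.5),
           D = runif(1, 0.5, 4), E = runif(1, 0.5, 3), F = runif(1, 0.05, 0.2))
    expect_equal(predict_m5(rs2, x), predict_m5(rs, x), tolerance = 1e-9)
  }
})

test_that("a ruleset must end with a default rule", {
  expect_error(m5_ruleset(list(
    list(conditions = list(list(attr = "A", op = ">", threshold = 0)),
         model = list(intercept = 0, coefs = c(A = 1))))), "unconditional")
})
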