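bi_problem <- function() {
  optimization_problem(
    models = list(function(x) x[1]^2, function(x) (x[1] - 2)^2),
    directions = c("min", "min"),
    bounds = rbind(-2, 4))
}

test_that("dominance follows the Pareto definition", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_false(dominates(c(1, 3), c(2, 2)))
  expect_false(dominates(c(2, 2), c(1, 3)))
  expect_true(dominates(c(2, 1), c(1, 1), directions = c("max", "min")))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("mono-objective GA finds a simple known optimum in every seed", {
  p <- optimization_problem(function(x) -(x[1] - 1)^2, "max", rbind(0, 2))
  for (s in 1:5) {
    r <- ga_optimize(p, pop_size = 40, generations = 60, seed = s)
    expect_equal(unname(r$par[1]), 1, tolerance = 1e-3)
  }
})

test_that("GA solutions always satisfy the box bounds", {
  p <- optimization_problem(function(x) sum(sin(5 * x) + x), "max",
                            pear_bounds())
  r <- ga_optimize(p, pop_size = 30, generations = 30, seed = 1)
  expect_true(all(r$par >= pear_bounds()[1, ] - 1e-12))
  expect_true(all(r$par <= pear_bounds()[2, ] + 1e-12))
})

test_that("the PSO velocity update matches the textbook equations", {
  b <- rbind(-100, 100)
  # pure inertia
  p <- list(x = 1, v = 0.5, pbest = 1)
  p2 <- pso_update(p, gbest = 1, bounds = b, w = 1, c1 = 0, c2 = 0)
  expect_equal(p2$v, 0.5)
  expect_equal(p2$x, 1.5)
  # x at both bests: velocity only decays by w
  p <- list(x = 2, v = 1, pbest = 2)
  p2 <- pso_update(p, gbest = 2, bounds = b, w = 0.9, c1 = 2, c2 = 2)
  expect_equal(p2$v, 0.9)
  # hand-computed full update with fixed random factors
  p <- list(x = 0, v = 1, pbest = 1)
  p2 <- pso_update(p, gbest = 2, bounds = b, w = 0.9, c1 = 2, c2 = 2,
                   r1 = 1, r2 = 1)
  expect_equal(p2$v, 0.9 + 2 + 4)
  expect_equal(p2$x, 6.9)
})

test_that("clamping zeroes the velocity at clamped coordinates", {
  b <- rbind(0, 1)
  p <- list(x = 0.9, v = 0.5, pbest = 0.9)
  p2 <- pso_update(p, gbest = 0.9, bounds = b, w = 1, c1 = 0, c2 = 0)
  expect_equal(p2$x, 1)
  expect_equal(p2$v, 0)
})

test_that("coefficient ranges are enforced", {
  b <- rbind(0, 1)
  p <- list(x = 0.5, v = 0, pbest = 0.5)
  expect_error(pso_update(p, 0.5, b, w = 0.5), "inertia")
  expect_error(pso_update(p, 0.5, b, c1 = 3), "c1")
})

test_that("archives never retain a dominated pair", {
  set.seed(30)
  a <- pareto_archive(30, directions = c("min", "min"))
  for (i in 1:2000) {
    x <- runif(2)
    archive_insert(a, x, c(sum(x^2), sum((x - 1)^2)))
    FF <- a$FF
    if (nrow(FF) > 1) {
      for (k in sample(nrow(FF), min(3, nrow(FF)))) {
        others <- FF[-k, , drop = FALSE]
        expect_false(any(apply(others, 1, function(f)
          dominates(f, FF[k, ], c("min", "min")))))
      }
    }
  }
  expect_lte(nrow(a$FF), 30)
})

test_that("inserting a dominated candidate leaves the archive unchanged", {
  a <- pareto_archive(10, directions = c("min", "min"))
  archive_insert(a, c(0, 0), c(1, 1))
  before <- list(X = a$X, FF = a$FF)
  expect_false(archive_insert(a, c(9, 9), c(2, 2)))
  expect_identical(list(X = a$X, FF = a$FF), before)
})

test_that("MOPSO covers the analytic front of the bi-objective benchmark", {
  arch <- mopso_optimize(bi_problem(), swarm_size = 40, iterations = 60,
                         capacity = 50, seed = 1)
  pos <- arch$X[, 1]
  expect_true(all(pos >= -0.05 & pos <= 2.05))
  hv <- vitropt:::.hypervolume2d(arch$FF, c(5, 5))
  # analytic hypervolume of the front {(t^2, (t-2)^2): t in [0, 2]} vs (5,5):
  # integral 1 + 4 sqrt(a) - a over [0,4] plus the 1 x 5 strip = 67/3
  expect_gt(hv, 0.95 * 67 / 3)
})

test_that("degenerate single-point bounds give a one-member archive", {
  p <- optimization_problem(list(function(x) x[1], function(x) -x[1]),
                            c("min", "min"), rbind(1, 1))
  arch <- mopso_optimize(p, swarm_size = 10, iterations = 5, seed = 1)
  expect_equal(nrow(arch$FF), 1)
})

test_that("NSGA-II matches the benchmark front and the GA on one objective", {
  arch <- nsga2_optimize(bi_problem(), pop_size = 40, generations = 40,
                         seed = 1)
  hv <- vitropt:::.hypervolume2d(arch$FF, c(5, 5))
  expect_gt(hv, 0.95 * 67 / 3)
  expect_lte(nrow(arch$FF), 40)
  # single-objective degenerate call approximates ga_optimize
  p1 <- optimization_problem(function(x) -(x[1] - 1)^2, "max", rbind(0, 2))
  a1 <- nsga2_optimize(p1, pop_size = 30, generations = 40, seed = 2)
  g1 <- ga_optimize(p1, pop_size = 30, generations = 40, seed = 2)
  expect_equal(max(a1$FF[, 1]), g1$value, tolerance = 1e-2)
})

test_that("representative selection follows the weighted scalarization", {
  a <- pareto_archive(10, directions = c("min", "min"))
  archive_insert(a, c(0), c(0, 4))
  archive_insert(a, c(1), c(1, 1))
  archive_insert(a, c(2), c(4, 0))
  one <- select_representative(a, weights = c(1, 0))
  expect_equal(unname(one$objectives), c(0, 4))
  knee <- select_representative(a, weights = c(1, 1))
  expect_equal(unname(knee$objectives), c(1, 1))
  empty <- pareto_archive(5, directions = "min")
  expect_error(select_representative(empty), "empty")
  expect_error(select_representative(a, weights = c(0, 0)), "weights")
})

test_that("single-member archives return that member", {
  a <- pareto_archive(10, directions = c("min", "min"))
  archive_insert(a, c(0.5), c(1, 2))
  r <- select_representative(a)
  expect_equal(unname(r$par), 0.5)
})
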