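make_gene <- function(head, tail) {
  list(head = head, tail = tail,
       rnc = rep(1L, length(tail)), pool = rep(0.5, 10))
}

test_that("Karva decoding is breadth-first", {
  g <- make_gene(c("+", "*", "A"), c("B", "A", "B", "A"))
  m <- decode_gene(g)
  # (B * A) + A
  x <- c(A = 3, B = 2, C = 0, D = 0, E = 0, F = 0)
  expect_equal(evaluate_expression(m, x), 2 * 3 + 3)
})

test_that("a terminal at the root terminates decoding immediately", {
  g <- make_gene(c("C", "+", "*"), c("A", "A", "A", "A"))
  m <- decode_gene(g)
  expect_equal(evaluate_expression(m, c(A = 1, B = 1, C = 7,
                                        D = 1, E = 1, F = 1)), 7)
})

test_that("function symbols in the tail are rejected", {
  g <- make_gene(c("+", "A", "A"), c("B", "+", "B", "B"))
  expect_error(decode_gene(g), "tail")
})

test_that("random genes always decode to complete, evaluable trees", {
  set.seed(42)
  fs <- gep_function_set()
  cfg <- gep_config()
  terms <- c(LETTERS[1:6], "?")
  x <- c(A = 0.9, B = 1.1, C = 1.5, D = 2, E = 1.7, F = 0.1)
  for (i in 1:500) {
    g <- vitropt:::.random_gene(fs, terms, cfg)
    m <- decode_gene(g)
    v <- evaluate_expression(m, x)
    expect_length(v, 1)  # complete tree; sentinels (NA) are permitted
  }
})

test_that("rrse matches its definition", {
  obs <- c(1, 2, 3)
  expect_equal(rrse(rep(mean(obs), 3), obs), 1)
  expect_equal(rrse(obs, obs), 0)
  expect_equal(rrse(c(1, 2, 4), obs), sqrt(1 / 2))
  expect_error(rrse(c(1, 2), c(5, 5)), "identical")
  expect_error(rrse(1:3, 1:4), "equal length")
})

test_that("protected semantics absorb domain violations as sentinels", {
  m <- model_expression("inv(A)")
  expect_true(is.na(evaluate_expression(m, c(A = 0, B = 0, C = 0,
                                             D = 0, E = 0, F = 0))))
  m2 <- model_expression("pln(A)")
  expect_true(is.na(evaluate_expression(m2, c(A = 0, B = 1, C = 1,
                                              D = 1, E = 1, F = 1))))
  expect_equal(evaluate_expression(m2, c(A = -exp(2), B = 1, C = 1,
                                         D = 1, E = 1, F = 1)), 2)
  m3 <- model_expression("pexp(A)")
  expect_true(is.finite(evaluate_expression(m3, c(A = 1e6, B = 1, C = 1,
                                                  D = 1, E = 1, F = 1))))
})

test_that("variation with zero rates is the identity", {
  set.seed(1)
  fs <- gep_function_set()
  cfg <- gep_config(mutation_rate = 0, inversion_rate = 0, one_point_rate = 0,
                    two_point_rate = 0, gene_recombination_rate = 0,
                    gene_transposition_rate = 0)
  pop <- replicate(6, vitropt:::.random_chromosome(fs, c(LETTERS[1:6], "?"),
                                                   cfg), simplify = FALSE)
  expect_identical(apply_variation(pop, cfg), pop)
})

test_that("tail mutation only ever writes terminals", {
  set.seed(2)
  fs <- gep_function_set()
  cfg <- gep_config(mutation_rate = 1, inversion_rate = 0, one_point_rate = 0,
                    two_point_rate = 0, gene_recombination_rate = 0,
                    gene_transposition_rate = 0)
  terms <- c(LETTERS[1:6], "?")
  pop <- replicate(10, vitropt:::.random_chromosome(fs, terms, cfg),
                   simplify = FALSE)
  out <- apply_variation(pop, cfg)
  for (ch in out) for (g in ch$genes)
    expect_true(all(g$tail %in% terms))
})

test_that("operators conserve chromosome architecture", {
  set.seed(3)
  fs <- gep_function_set()
  cfg <- gep_config()
  terms <- c(LETTERS[1:6], "?")
  pop <- replicate(20, vitropt:::.random_chromosome(fs, terms, cfg),
                   simplify = FALSE)
  for (rep_ in 1:20) {
    pop <- apply_variation(pop, cfg)
    for (ch in pop) {
      expect_length(ch$genes, cfg$n_genes)
      for (g in ch$genes) {
        expect_length(g$head, cfg$head_length)
        expect_length(g$tail, cfg$head_length + 1L)
        expect_no_error(decode_gene(g, fs))
      }
    }
  }
})

test_that("the best-RRSE trace is non-increasing under elitism", {
  d <- generate_bbd(6)
  X <- design_actual(d)
  y <- X[, 1] * X[, 3] + X[, 5]^2
  f <- fit_gep(X, y, gep_config(generations = 30), seed = 11)
  expect_true(all(diff(f$trace) <= 1e-12))
})

test_that("serialization round-trips bit-identically on a grid", {
  m <- get_model("OHF", "PR", "GEP")
  m2 <- model_expression(render_expression_text(m))
  set.seed(4)
  grid <- matrix(runif(100 * 6, 0.5, 2), ncol = 6,
                 dimnames = list(NULL, LETTERS[1:6]))
  expect_equal(evaluate_expression(m2, grid), evaluate_expression(m, grid),
               tolerance = 1e-12)
})

test_that("model text files round-trip with provenance", {
  m <- model_expression("A + x2(B) - 0.5", provenance = "fitted")
  path <- withr::local_tempfile(fileext = ".txt")
  write_model_text(m, path, metadata = list(response = "PR"))
  m2 <- read_model_text(path)
  expect_equal(m2$provenance, "fitted")
  x <- c(A = 1, B = 2, C = 0, D = 0, E = 0, F = 0)
  expect_equal(evaluate_expression(m2, x), evaluate_expression(m, x))
})

test_that("fitting in gene-OLS mode folds weights into the returned model", {
  d <- generate_bbd(6)
  X <- design_actual(d)
  y <- 2 + 3 * X[, 2] - 0.5 * X[, 4]
  f <- fit_gep(X, y, gep_config(generations = 60, gene_ols = TRUE), seed = 5)
  colnames(X) <- LETTERS[1:6]
  expect_equal(rrse(evaluate_expression(f$model, X), y), f$rrse,
               tolerance = 1e-8)
})
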