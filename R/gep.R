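# Gene expression programming: Karva-encoded fixed-length chromosomes,
# protected function set, RRSE fitness, and the classic genetic operators.

#' The GEP function set
#'
#' The sixteen operators used for the pear-media models: the four arithmetic
#' operators, square and cube roots, sin, cos, arctangent, square, cube,
#' exponential, (protected) natural log, inverse, hyperbolic tangent, and the
#' two-input average. Maximum arity is 2.
#'
#' @return Data frame with columns `symbol`, `arity`, `fun` (name of the
#'   protected primitive used for evaluation).
#' @export
gep_function_set <- function() {
  data.frame(
    symbol = c("+", "-", "*", "/", "sqrt", "cbrt", "sin", "cos", "atan",
               "x2", "x3", "exp", "ln", "inv", "tanh", "avg2"),
    arity  = c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2),
    fun    = c("+", "-", "*", "pdiv", "psqrt", "cbrt", "sin", "cos", "arctg",
               "x2", "x3", "pexp", "pln", "inv", "tanh", "avg2"),
    stringsAsFactors = FALSE
  )
}

#' GEP run configuration
#'
#' Defaults follow the published training setup: population 50, head length 8,
#' three genes linked by addition, mutation 0.044, inversion 0.1, one-point
#' recombination 0.1, two-point recombination 0.3, gene recombination 0.1 and
#' gene transposition 0.1. The selection scheme and generation count are not
#' part of that setup; defaults are roulette-wheel selection on fitness
#' 1000/(1 + RRSE) with single elitism, stopping after `generations`
#' generations or once RRSE < 1e-6. Random numerical constants (a per-gene
#' ten-value pool on \[-10, 10\]) are enabled by default.
#'
#' @param population Population size (>= 2).
#' @param head_length Gene head length h; tail length is h + 1.
#' @param n_genes Genes per chromosome; sub-trees are linked by addition.
#' @param mutation_rate,inversion_rate,one_point_rate,two_point_rate,gene_recombination_rate,gene_transposition_rate
#'   Operator rates in \[0, 1\].
#' @param generations Maximum generations.
#' @param selection `"roulette"` or `"tournament"` (size 2).
#' @param elitism Number of best individuals copied unchanged.
#' @param rnc_enabled Use random numerical constants?
#' @param rnc_pool_size,rnc_range Constant pool size and range.
#' @param stop_rrse Early-stop threshold on best RRSE.
#' @param gene_ols Weight the gene sub-trees by least squares instead of
#'   plain addition, treating each decoded gene as a discovered basis
#'   function. Off by default (the published setup links genes by plain
#'   addition); switching it on greatly improves recovery of additive
#'   polynomial surfaces.
#' @param linear_scaling Fit each candidate's optimal affine output scaling
#'   (slope/intercept by least squares) before computing RRSE, folding the
#'   two constants back into the returned expression. Standard
#'   symbolic-regression practice: it relieves the evolutionary search of
#'   output-scale constant tuning without changing the model class.
#' @return A `gep_config` list.
#' @export
gep_config <- function(population = 50, head_length = 8, n_genes = 3,
                       mutation_rate = 0.044, inversion_rate = 0.1,
                       one_point_rate = 0.1, two_point_rate = 0.3,
                       gene_recombination_rate = 0.1,
                       gene_transposition_rate = 0.1,
                       generations = 500, selection = c("roulette", "tournament"),
                       elitism = 1, rnc_enabled = TRUE, rnc_pool_size = 10,
                       rnc_range = c(-10, 10), stop_rrse = 1e-6,
                       linear_scaling = TRUE, gene_ols = FALSE) {
  rates <- c(mutation_rate, inversion_rate, one_point_rate, two_point_rate,
             gene_recombination_rate, gene_transposition_rate)
  if (any(rates < 0 | rates > 1)) stop("operator rates must lie in [0, 1]")
  if (population < 2) stop("population must be >= 2")
  structure(list(population = population, head_length = head_length,
                 n_genes = n_genes, mutation_rate = mutation_rate,
                 inversion_rate = inversion_rate, one_point_rate = one_point_rate,
                 two_point_rate = two_point_rate,
                 gene_recombination_rate = gene_recombination_rate,
                 gene_transposition_rate = gene_transposition_rate,
                 generations = generations,
                 selection = match.arg(selection), elitism = elitism,
                 rnc_enabled = rnc_enabled, rnc_pool_size = rnc_pool_size,
                 rnc_range = rnc_range, stop_rrse = stop_rrse,
                 linear_scaling = linear_scaling, gene_ols = gene_ols),
            class = "gep_config")
}

.gep_terminals <- function(n_inputs, rnc) {
  c(LETTERS[seq_len(n_inputs)], if (rnc) "?")
}

# head symbols: functions and terminals as classes get equal probability, so
# half the head positions are leaves on average and additive structures are
# reachable (uniform sampling over the 16-function set buries them)
.sample_head <- function(n, fs, terminals) {
  is_fun <- stats::runif(n) < 0.5
  out <- character(n)
  out[is_fun] <- sample(fs$symbol, sum(is_fun), replace = TRUE)
  out[!is_fun] <- sample(terminals, sum(!is_fun), replace = TRUE)
  out
}

.random_gene <- function(fs, terminals, config) {
  h <- config$head_length
  t <- h + 1L  # max arity is 2
  gene <- list(
    head = .sample_head(h, fs, terminals),
    tail = sample(terminals, t, replace = TRUE),
    rnc  = sample.int(config$rnc_pool_size, t, replace = TRUE),
    pool = stats::runif(config$rnc_pool_size, config$rnc_range[1],
                        config$rnc_range[2])
  )
  gene
}

.random_chromosome <- function(fs, terminals, config) {
  list(genes = replicate(config$n_genes,
                         .random_gene(fs, terminals, config), simplify = FALSE))
}

#' Decode one gene by Karva (breadth-first) reading
#'
#' Reads the gene's symbols left to right, filling the argument slots of the
#' growing expression tree level by level; unused trailing symbols are
#' ignored. Tail symbols must all be terminals.
#'
#' @param gene List with `head` and `tail` character vectors (and, when
#'   constants are in use, `rnc` index vector and `pool` numeric vector).
#' @param fs Function set from [gep_function_set()].
#' @return A `model_expression` for the gene's sub-tree.
#' @export
decode_gene <- function(gene, fs = gep_function_set()) {
  syms <- c(gene$head, gene$tail)
  if (any(gene$tail %in% fs$symbol))
    stop("invalid gene: tail contains function symbols")
  arity <- stats::setNames(fs$arity, fs$symbol)
  fun   <- stats::setNames(fs$fun, fs$symbol)
  n_const <- 0L
  # breadth-first: queue of nodes to expand, each consuming symbols in order
  pos <- 1L
  take <- function() {
    s <- syms[[pos]]; pos <<- pos + 1L
    s
  }
  new_node <- function() {
    s <- take()
    if (s %in% fs$symbol) list(op = s, need = arity[[s]], args = list())
    else if (s == "?") {
      n_const <<- n_const + 1L
      val <- gene$pool[[gene$rnc[[n_const]]]]
      list(op = NULL, value = val)
    } else list(op = NULL, value = as.name(s))
  }
  root <- new_node()
  queue <- list()  # references by index into a flat node store
  store <- list(root)
  if (!is.null(root$op)) queue <- c(queue, 1L)
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(store[[i]]$need)) {
      child <- new_node()
      store[[length(store) + 1L]] <- child
      store[[i]]$args <- c(store[[i]]$args, length(store))
      if (!is.null(child$op)) queue <- c(queue, length(store))
    }
  }
  build <- function(i) {
    nd <- store[[i]]
    if (is.null(nd$op)) return(nd$value)
    as.call(c(as.name(fun[[nd$op]]), lapply(nd$args, build)))
  }
  model_expression(build(1L), provenance = "fitted")
}

.decode_chromosome <- function(chrom, fs) {
  exprs <- lapply(chrom$genes, function(g) decode_gene(g, fs)$expr)
  Reduce(function(a, b) call("+", a, b), exprs)
}

#' Chromosome as a model expression
#'
#' @param chrom A chromosome (list of genes).
#' @param fs Function set.
#' @return A `model_expression` (genes linked by addition).
#' @export
decode_chromosome <- function(chrom, fs = gep_function_set()) {
  model_expression(.decode_chromosome(chrom, fs), provenance = "fitted")
}

#' Root relative squared error
#'
#' `sqrt(sum((o - p)^2) / sum((o - mean(o))^2))`: 0 for a perfect fit, 1 for
#' the mean predictor.
#'
#' @param predictions,observations Equal-length numeric vectors (length >= 2).
#' @return Non-negative scalar; `NA` inputs propagate to `Inf`-like worst
#'   fitness in the fitting loop.
#' @export
rrse <- function(predictions, observations) {
  if (length(predictions) != length(observations))
    stop("predictions and observations must have equal length")
  if (length(observations) < 2) stop("need at least two observations")
  sst <- sum((observations - mean(observations))^2)
  if (sst == 0) stop("observations are all identical: RRSE undefined")
  sqrt(sum((observations - predictions)^2) / sst)
}

# -- genetic operators --------------------------------------------------------

.mutate_chromosome <- function(chrom, fs, terminals, config) {
  for (gi in seq_along(chrom$genes)) {
    g <- chrom$genes[[gi]]
    hm <- stats::runif(length(g$head)) < config$mutation_rate
    if (any(hm)) g$head[hm] <- .sample_head(sum(hm), fs, terminals)
    tm <- stats::runif(length(g$tail)) < config$mutation_rate
    if (any(tm)) g$tail[tm] <- sample(terminals, sum(tm), replace = TRUE)
    if (config$rnc_enabled) {
      rm_ <- stats::runif(length(g$rnc)) < config$mutation_rate
      if (any(rm_)) g$rnc[rm_] <- sample.int(config$rnc_pool_size, sum(rm_),
                                             replace = TRUE)
      pm <- stats::runif(length(g$pool)) < config$mutation_rate
      if (any(pm))
        g$pool[pm] <- pmin(pmax(g$pool[pm] + stats::rnorm(sum(pm), 0, 0.5),
                                config$rnc_range[1]), config$rnc_range[2])
    }
    chrom$genes[[gi]] <- g
  }
  chrom
}

# insertion-sequence transposition: copy a short element and insert it in the
# head (shifting symbols right); root variant forces a function at position 1
.is_transpose <- function(chrom, config, fs, root = FALSE) {
  rate <- config$gene_transposition_rate  # shared rate for the transposon family
  if (stats::runif(1) >= rate) return(chrom)
  gi <- sample.int(length(chrom$genes), 1)
  g <- chrom$genes[[gi]]
  syms <- c(g$head, g$tail)
  len <- sample(1:3, 1)
  start <- sample.int(length(syms) - len + 1L, 1)
  piece <- syms[start:(start + len - 1L)]
  h <- length(g$head)
  if (root) {
    fpos <- which(piece %in% fs$symbol)
    if (!length(fpos)) return(chrom)
    piece <- piece[fpos[1]:length(piece)]
    g$head <- c(piece, g$head)[seq_len(h)]
  } else {
    if (h < 2) return(chrom)
    at <- sample(2:h, 1)
    g$head <- append(g$head, piece, after = at - 1L)[seq_len(h)]
  }
  chrom$genes[[gi]] <- g
  chrom
}

.invert_chromosome <- function(chrom, config) {
  if (stats::runif(1) >= config$inversion_rate) return(chrom)
  gi <- sample.int(length(chrom$genes), 1)
  h <- length(chrom$genes[[gi]]$head)
  if (h < 2) return(chrom)
  ends <- sort(sample.int(h, 2))
  idx <- ends[1]:ends[2]
  chrom$genes[[gi]]$head[idx] <- rev(chrom$genes[[gi]]$head[idx])
  chrom
}

.transpose_gene <- function(chrom, config) {
  if (length(chrom$genes) < 2 ||
      stats::runif(1) >= config$gene_transposition_rate) return(chrom)
  gi <- sample(2:length(chrom$genes), 1)
  chrom$genes <- c(chrom$genes[gi], chrom$genes[-gi])
  chrom
}

# flatten to a linear string of per-position slots for crossover; positions
# are (gene, section, index) triples shared by all chromosomes of a run
.chrom_flatten <- function(chrom) {
  unlist(lapply(chrom$genes, function(g)
    c(g$head, g$tail, as.character(g$rnc))), use.names = FALSE)
}

.chrom_unflatten <- function(flat, template) {
  pos <- 1L
  for (gi in seq_along(template$genes)) {
    g <- template$genes[[gi]]
    nh <- length(g$head); nt <- length(g$tail); nr <- length(g$rnc)
    g$head <- flat[pos:(pos + nh - 1L)]; pos <- pos + nh
    g$tail <- flat[pos:(pos + nt - 1L)]; pos <- pos + nt
    g$rnc  <- as.integer(flat[pos:(pos + nr - 1L)]); pos <- pos + nr
    template$genes[[gi]] <- g
  }
  template
}

.recombine <- function(c1, c2, points) {
  f1 <- .chrom_flatten(c1); f2 <- .chrom_flatten(c2)
  n <- length(f1)
  cuts <- sort(sample.int(n - 1L, points))
  swap <- FALSE; from <- 1L
  for (cut in c(cuts, n)) {
    if (swap) {
      tmp <- f1[from:cut]; f1[from:cut] <- f2[from:cut]; f2[from:cut] <- tmp
    }
    swap <- !swap; from <- cut + 1L
  }
  list(.chrom_unflatten(f1, c1), .chrom_unflatten(f2, c2))
}

.gene_recombine <- function(c1, c2) {
  gi <- sample.int(length(c1$genes), 1)
  tmp <- c1$genes[[gi]]; c1$genes[[gi]] <- c2$genes[[gi]]; c2$genes[[gi]] <- tmp
  list(c1, c2)
}

#' Apply the GEP variation operators to a population
#'
#' Point mutation (tail positions stay terminal), head-segment inversion,
#' one-point / two-point / whole-gene recombination and whole-gene
#' transposition, each at its configured rate. Chromosome architecture
#' (gene count, head/tail lengths) is conserved, so every offspring decodes
#' to a valid expression tree.
#'
#' @param population List of chromosomes.
#' @param config A [gep_config()].
#' @param fs Function set.
#' @param n_inputs Number of input terminals.
#' @return The varied population (same size).
#' @export
apply_variation <- function(population, config, fs = gep_function_set(),
                            n_inputs = 6) {
  terminals <- .gep_terminals(n_inputs, config$rnc_enabled)
  population <- lapply(population, function(ch) {
    ch <- .mutate_chromosome(ch, fs, terminals, config)
    ch <- .invert_chromosome(ch, config)
    ch <- .is_transpose(ch, config, fs, root = FALSE)
    ch <- .is_transpose(ch, config, fs, root = TRUE)
    .transpose_gene(ch, config)
  })
  n <- length(population)
  if (n >= 2) {
    pair_apply <- function(rate, fun) {
      idx <- sample.int(n)
      for (i in seq(1, n - 1, by = 2)) {
        if (stats::runif(1) < rate) {
          out <- fun(population[[idx[i]]], population[[idx[i + 1]]])
          population[[idx[i]]] <<- out[[1]]
          population[[idx[i + 1]]] <<- out[[2]]
        }
      }
    }
    pair_apply(config$one_point_rate, function(a, b) .recombine(a, b, 1L))
    pair_apply(config$two_point_rate, function(a, b) .recombine(a, b, 2L))
    pair_apply(config$gene_recombination_rate, .gene_recombine)
  }
  population
}

#' Fit a symbolic-regression model by gene expression programming
#'
#' Evolves a population of Karva-encoded chromosomes against the root
#' relative squared error of their decoded expressions, with elitism, and
#' returns the best-of-run model together with the per-generation best-RRSE
#' trace (non-increasing under elitism). Individuals whose protected
#' evaluation produces a sentinel (`NA`) anywhere on the training data get
#' worst-possible fitness.
#'
#' @param design A `design_table`, or a numeric matrix of inputs (columns are
#'   mapped to terminals `A`, `B`, ... in order). Design tables are expanded
#'   to actual units.
#' @param responses Numeric response vector aligned with the rows.
#' @param config A [gep_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return List with `model` (a `model_expression`), `rrse` (best RRSE),
#'   `trace` (best RRSE per generation), and `chromosome`.
#' @export
fit_gep <- function(design, responses, config = gep_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (inherits(design, "design_table")) design_actual(design) else
    as.matrix(design)
  n_inputs <- ncol(X)
  if (n_inputs > 12) stop("at most 12 input terminals supported")
  colnames(X) <- LETTERS[seq_len(n_inputs)]
  if (nrow(X) != length(responses))
    stop("responses must align with design rows")
  sst <- sum((responses - mean(responses))^2)
  if (sst == 0) stop("observations are all identical: RRSE undefined")

  fs <- gep_function_set()
  terminals <- .gep_terminals(n_inputs, config$rnc_enabled)
  env_data <- new.env(parent = .protected_env())
  for (v in colnames(X)) assign(v, X[, v], envir = env_data)

  gene_matrix <- function(chrom) {
    cols <- lapply(chrom$genes, function(g) {
      v <- tryCatch(as.numeric(eval(decode_gene(g, fs)$expr, env_data)),
                    error = function(e) NA)
      if (length(v) == 1L) v <- rep(v, nrow(X))
      v
    })
    do.call(cbind, cols)
  }
  ols_fit <- function(chrom) {
    G <- gene_matrix(chrom)
    if (anyNA(G) || !all(is.finite(G))) return(NULL)
    fit <- stats::lm.fit(cbind(1, G), responses)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(beta = beta, pred = drop(cbind(1, G) %*% beta))
  }
  score <- function(chrom) {
    if (config$gene_ols) {
      f <- ols_fit(chrom)
      if (is.null(f)) return(Inf)
      return(sqrt(sum((responses - f$pred)^2) / sst))
    }
    expr <- .decode_chromosome(chrom, fs)
    pred <- tryCatch(as.numeric(eval(expr, env_data)), error = function(e) NA)
    if (length(pred) == 1L) pred <- rep(pred, nrow(X))
    if (anyNA(pred) || !all(is.finite(pred))) return(Inf)
    if (config$linear_scaling) {
      vp <- stats::var(pred)
      b <- if (vp > 1e-300) stats::cov(responses, pred) / vp else 0
      a <- mean(responses) - b * mean(pred)
      pred <- a + b * pred
    }
    sqrt(sum((responses - pred)^2) / sst)
  }

  pop <- replicate(config$population,
                   .random_chromosome(fs, terminals, config), simplify = FALSE)
  fit <- vapply(pop, score, 0)
  best_i <- which.min(fit)
  best <- list(chrom = pop[[best_i]], rrse = fit[[best_i]])
  trace <- numeric(0)

  for (gen in seq_len(config$generations)) {
    w <- 1000 / (1 + ifelse(is.finite(fit), fit, 1e12))
    pick <- if (config$selection == "roulette") {
      sample.int(length(pop), length(pop), replace = TRUE, prob = w)
    } else {
      vapply(seq_along(pop), function(i) {
        cand <- sample.int(length(pop), 2)
        cand[which.max(w[cand])]
      }, 0L)
    }
    pop <- apply_variation(pop[pick], config, fs, n_inputs)
    # elitism: reinsert the best-so-far chromosome unchanged
    if (config$elitism > 0) pop[[1]] <- best$chrom
    fit <- vapply(pop, score, 0)
    gi <- which.min(fit)
    if (fit[[gi]] < best$rrse) best <- list(chrom = pop[[gi]], rrse = fit[[gi]])
    # memetic polish: a few hill-climbing proposals on the elite's constant
    # pools each generation (accepted only when RRSE improves)
    if (config$rnc_enabled && is.finite(best$rrse) && best$rrse > config$stop_rrse) {
      for (trial in 1:5) {
        cand <- best$chrom
        gi <- sample.int(length(cand$genes), 1)
        pool <- cand$genes[[gi]]$pool
        j <- sample.int(length(pool), 1)
        pool[j] <- min(max(pool[j] + stats::rnorm(1, 0, 0.2 * (1 + abs(pool[j]))),
                           config$rnc_range[1]), config$rnc_range[2])
        cand$genes[[gi]]$pool <- pool
        fc <- score(cand)
        if (fc < best$rrse) best <- list(chrom = cand, rrse = fc)
      }
    }
    trace <- c(trace, best$rrse)
    if (best$rrse < config$stop_rrse) break
  }
  model <- decode_chromosome(best$chrom, fs)
  if (config$gene_ols) {
    f <- ols_fit(best$chrom)
    if (!is.null(f)) {
      terms <- lapply(seq_along(best$chrom$genes), function(i)
        call("*", unname(f$beta[i + 1]),
             decode_gene(best$chrom$genes[[i]], fs)$expr))
      expr <- Reduce(function(a, b) call("+", a, b), terms,
                     init = unname(f$beta[1]))
      model <- model_expression(expr, provenance = "fitted")
    }
  } else if (config$linear_scaling) {
    pred <- as.numeric(eval(model$expr, env_data))
    if (length(pred) == 1L) pred <- rep(pred, nrow(X))
    vp <- stats::var(pred)
    b <- if (is.finite(vp) && vp > 1e-300) stats::cov(responses, pred) / vp else 0
    a <- mean(responses) - b * mean(pred)
    model <- model_expression(call("+", a, call("*", b, model$expr)),
                              provenance = "fitted")
  }
  list(model = model, rrse = best$rrse, trace = trace, chromosome = best$chrom)
}
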