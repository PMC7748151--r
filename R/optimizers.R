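# Evolutionary optimizers over surrogate media models: a real-coded
# mono-objective GA, NSGA-II (the multi-objective GA), and MOPSO with an
# external crowding-pruned archive.

#' Define an optimization problem over surrogate models
#'
#' @param models List of objective functions; each is a `model_expression`,
#'   an `m5_ruleset`/`m5_node`, or a plain R function of a numeric vector.
#' @param directions Character vector, `"max"` or `"min"` per objective.
#'   The pear problem maximizes PR, SL, QI and minimizes STN and Vitri.
#' @param bounds 2-row matrix (or list of length-2 vectors): per-factor
#'   lower/upper bounds in actual units.
#' @param names Optional factor names.
#' @return An `optimization_problem`.
#' @export
optimization_problem <- function(models, directions, bounds, names = NULL) {
  if (!is.list(models) ||
      inherits(models, c("model_expression", "m5_ruleset", "m5_node")))
    models <- list(models)
  directions <- match.arg(directions, c("max", "min"), several.ok = TRUE)
  if (length(directions) != length(models))
    stop("one direction per objective required")
  if (is.list(bounds)) bounds <- do.call(cbind, bounds)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2) stop("bounds must have rows lower, upper")
  if (any(bounds[1, ] > bounds[2, ])) stop("need lower <= upper bounds")
  if (!is.null(names)) colnames(bounds) <- names
  structure(list(models = models, directions = directions, bounds = bounds),
            class = "optimization_problem")
}

#' Factor bounds of the pear experiments
#'
#' The experimental ranges: KNO3 and NH4NO3 0.5--2 xMS, Mesos 0.5--2.5 xMS,
#' Micros 0.5--4 xMS, BA 0.5--3 mg/l, IBA 0.05--0.2 mg/l, in the input-letter
#' order of the published equations (A = NH4NO3, ..., F = IBA).
#'
#' @param iba_low Lower IBA bound; the published multi-objective media list
#'   IBA 0.02, below the experimental 0.05, so reproduction runs widen this.
#' @return 2 x 6 bounds matrix.
#' @export
pear_bounds <- function(iba_low = 0.05) {
  m <- rbind(lower = c(0.5, 0.5, 0.5, 0.5, 0.5, iba_low),
             upper = c(2,   2,   2.5, 4,   3,   0.2))
  colnames(m) <- c("NH4NO3", "KNO3", "Mesos", "Micros", "BA", "IBA")
  m
}

.evaluate_objectives <- function(problem, x) {
  nm <- colnames(problem$bounds)
  vapply(problem$models, function(m) {
    if (is.function(m)) m(x)
    else if (inherits(m, "model_expression"))
      evaluate_expression(m, stats::setNames(x, m$vars[seq_along(x)]))
    else predict_m5(m, stats::setNames(x, if (!is.null(nm)) nm else
      LETTERS[seq_along(x)]))
  }, 0)
}

# apply a vector-to-vector function over rows, keeping matrix shape for d = 1
.row_apply <- function(m, f) {
  out <- apply(m, 1, f)
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}

.init_pop <- function(n, lo, hi) {
  d <- length(lo)
  sweep(sweep(matrix(stats::runif(n * d), n, d), 2, hi - lo, "*"),
        2, lo, "+")
}

# objective vector on a "minimize everything" scale
.as_min <- function(obj, directions) {
  ifelse(directions == "max", -obj, obj)
}

#' Pareto dominance
#'
#' `a` dominates `b` when, after orienting every objective, `a` is no worse
#' everywhere and strictly better somewhere.
#'
#' @param a,b Objective vectors of equal length.
#' @param directions `"max"`/`"min"` per objective.
#' @return Logical.
#' @export
dominates <- function(a, b, directions = rep("min", length(a))) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  am <- .as_min(a, directions); bm <- .as_min(b, directions)
  all(am <= bm) && any(am < bm)
}

#' Mono-objective real-coded genetic algorithm
#'
#' Tournament selection, blend crossover and gaussian mutation with
#' reflection at the box bounds; returns the best solution ever evaluated.
#'
#' @param problem Single-objective [optimization_problem()].
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate,mutation_sd Operator settings
#'   (`mutation_sd` is relative to each factor's range).
#' @param seed Optional seed.
#' @return List with `par` (best position), `value` (best objective value on
#'   the problem's own scale) and `trace`.
#' @export
ga_optimize <- function(problem, pop_size = 100, generations = 250,
                        crossover_rate = 0.9, mutation_rate = 0.15,
                        mutation_sd = 0.1, seed = NULL) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (length(problem$models) != 1)
    stop("ga_optimize requires exactly one objective")
  if (!is.null(seed)) set.seed(seed)
  lo <- problem$bounds[1, ]; hi <- problem$bounds[2, ]
  d <- length(lo); rng <- hi - lo
  sgn <- if (problem$directions[1] == "max") -1 else 1
  f <- function(x) sgn * .evaluate_objectives(problem, x)[1]

  pop <- .init_pop(pop_size, lo, hi)
  fit <- apply(pop, 1, f)
  best_i <- which.min(fit)
  best <- list(par = pop[best_i, ], value = fit[best_i])
  trace <- numeric(0)
  reflect <- function(x) {
    for (rep_ in 1:3) {
      x <- ifelse(x < lo, 2 * lo - x, x)
      x <- ifelse(x > hi, 2 * hi - x, x)
    }
    pmin(pmax(x, lo), hi)
  }
  for (gen in seq_len(generations)) {
    idx <- matrix(sample.int(pop_size, 2 * pop_size, replace = TRUE), ncol = 2)
    parents <- ifelse(fit[idx[, 1]] <= fit[idx[, 2]], idx[, 1], idx[, 2])
    newpop <- pop[parents, , drop = FALSE]
    for (i in seq(1, pop_size - 1, by = 2)) {
      if (stats::runif(1) < crossover_rate) {
        a <- stats::runif(d, -0.1, 1.1)  # blend-alpha crossover
        p1 <- newpop[i, ]; p2 <- newpop[i + 1, ]
        newpop[i, ]     <- reflect(a * p1 + (1 - a) * p2)
        newpop[i + 1, ] <- reflect(a * p2 + (1 - a) * p1)
      }
    }
    mut <- matrix(stats::runif(pop_size * d) < mutation_rate, pop_size, d)
    noise <- matrix(stats::rnorm(pop_size * d, 0, 1), pop_size, d) *
      rep(rng * mutation_sd, each = pop_size)
    newpop[mut] <- newpop[mut] + noise[mut]
    newpop <- .row_apply(newpop, reflect)
    newpop[1, ] <- best$par  # elitism
    pop <- newpop
    fit <- apply(pop, 1, f)
    gi <- which.min(fit)
    if (fit[gi] < best$value) best <- list(par = pop[gi, ], value = fit[gi])
    # elite polish: shrinking gaussian probes around the incumbent keep the
    # final iterate converging once the basin is found
    sdg <- 0.1 * exp(-3 * gen / generations)
    for (probe in 1:4) {
      # clamped probes so boundary optima are reachable exactly
      cand <- pmin(pmax(best$par + stats::rnorm(d, 0, sdg * rng), lo), hi)
      fc <- f(cand)
      if (fc < best$value) best <- list(par = cand, value = fc)
    }
    trace <- c(trace, sgn * best$value)
  }
  list(par = stats::setNames(best$par, colnames(problem$bounds)),
       value = sgn * best$value, trace = trace)
}

# -- Pareto archive -----------------------------------------------------------

#' Bounded non-dominated archive
#'
#' @param capacity Maximum number of members; crowding-distance pruning keeps
#'   the archive spread once full.
#' @param directions Objective directions.
#' @return An environment-backed `pareto_archive`.
#' @export
pareto_archive <- function(capacity = 100, directions) {
  if (capacity < 1) stop("archive capacity must be >= 1")
  a <- new.env()
  a$X <- NULL; a$FF <- NULL
  a$capacity <- capacity; a$directions <- directions
  class(a) <- "pareto_archive"
  a
}

.crowding_distance <- function(FF) {
  n <- nrow(FF); m <- ncol(FF)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (j in seq_len(m)) {
    o <- order(FF[, j])
    rng <- FF[o[n], j] - FF[o[1], j]
    dist[o[c(1, n)]] <- Inf
    if (rng > 0)
      dist[o[2:(n - 1)]] <- dist[o[2:(n - 1)]] +
        (FF[o[3:n], j] - FF[o[1:(n - 2)], j]) / rng
  }
  dist
}

#' Insert a candidate into a Pareto archive
#'
#' Dominated candidates leave the archive unchanged; an accepted candidate
#' evicts the members it dominates, and when capacity is exceeded the most
#' crowded member is dropped.
#'
#' @param archive A [pareto_archive()].
#' @param x Position vector.
#' @param obj Objective vector.
#' @return TRUE (invisibly) if the candidate was admitted.
#' @export
archive_insert <- function(archive, x, obj) {
  dirs <- archive$directions
  if (!is.null(archive$FF)) {
    dominated_by_existing <- any(apply(archive$FF, 1, function(f)
      dominates(f, obj, dirs) || all(f == obj)))
    if (dominated_by_existing) return(invisible(FALSE))
    keep <- !apply(archive$FF, 1, function(f) dominates(obj, f, dirs))
    archive$X <- archive$X[keep, , drop = FALSE]
    archive$FF <- archive$FF[keep, , drop = FALSE]
  }
  archive$X <- rbind(archive$X, x)
  archive$FF <- rbind(archive$FF, obj)
  if (nrow(archive$FF) > archive$capacity) {
    cd <- .crowding_distance(.as_min(archive$FF, matrix(dirs,
            nrow(archive$FF), length(dirs), byrow = TRUE)))
    drop_i <- which.min(cd)
    archive$X <- archive$X[-drop_i, , drop = FALSE]
    archive$FF <- archive$FF[-drop_i, , drop = FALSE]
  }
  invisible(TRUE)
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive> %d members (capacity %d)\n",
              if (is.null(x$FF)) 0L else nrow(x$FF), x$capacity))
  invisible(x)
}

#' Archive contents as a data frame
#' @param archive A `pareto_archive`.
#' @return Data frame of positions and objective values.
#' @export
archive_as_df <- function(archive) {
  X <- archive$X; FF <- archive$FF
  colnames(FF) <- paste0("obj", seq_len(ncol(FF)))
  data.frame(X, FF, check.names = FALSE)
}

# -- PSO ----------------------------------------------------------------------

#' One particle-swarm velocity/position update
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; `x' = x + v'`, then
#' clamped to the bounds with the velocity zeroed at clamped coordinates.
#'
#' @param particle List with `x`, `v`, `pbest`.
#' @param gbest Leader position.
#' @param bounds 2-row bounds matrix.
#' @param w,c1,c2 Inertia (0.8--1.2), cognitive and social coefficients
#'   (0--2).
#' @param r1,r2 Optional fixed random factors in \[0, 1\] (drawn uniformly
#'   when NULL); exposed for deterministic testing.
#' @return Updated particle.
#' @export
pso_update <- function(particle, gbest, bounds, w = 0.9, c1 = 2, c2 = 2,
                       r1 = NULL, r2 = NULL) {
  if (w < 0.8 - 1e-9 || w > 1.2 + 1e-9) stop("inertia w outside [0.8, 1.2]")
  if (any(c(c1, c2) < 0) || any(c(c1, c2) > 2)) stop("c1, c2 outside [0, 2]")
  d <- length(particle$x)
  if (is.null(r1)) r1 <- stats::runif(d)
  if (is.null(r2)) r2 <- stats::runif(d)
  v <- w * particle$v + c1 * r1 * (particle$pbest - particle$x) +
    c2 * r2 * (gbest - particle$x)
  x <- particle$x + v
  lo <- bounds[1, ]; hi <- bounds[2, ]
  clamped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clamped] <- 0
  particle$x <- x; particle$v <- v
  particle
}

#' Multi-objective particle swarm optimization
#'
#' Swarm plus external non-dominated archive; leaders are drawn from the
#' low-density (high crowding-distance) region of the archive, and the
#' archive is crowding-pruned at capacity. Personal bests are replaced when
#' dominated (random tie-break on incomparability).
#'
#' @param problem Multi-objective [optimization_problem()].
#' @param swarm_size,iterations Swarm settings.
#' @param w,c1,c2 PSO coefficients.
#' @param capacity Archive capacity.
#' @param seed Optional seed.
#' @return The final `pareto_archive`.
#' @export
mopso_optimize <- function(problem, swarm_size = 100, iterations = 250,
                           w = 0.9, c1 = 2, c2 = 2, capacity = 100,
                           seed = NULL) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (length(problem$models) < 2) stop("mopso_optimize needs >= 2 objectives")
  if (!is.null(seed)) set.seed(seed)
  lo <- problem$bounds[1, ]; hi <- problem$bounds[2, ]
  d <- length(lo); dirs <- problem$directions
  arch <- pareto_archive(capacity, dirs)
  particles <- lapply(seq_len(swarm_size), function(i) {
    x <- lo + stats::runif(d) * (hi - lo)
    obj <- .evaluate_objectives(problem, x)
    archive_insert(arch, x, obj)
    list(x = x, v = stats::runif(d, -1, 1) * (hi - lo) * 0.1,
         pbest = x, pobj = obj)
  })
  pick_leader <- function() {
    n <- nrow(arch$FF)
    if (n == 1) return(arch$X[1, ])
    cd <- .crowding_distance(.as_min(arch$FF,
            matrix(dirs, n, length(dirs), byrow = TRUE)))
    cand <- sample.int(n, min(2, n))
    arch$X[cand[which.max(cd[cand])], ]
  }
  for (it in seq_len(iterations)) {
    for (i in seq_along(particles)) {
      p <- particles[[i]]
      p <- pso_update(p, pick_leader(), problem$bounds, w, c1, c2)
      obj <- .evaluate_objectives(problem, p$x)
      archive_insert(arch, p$x, obj)
      if (dominates(obj, p$pobj, dirs) ||
          (!dominates(p$pobj, obj, dirs) && stats::runif(1) < 0.5)) {
        p$pbest <- p$x; p$pobj <- obj
      }
      particles[[i]] <- p
    }
  }
  arch
}

# -- NSGA-II ------------------------------------------------------------------

.nd_sort <- function(FF) {
  n <- nrow(FF)
  dominated_count <- integer(n)
  dominates_list <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(FF[i, ] <= FF[j, ]) && any(FF[i, ] < FF[j, ]))
        dominates_list[[i]] <- c(dominates_list[[i]], j)
      else if (all(FF[j, ] <= FF[i, ]) && any(FF[j, ] < FF[i, ]))
        dominated_count[i] <- dominated_count[i] + 1L
    }
  }
  fronts <- list(); rank <- integer(n)
  current <- which(dominated_count == 0L)
  f <- 1L
  while (length(current)) {
    fronts[[f]] <- current; rank[current] <- f
    nxt <- integer(0)
    for (i in current) for (j in dominates_list[[i]]) {
      dominated_count[j] <- dominated_count[j] - 1L
      if (dominated_count[j] == 0L) nxt <- c(nxt, j)
    }
    current <- nxt; f <- f + 1L
  }
  list(fronts = fronts, rank = rank)
}

#' NSGA-II multi-objective genetic algorithm
#'
#' Real-coded NSGA-II: fast non-dominated sorting with crowding-distance
#' selection, blend crossover and gaussian mutation with reflection at the
#' bounds. Returns the first front of the final population as an archive.
#'
#' @inheritParams ga_optimize
#' @param problem An [optimization_problem()] (one objective degenerates to
#'   elitist mono-objective selection).
#' @param capacity Archive capacity for the returned front.
#' @return A `pareto_archive` holding the final non-dominated set.
#' @export
nsga2_optimize <- function(problem, pop_size = 100, generations = 250,
                           crossover_rate = 0.9, mutation_rate = 0.15,
                           mutation_sd = 0.1, capacity = 100, seed = NULL) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (!is.null(seed)) set.seed(seed)
  lo <- problem$bounds[1, ]; hi <- problem$bounds[2, ]
  d <- length(lo); rng <- hi - lo; dirs <- problem$directions
  reflect <- function(x) {
    for (rep_ in 1:3) {
      x <- ifelse(x < lo, 2 * lo - x, x)
      x <- ifelse(x > hi, 2 * hi - x, x)
    }
    pmin(pmax(x, lo), hi)
  }
  evalm <- function(X) {
    out <- apply(X, 1, function(x)
      .as_min(.evaluate_objectives(problem, x), dirs))
    if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
  }
  pop <- .init_pop(pop_size, lo, hi)
  FF <- evalm(pop)
  for (gen in seq_len(generations)) {
    ns <- .nd_sort(FF); cd <- numeric(nrow(FF))
    for (fr in ns$fronts) cd[fr] <- .crowding_distance(FF[fr, , drop = FALSE])
    tour <- function() {
      ij <- sample.int(nrow(pop), 2)
      i <- ij[1]; j <- ij[2]
      if (ns$rank[i] < ns$rank[j] ||
          (ns$rank[i] == ns$rank[j] && cd[i] > cd[j])) i else j
    }
    child <- matrix(0, pop_size, d)
    for (i in seq(1, pop_size - 1, by = 2)) {
      p1 <- pop[tour(), ]; p2 <- pop[tour(), ]
      if (stats::runif(1) < crossover_rate) {
        a <- stats::runif(d, -0.1, 1.1)
        c1 <- a * p1 + (1 - a) * p2; c2 <- a * p2 + (1 - a) * p1
      } else { c1 <- p1; c2 <- p2 }
      child[i, ] <- c1; child[i + 1, ] <- c2
    }
    if (pop_size %% 2 == 1) child[pop_size, ] <- pop[tour(), ]
    mut <- matrix(stats::runif(pop_size * d) < mutation_rate, pop_size, d)
    noise <- matrix(stats::rnorm(pop_size * d), pop_size, d) *
      rep(rng * mutation_sd, each = pop_size)
    child[mut] <- child[mut] + noise[mut]
    child <- .row_apply(child, reflect)
    allX <- rbind(pop, child); allF <- rbind(FF, evalm(child))
    ns <- .nd_sort(allF)
    keep <- integer(0)
    for (fr in ns$fronts) {
      if (length(keep) + length(fr) <= pop_size) keep <- c(keep, fr)
      else {
        cd <- .crowding_distance(allF[fr, , drop = FALSE])
        keep <- c(keep, fr[order(-cd)][seq_len(pop_size - length(keep))])
        break
      }
    }
    pop <- allX[keep, , drop = FALSE]; FF <- allF[keep, , drop = FALSE]
  }
  arch <- pareto_archive(capacity, dirs)
  first <- .nd_sort(FF)$fronts[[1]]
  for (i in first) {
    obj <- .evaluate_objectives(problem, pop[i, ])
    archive_insert(arch, pop[i, ], obj)
  }
  arch
}

#' Pick one representative medium from a Pareto archive
#'
#' Scores every member by the weighted sum of its direction-normalized,
#' min-max-scaled objectives and returns the maximizer (deterministic given
#' archive order). This is the documented stand-in for the unspecified rule
#' by which a single published medium was drawn from each method's front.
#'
#' @param archive A `pareto_archive`.
#' @param weights Non-negative per-objective weights (not all zero).
#' @return List with `par` and `objectives`.
#' @export
select_representative <- function(archive,
                                  weights = rep(1, length(archive$directions))) {
  if (is.null(archive$FF) || nrow(archive$FF) == 0) stop("empty archive")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative, not all zero")
  FF <- archive$FF
  score <- rep(0, nrow(FF))
  for (j in seq_len(ncol(FF))) {
    v <- FF[, j]
    if (archive$directions[j] == "min") v <- -v
    rngj <- diff(range(v))
    vs <- if (rngj == 0) rep(0.5, length(v)) else (v - min(v)) / rngj
    score <- score + weights[j] * vs
  }
  i <- which.max(score)
  list(par = archive$X[i, ], objectives = archive$FF[i, ])
}

# 2-D hypervolume (minimization) w.r.t. a reference point; used by the
# benchmark tests against fronts with a closed-form Pareto set.
.hypervolume2d <- function(FF, ref) {
  FF <- FF[FF[, 1] <= ref[1] & FF[, 2] <= ref[2], , drop = FALSE]
  if (!nrow(FF)) return(0)
  o <- order(FF[, 1], FF[, 2])
  FF <- FF[o, , drop = FALSE]
  hv <- 0; y_prev <- ref[2]
  for (i in seq_len(nrow(FF))) {
    if (FF[i, 2] < y_prev) {
      hv <- hv + (ref[1] - FF[i, 1]) * (y_prev - FF[i, 2])
      y_prev <- FF[i, 2]
    }
  }
  hv
}
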