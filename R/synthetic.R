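# Synthetic Box-Behnken datasets with known ground truth, so every pipeline
# stage (surrogate fitting, Gamma ranking, optimization) can be validated
# end to end without any experimental data.

#' Define a smooth truth surface over the six medium factors
#'
#' A truth surface is a quadratic response-surface polynomial (intercept,
#' linear, quadratic and pairwise-interaction coefficients) over the design
#' factors, optionally clipped to an output range, with declared-irrelevant
#' factors whose coefficients are exactly zero. The `"pear-like"` preset
#' draws five such surfaces with magnitudes matching the five explant
#' responses (proliferation rate about 0--13 shoots, shoot length 0--10 cm,
#' quality 0--5, necrosis and hyperhydricity percentages 0--100).
#'
#' @param preset `"pear-like"` or `NULL` to pass an explicit `spec`.
#' @param spec Optional list with elements `intercept`, `linear` (length d),
#'   `quadratic` (length d), `interactions` (d x d upper-triangular matrix or
#'   NULL), `clip` (length-2 range or NULL), `irrelevant` (integer indices).
#' @param n_factors Number of factors (default 6).
#' @param seed Integer seed used to draw preset coefficients.
#' @return A `truth_surface` (for presets, a list of five).
#' @export
make_truth_surface <- function(preset = NULL, spec = NULL, n_factors = 6,
                               seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "pear-like")
    set.seed(seed)
    ranges <- list(PR = c(0, 13), SL = c(0, 10), QI = c(0, 5),
                   STN = c(0, 100), Vitri = c(0, 100))
    out <- lapply(names(ranges), function(nm) {
      r <- ranges[[nm]]
      amp <- diff(r)
      # effect sparsity, the standard response-surface assumption: three
      # active main effects, two curvatures, one two-factor interaction
      active <- sample(n_factors, 3)
      linear <- numeric(n_factors)
      linear[active] <- stats::runif(3, 0.08, 0.18) * amp *
        sample(c(-1, 1), 3, replace = TRUE)
      quadratic <- numeric(n_factors)
      quadratic[active[1:2]] <- stats::runif(2, -0.1, -0.03) * amp
      inter <- matrix(0, n_factors, n_factors)
      inter[active[1], active[2]] <- stats::runif(1, -0.06, 0.06) * amp
      .truth_surface(
        intercept = r[1] + 0.5 * amp,
        linear = linear, quadratic = quadratic,
        interactions = inter, clip = r, irrelevant = integer(0),
        name = nm)
    })
    names(out) <- names(ranges)
    return(out)
  }
  if (is.null(spec)) stop("either a preset or a spec must be given")
  need <- c("intercept", "linear", "quadratic")
  if (!all(need %in% names(spec)))
    stop("spec must contain intercept, linear and quadratic coefficients")
  .truth_surface(spec$intercept, spec$linear, spec$quadratic,
                 spec$interactions, spec$clip,
                 as.integer(spec$irrelevant %||% integer(0)),
                 spec$name %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.truth_surface <- function(intercept, linear, quadratic, interactions = NULL,
                           clip = NULL, irrelevant = integer(0),
                           name = "surface") {
  d <- length(linear)
  if (length(quadratic) != d) stop("linear and quadratic lengths differ")
  if (is.null(interactions)) interactions <- matrix(0, d, d)
  linear[irrelevant] <- 0
  quadratic[irrelevant] <- 0
  interactions[irrelevant, ] <- 0
  interactions[, irrelevant] <- 0
  structure(list(intercept = intercept, linear = linear,
                 quadratic = quadratic, interactions = interactions,
                 clip = clip, irrelevant = irrelevant, name = name),
            class = "truth_surface")
}

#' Evaluate a truth surface
#'
#' Coded units are the natural scale for the polynomial; a `design_table` is
#' evaluated on its coded runs. Clipping is applied (percentages cannot
#' leave \[0, 100\]).
#'
#' @param surface A `truth_surface`.
#' @param x Matrix of rows in coded units, or a `design_table`.
#' @return Numeric vector of surface values.
#' @export
surface_values <- function(surface, x) {
  if (inherits(x, "design_table")) x <- x$codes
  x <- as.matrix(x)
  v <- surface$intercept +
    drop(x %*% surface$linear) +
    drop((x^2) %*% surface$quadratic) +
    vapply(seq_len(nrow(x)), function(i)
      drop(t(x[i, ]) %*% surface$interactions %*% x[i, ]), 0)
  if (!is.null(surface$clip)) v <- pmin(pmax(v, surface$clip[1]),
                                        surface$clip[2])
  v
}

#' Simulate replicated responses on a design
#'
#' Responses are the clipped surface values plus independent gaussian
#' replicate noise (treatment means over ten or more replicates are close to
#' normal, which is what the real tables record). Per-treatment means are
#' returned alongside the replicate-level values.
#'
#' @param design A `design_table`.
#' @param surface A `truth_surface` or list of them (multi-output).
#' @param noise_sd Noise standard deviation per output (recycled).
#' @param replicates Replicates per treatment (>= 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `synthetic_dataset`: list with `design`, `truth` (clipped
#'   surface values per output), `replicates` (long data frame), `means`
#'   (treatment-mean matrix), `noise_sd`, `seed`.
#' @export
simulate_responses <- function(design, surface, noise_sd = 0, replicates = 1,
                               seed = 1) {
  stopifnot(inherits(design, "design_table"))
  if (inherits(surface, "truth_surface")) surface <- list(surface)
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  noise_sd <- rep(noise_sd, length.out = length(surface))
  set.seed(seed)
  n <- nrow(design$codes)
  truth <- vapply(surface, surface_values, numeric(n), x = design)
  nm <- vapply(seq_along(surface), function(i)
    surface[[i]]$name %||% paste0("y", i), "")
  colnames(truth) <- nm
  reps <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    vals <- truth + matrix(stats::rnorm(n * length(surface), 0,
                                        rep(noise_sd, each = n)),
                           n, length(surface))
    data.frame(run_id = seq_len(n), replicate = r, vals,
               check.names = FALSE)
  }))
  means <- as.matrix(stats::aggregate(reps[nm], list(run_id = reps$run_id),
                                      mean)[nm])
  structure(list(design = design, truth = truth, replicates = reps,
                 means = means, noise_sd = noise_sd, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d runs x %d outputs, %d replicate(s), seed %d\n",
              nrow(x$means), ncol(x$means),
              max(x$replicates$replicate), x$seed))
  invisible(x)
}

#' Write a synthetic dataset in the shared CSV schema
#'
#' Design columns (coded), actual-unit columns, one column per output and an
#' optional replicate column: the same schema used for transcribed
#' experimental tables, so the two are interchangeable.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output CSV path.
#' @param means Write treatment means (default) or replicate-level rows?
#' @export
write_dataset_csv <- function(dataset, path, means = TRUE) {
  d <- dataset$design
  base <- data.frame(run_id = seq_len(nrow(d$codes)), d$codes,
                     check.names = FALSE)
  act <- design_actual(d)
  colnames(act) <- paste0(colnames(act), "_actual")
  if (means) {
    df <- cbind(base, act, dataset$means)
  } else {
    df <- merge(cbind(base, act), dataset$replicates, by = "run_id")
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
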