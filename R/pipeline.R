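# Pipeline configuration and orchestration: design -> simulate/load ->
# fit (GEP and/or M5') -> Gamma ranking -> optimization -> reports, with a
# single global seed fanned out to per-stage streams so any stage can be
# re-run reproducibly in isolation.

#' Assemble a pipeline run configuration
#'
#' @param seed Global integer seed; each stochastic stage derives its own
#'   child seed from it, so no stage reads ambient randomness.
#' @param out_dir Output directory for run artifacts.
#' @param data_csv Optional input CSV (design + response columns); when NULL
#'   a synthetic pear-like dataset is generated.
#' @param responses Response column names to model.
#' @param fit GEP, M5, or both.
#' @param gep,m5 Stage configurations ([gep_config()], [m5_config()]).
#' @param gamma_p Near-neighbour count for the Gamma test.
#' @param optimizer `"mono"` (GA per response), `"moga"` (NSGA-II) or
#'   `"mopso"`.
#' @param directions Per-response optimization directions.
#' @param bounds Factor bounds (defaults to the pear experimental ranges).
#' @param noise_sd,replicates Synthetic-data settings (used when `data_csv`
#'   is NULL).
#' @param opt_pop,opt_iter Population/swarm size and iteration count for the
#'   optimization stage.
#' @param verbose Print stage progress?
#' @return A `run_config` list, serializable to JSON via [write_config()].
#' @export
run_config <- function(seed = 1, out_dir = "vitropt-run", data_csv = NULL,
                       responses = c("PR", "SL", "QI", "STN", "Vitri"),
                       fit = c("gep", "m5"), gep = gep_config(),
                       m5 = m5_config(), gamma_p = 10,
                       optimizer = c("mopso", "moga", "mono"),
                       directions = NULL, bounds = NULL,
                       noise_sd = 0.5, replicates = 10,
                       opt_pop = 100, opt_iter = 250, verbose = TRUE) {
  fit <- match.arg(fit, several.ok = TRUE)
  optimizer <- match.arg(optimizer)
  if (is.null(directions))
    directions <- stats::setNames(
      ifelse(responses %in% c("STN", "Vitri"), "min", "max"), responses)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 data_csv = data_csv, responses = responses, fit = fit,
                 gep = gep, m5 = m5, gamma_p = gamma_p,
                 optimizer = optimizer, directions = directions,
                 bounds = bounds, noise_sd = noise_sd,
                 replicates = replicates, opt_pop = opt_pop,
                 opt_iter = opt_iter, verbose = verbose),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(seed = raw$seed %||% 1)
  for (nm in names(raw)) {
    if (nm %in% c("gep", "m5")) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

# deterministic per-stage child seeds below 2^31
.child_seed <- function(seed, stage) {
  (seed * 48271 + sum(utf8ToInt(stage)) * 7919) %% 2147483647L
}

#' Run the full modelling-and-optimization pipeline
#'
#' Executes design generation, data simulation (or loading), surrogate
#' fitting, Gamma-test input ranking and evolutionary optimization, writing
#' all artifacts (CSV tables, model text files, the resolved configuration
#' and seeds) under `config$out_dir`. Re-running with an identical
#' configuration and seed reproduces every numeric output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted models, gamma rankings, and the
#'   optimization result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message("[vitropt] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage: design + data
  design <- generate_bbd(6)
  if (is.null(config$data_csv)) {
    say("simulating pear-like dataset (seed ",
        .child_seed(config$seed, "simulate"), ")")
    surfaces <- make_truth_surface("pear-like",
                                   seed = .child_seed(config$seed, "surface"))
    surfaces <- surfaces[config$responses]
    ds <- simulate_responses(design, surfaces, noise_sd = config$noise_sd,
                             replicates = config$replicates,
                             seed = .child_seed(config$seed, "simulate"))
    X <- design_actual(design)
    Y <- ds$means
    write_dataset_csv(ds, file.path(config$out_dir, "dataset.csv"))
  } else {
    if (!file.exists(config$data_csv))
      stop("input data file does not exist: ", config$data_csv)
    df <- utils::read.csv(config$data_csv, check.names = FALSE)
    miss <- setdiff(config$responses, names(df))
    if (length(miss))
      stop("input data is missing response columns: ",
           paste(miss, collapse = ", "))
    act_cols <- grep("_actual$", names(df), value = TRUE)
    if (length(act_cols) >= 6) {
      X <- as.matrix(df[act_cols[1:6]])
      colnames(X) <- sub("_actual$", "", act_cols[1:6])
    } else {
      fac <- setdiff(names(df), c("run_id", "replicate", config$responses))
      X <- as.matrix(df[fac[1:6]])
    }
    Y <- as.matrix(df[config$responses])
  }

  # stage: surrogate fitting
  models <- list()
  for (resp in config$responses) {
    if ("gep" %in% config$fit) {
      say("fitting GEP surrogate for ", resp)
      fitg <- fit_gep(X, Y[, resp], config$gep,
                      seed = .child_seed(config$seed, paste0("gep-", resp)))
      models[[paste0(resp, ".gep")]] <- fitg$model
      write_model_text(fitg$model,
                       file.path(config$out_dir, paste0(resp, "_gep.txt")),
                       metadata = list(response = resp, rrse = fitg$rrse))
    }
    if ("m5" %in% config$fit) {
      say("fitting M5' tree for ", resp)
      tree <- build_m5(X, Y[, resp], config$m5)
      models[[paste0(resp, ".m5")]] <- tree
      write_ruleset_text(m5_to_ruleset(tree),
                         file.path(config$out_dir, paste0(resp, "_m5.txt")))
    }
  }

  # stage: Gamma-test input ranking
  rankings <- list()
  for (resp in config$responses) {
    # designed runs project onto duplicate rows once a factor is masked out,
    # so deterministic tie-breaking is required here
    scan <- mask_scan(X, Y[, resp], loo_masks(ncol(X)), p = config$gamma_p,
                      allow_ties = TRUE)
    rankings[[resp]] <- rank_inputs(scan, colnames(X))
    write_gamma_report(scan,
                       file.path(config$out_dir, paste0(resp, "_gamma.csv")),
                       colnames(X))
  }

  # stage: optimization over the fitted surrogates
  kind <- if ("gep" %in% config$fit) "gep" else "m5"
  objs <- lapply(config$responses, function(r) models[[paste0(r, ".", kind)]])
  bounds <- config$bounds
  if (is.null(bounds)) {
    bounds <- pear_bounds()
    colnames(bounds) <- colnames(X)
  }
  problem <- optimization_problem(objs, unname(config$directions[config$responses]),
                                  bounds, names = colnames(X))
  opt_seed <- .child_seed(config$seed, "optimize")
  say("optimizing (", config$optimizer, ", seed ", opt_seed, ")")
  result <- switch(config$optimizer,
    mono = {
      per <- lapply(seq_along(objs), function(i) {
        p1 <- optimization_problem(objs[i],
                                   unname(config$directions[config$responses][i]),
                                   bounds, names = colnames(X))
        ga_optimize(p1, pop_size = config$opt_pop,
                    generations = config$opt_iter, seed = opt_seed + i)
      })
      names(per) <- config$responses
      per
    },
    moga = nsga2_optimize(problem, pop_size = config$opt_pop,
                          generations = config$opt_iter, seed = opt_seed),
    mopso = mopso_optimize(problem, swarm_size = config$opt_pop,
                           iterations = config$opt_iter, seed = opt_seed))

  if (config$optimizer %in% c("moga", "mopso")) {
    utils::write.csv(archive_as_df(result),
                     file.path(config$out_dir, "pareto_archive.csv"),
                     row.names = FALSE)
    rep_ <- select_representative(result)
    media <- data.frame(t(c(rep_$par, rep_$objectives)))
    names(media) <- c(colnames(X), config$responses)
  } else {
    media <- do.call(rbind, lapply(names(result), function(r)
      data.frame(response = r, value = result[[r]]$value,
                 t(result[[r]]$par))))
  }
  utils::write.csv(media, file.path(config$out_dir, "optimal_media.csv"),
                   row.names = FALSE)
  write_config(config, file.path(config$out_dir, "resolved_config.json"))
  say("artifacts written to ", config$out_dir)
  invisible(list(models = models, rankings = rankings, optimum = result,
                 media = media))
}
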