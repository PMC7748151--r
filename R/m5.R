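# M5' model trees: growth by standard-deviation reduction, bottom-up pruning
# against a complexity-penalized error estimate, and ordered If/Then rule
# sets with first-match evaluation (the export format used for the published
# pear models).

#' Standard deviation reduction of a partition
#'
#' `sd(T) - sum(|Ti|/|T| * sd(Ti))` over the blocks of a disjoint partition
#' of the parent's responses. Population (n-denominator) standard deviation
#' is used, as the splitting criterion carries no Bessel correction.
#'
#' @param parent Numeric response vector of the node.
#' @param partition List of numeric vectors covering `parent` disjointly.
#' @return The reduction (the maximizing single-attribute split has SDR >= 0).
#' @export
sdr <- function(parent, partition) {
  if (!length(parent)) stop("empty parent node")
  if (sum(lengths(partition)) != length(parent))
    stop("partition must cover the parent exactly")
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  psd(parent) - sum(vapply(partition, function(b)
    length(b) / length(parent) * psd(b), 0))
}

#' M5' induction configuration
#'
#' @param min_instances Minimum instances per leaf (>= 2); a node with fewer
#'   than `2 * min_instances` rows is not split.
#' @param sd_stop_fraction Stop splitting when a node's response sd falls
#'   below this fraction of the root sd.
#' @param pruning Prune bottom-up using the (n + v)/(n - v) penalized error?
#' @param smoothing Blend leaf predictions with ancestor models on the path?
#'   Off by default so exported rules equal the leaf models exactly.
#' @return An `m5_config` list.
#' @export
m5_config <- function(min_instances = 4, sd_stop_fraction = 0.05,
                      pruning = TRUE, smoothing = FALSE) {
  if (min_instances < 2) stop("min_instances must be >= 2")
  if (sd_stop_fraction <= 0 || sd_stop_fraction >= 1)
    stop("sd_stop_fraction must lie in (0, 1)")
  structure(list(min_instances = min_instances,
                 sd_stop_fraction = sd_stop_fraction,
                 pruning = pruning, smoothing = smoothing),
            class = "m5_config")
}

.psd <- function(x) sqrt(mean((x - mean(x))^2))

.leaf_model <- function(X, y) {
  # least-squares linear model over the attributes; constant-column safe
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (any(keep)) {
    fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    intercept <- b[1]
    coefs[colnames(X)[keep]] <- b[-1]
  } else intercept <- mean(y)
  list(intercept = unname(intercept), coefs = coefs)
}

.leaf_predict <- function(model, X) {
  drop(X %*% model$coefs) + model$intercept
}

.leaf_params <- function(model) 1 + sum(model$coefs != 0)

.best_split <- function(X, y, min_instances) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    u <- sort(unique(v))
    if (length(u) < 2) next
    thr <- (u[-1] + u[-length(u)]) / 2  # midpoints between adjacent values
    for (t in thr) {
      left <- v <= t
      if (sum(left) < min_instances || sum(!left) < min_instances) next
      s <- sdr(y, list(y[left], y[!left]))
      if (is.null(best) || s > best$sdr)
        best <- list(attribute = j, threshold = t, sdr = s)
    }
  }
  best
}

.grow_m5 <- function(X, y, config, root_sd) {
  n <- length(y)
  make_leaf <- function() {
    m <- .leaf_model(X, y)
    structure(list(type = "leaf", model = m, n = n,
                   resid = y - .leaf_predict(m, X)), class = "m5_node")
  }
  if (n < 2 * config$min_instances || .psd(y) < config$sd_stop_fraction * root_sd)
    return(make_leaf())
  sp <- .best_split(X, y, config$min_instances)
  if (is.null(sp) || sp$sdr <= 0) return(make_leaf())
  left <- X[, sp$attribute] <= sp$threshold
  structure(list(type = "split", attribute = sp$attribute,
                 attr_name = colnames(X)[sp$attribute],
                 threshold = sp$threshold, n = n,
                 left = .grow_m5(X[left, , drop = FALSE], y[left], config, root_sd),
                 right = .grow_m5(X[!left, , drop = FALSE], y[!left], config, root_sd)),
            class = "m5_node")
}

# complexity-penalized error estimate: mean |residual| * (n + v)/(n - v)
.node_error <- function(node, X, y) {
  pred <- predict_m5(node, X)
  v <- .n_params(node)
  n <- length(y)
  mean(abs(y - pred)) * if (n > v) (n + v) / (n - v) else 1e6
}

.n_params <- function(node) {
  if (node$type == "leaf") return(.leaf_params(node$model))
  1 + .n_params(node$left) + .n_params(node$right)
}

.prune_m5 <- function(node, X, y) {
  if (node$type == "leaf") return(node)
  left <- X[, node$attribute] <= node$threshold
  node$left  <- .prune_m5(node$left,  X[left, , drop = FALSE], y[left])
  node$right <- .prune_m5(node$right, X[!left, , drop = FALSE], y[!left])
  leaf <- structure(list(type = "leaf", model = .leaf_model(X, y),
                         n = length(y)), class = "m5_node")
  # ties (to numerical precision) favour the simpler model
  le <- .node_error(leaf, X, y); ne <- .node_error(node, X, y)
  if (le <= ne * (1 + 1e-8) + 1e-12) leaf else node
}

#' Induce an M5' model tree
#'
#' Grows a binary regression tree by choosing, at every node, the
#' attribute/threshold split maximizing the standard deviation reduction of
#' the responses, stopping on small nodes or near-constant responses; then
#' (optionally) prunes bottom-up, replacing a subtree by a linear model
#' whenever the complexity-penalized error estimate
#' `err * (n + v)/(n - v)` does not increase.
#'
#' @param X Numeric attribute matrix (or data.frame).
#' @param y Numeric response vector.
#' @param config An [m5_config()].
#' @return The root `m5_node`.
#' @export
build_m5 <- function(X, y, config = m5_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- LETTERS[seq_len(ncol(X))]
  blank <- !nzchar(colnames(X))
  colnames(X)[blank] <- LETTERS[seq_len(ncol(X))][blank]
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 2 * config$min_instances)
    stop("insufficient data: need at least ", 2 * config$min_instances, " rows")
  root <- .grow_m5(X, y, config, root_sd = .psd(y))
  if (config$pruning) root <- .prune_m5(root, X, y)
  root
}

#' @export
print.m5_node <- function(x, indent = "", ...) {
  if (x$type == "leaf") {
    terms <- x$model$coefs[x$model$coefs != 0]
    rhs <- paste(c(sprintf("%.4g*%s", terms, names(terms)),
                   sprintf("%.4g", x$model$intercept)), collapse = " + ")
    cat(indent, "LM: y = ", rhs, "  (n=", x$n, ")\n", sep = "")
  } else {
    cat(indent, x$attr_name, " <= ", format(x$threshold), ":\n", sep = "")
    print(x$left, paste0(indent, "|  "))
    cat(indent, x$attr_name, " > ", format(x$threshold), ":\n", sep = "")
    print(x$right, paste0(indent, "|  "))
  }
  invisible(x)
}

#' Count the leaves of an M5 tree
#' @param node An `m5_node`.
#' @return Integer leaf count.
#' @export
m5_leaf_count <- function(node) {
  if (node$type == "leaf") return(1L)
  m5_leaf_count(node$left) + m5_leaf_count(node$right)
}

# -- ordered rule sets --------------------------------------------------------

#' Ordered condition -> linear-model rule set
#'
#' The export format of an M5' tree and the form in which the published
#' pear-rootstock trees are distributed: an ordered list of rules, each a
#' conjunction of `attribute <= / > threshold` conditions plus a linear
#' model. Evaluation is first-match; the final rule must be unconditional
#' (the default rule).
#'
#' @param rules List of rules; each rule is a list with `conditions` (a list
#'   of `list(attr =, op = "<="|">", threshold =)`) and `model`
#'   (`list(intercept =, coefs = named numeric)`).
#' @param mapping Named character vector documenting the input-letter
#'   mapping, e.g. `c(A = "KNO3", ...)`.
#' @param note Free-text transcription note.
#' @return An `m5_ruleset`.
#' @export
m5_ruleset <- function(rules, mapping = NULL, note = NULL) {
  if (!length(rules)) stop("empty rule set")
  if (length(rules[[length(rules)]]$conditions))
    stop("last rule must be unconditional (default rule)")
  structure(list(rules = rules, mapping = mapping, note = note),
            class = "m5_ruleset")
}

#' @export
print.m5_ruleset <- function(x, ...) {
  cat("<m5_ruleset> ", length(x$rules), " rules\n", sep = "")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- vapply(r$conditions, function(cn)
      paste(cn$attr, cn$op, cn$threshold), "")
    cat(sprintf(" %d: %s\n", i,
                if (length(conds)) paste(conds, collapse = " & ") else "<default>"))
  }
  invisible(x)
}

.rule_matches <- function(rule, x) {
  for (cn in rule$conditions) {
    v <- x[[cn$attr]]
    ok <- if (cn$op == "<=") v <= cn$threshold else v > cn$threshold
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Predict from an M5 tree or rule set
#'
#' Trees route each row through the split thresholds to a leaf model; rule
#' sets evaluate the first rule whose conditions all hold.
#'
#' @param model An `m5_node` or `m5_ruleset`.
#' @param inputs Named numeric vector, matrix or data.frame of attribute
#'   values.
#' @return Numeric predictions.
#' @export
predict_m5 <- function(model, inputs) {
  if (is.data.frame(inputs)) inputs <- as.matrix(inputs)
  if (is.null(dim(inputs)))
    inputs <- matrix(inputs, nrow = 1, dimnames = list(NULL, names(inputs)))
  if (is.null(colnames(inputs)) || !all(nzchar(colnames(inputs))))
    colnames(inputs) <- LETTERS[seq_len(ncol(inputs))]
  if (inherits(model, "m5_node")) {
    one <- function(x) {
      nd <- model
      while (nd$type == "split") {
        v <- if (!is.null(names(x)) && nzchar(nd$attr_name) &&
                 nd$attr_name %in% names(x)) x[[nd$attr_name]] else
                   x[[nd$attribute]]
        nd <- if (v <= nd$threshold) nd$left else nd$right
      }
      xm <- x[names(nd$model$coefs)]
      sum(xm * nd$model$coefs) + nd$model$intercept
    }
    return(apply(inputs, 1, one))
  }
  stopifnot(inherits(model, "m5_ruleset"))
  apply(inputs, 1, function(x) {
    x <- as.list(x)
    for (rule in model$rules) {
      if (.rule_matches(rule, x)) {
        xm <- unlist(x[names(rule$model$coefs)])
        return(sum(xm * rule$model$coefs) + rule$model$intercept)
      }
    }
    stop("no rule matched (missing default rule?)")
  })
}

#' Export an M5 tree as an ordered rule set
#'
#' Depth-first left-to-right flattening: each leaf becomes one rule carrying
#' the conditions on its path; the right-most leaf supplies the default rule
#' (its conditions are dropped, preserving first-match equivalence for the
#' remaining region).
#'
#' @param node Root `m5_node`.
#' @param mapping Optional input-letter mapping to record.
#' @return An `m5_ruleset` equivalent to the tree.
#' @export
m5_to_ruleset <- function(node, mapping = NULL) {
  rules <- list()
  walk <- function(nd, conds) {
    if (nd$type == "leaf") {
      rules[[length(rules) + 1L]] <<- list(conditions = conds,
                                           model = nd$model)
      return(invisible())
    }
    walk(nd$left, c(conds, list(list(attr = nd$attr_name, op = "<=",
                                     threshold = nd$threshold))))
    walk(nd$right, c(conds, list(list(attr = nd$attr_name, op = ">",
                                      threshold = nd$threshold))))
  }
  walk(node, list())
  rules[[length(rules)]]$conditions <- list()
  m5_ruleset(rules, mapping = mapping)
}

#' Write / read a rule set in the plain-text If/Then format
#'
#' Mirrors the published layout: one condition per line, then a linear-model
#' line `X = c1*A + ... + intercept`, rules separated by blank lines.
#'
#' @param ruleset An `m5_ruleset`.
#' @param path File path.
#' @export
write_ruleset_text <- function(ruleset, path) {
  lines <- character(0)
  for (i in seq_along(ruleset$rules)) {
    r <- ruleset$rules[[i]]
    lines <- c(lines, paste0("Rule ", i, ":"))
    for (cn in r$conditions)
      lines <- c(lines, paste("  If", cn$attr, cn$op, cn$threshold))
    terms <- r$model$coefs[r$model$coefs != 0]
    rhs <- paste(c(sprintf("%g*%s", terms, names(terms)),
                   sprintf("%g", r$model$intercept)), collapse = " + ")
    lines <- c(lines, paste0("  Then X = ", rhs), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ruleset_text
#' @export
read_ruleset_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rules <- list(); conds <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^If ", ln)) {
      p <- strsplit(sub("^If ", "", ln), " ")[[1]]
      conds[[length(conds) + 1L]] <- list(attr = p[1], op = p[2],
                                          threshold = as.numeric(p[3]))
    } else if (grepl("^Then X = ", ln)) {
      rhs <- sub("^Then X = ", "", ln)
      parts <- strsplit(rhs, " \\+ ")[[1]]
      coefs <- c(); intercept <- 0
      for (p in parts) {
        if (grepl("\\*", p)) {
          kv <- strsplit(p, "\\*")[[1]]
          coefs[kv[2]] <- as.numeric(kv[1])
        } else intercept <- as.numeric(p)
      }
      rules[[length(rules) + 1L]] <- list(conditions = conds,
                                          model = list(intercept = intercept,
                                                       coefs = coefs))
      conds <- list()
    }
  }
  m5_ruleset(rules)
}
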