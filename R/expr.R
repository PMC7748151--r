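# Evaluable symbolic-regression models: expression trees over inputs A..F
# with protected arithmetic, rendered to / parsed from canonical infix text.

# Protected primitives. Domain violations return NA ("sentinel"), which
# fitness evaluation treats as worst-possible; exp is clamped instead so
# large arguments stay finite.
.protected_env <- function() {
  e <- new.env(parent = baseenv())
  e$pdiv  <- function(x, y) ifelse(abs(y) < 1e-12, NA_real_, x / y)
  e$inv   <- function(x) ifelse(abs(x) < 1e-12, NA_real_, 1 / x)
  e$pln   <- function(x) ifelse(x == 0, NA_real_, log(abs(x)))
  e$psqrt <- function(x) sqrt(abs(x))
  e$cbrt  <- function(x) sign(x) * abs(x)^(1 / 3)
  e$pexp  <- function(x) exp(pmin(x, 700))
  e$x2    <- function(x) x * x
  e$x3    <- function(x) x * x * x
  e$avg2  <- function(x, y) (x + y) / 2
  e$arctg <- atan
  e$tanh  <- base::tanh
  e$sin   <- base::sin
  e$cos   <- base::cos
  e$pow   <- function(x, y) {
    out <- suppressWarnings(x^y)
    ifelse(is.nan(out), NA_real_, out)
  }
  e
}

.expr_symbols <- c("pdiv", "inv", "pln", "psqrt", "cbrt", "pexp", "x2", "x3",
                   "avg2", "arctg", "tanh", "sin", "cos", "pow",
                   "+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "abs")

#' Create a model expression
#'
#' Wraps an R expression over the input letters `A`..`F` (one letter per
#' medium component) as an evaluable surrogate model. Expressions may use
#' ordinary arithmetic plus the protected primitives `pdiv(x, y)` (division,
#' NA when `|y| < 1e-12`), `inv(x)`, `pln(x)` (log of `|x|`, NA at 0),
#' `psqrt(x)`, `cbrt(x)`, `pexp(x)` (exp clamped at 700), `x2(x)`, `x3(x)`,
#' `avg2(x, y)`, `arctg(x)`, `tanh`, `sin`, `cos`.
#'
#' @param expr An R expression (language object) or a string of canonical
#'   infix text.
#' @param vars Input letters, default `c("A", ..., "F")`.
#' @param provenance Free-text provenance tag (`"fitted"` or a fixture tag).
#' @return A `model_expression`.
#' @examples
#' m <- model_expression("A + x2(B)")
#' evaluate_expression(m, c(A = 1, B = 2, C = 0, D = 0, E = 0, F = 0))
#' @export
model_expression <- function(expr, vars = LETTERS[1:6],
                             provenance = "fitted") {
  if (is.character(expr)) expr <- parse_expression_text(expr, vars)
  stopifnot(is.language(expr) || is.numeric(expr))
  used <- setdiff(all.names(if (is.numeric(expr)) quote(0) else expr),
                  c(.expr_symbols, vars))
  if (length(used))
    stop("unknown symbols in model expression: ",
         paste(used, collapse = ", "))
  structure(list(expr = expr, vars = vars, provenance = provenance),
            class = "model_expression")
}

#' @export
print.model_expression <- function(x, ...) {
  cat("<model_expression> [", x$provenance, "]\n  ",
      render_expression_text(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a model expression
#'
#' Deterministic, vectorized evaluation with protected semantics: domain
#' violations (division by ~0, ln(0), inverse of 0) yield `NA`, which callers
#' such as the GEP fitness treat as worst-possible.
#'
#' @param model A `model_expression` (or [m5_ruleset()] / `m5_node`, which are
#'   dispatched to [predict_m5()]).
#' @param inputs Named numeric vector, or matrix/data.frame with one column
#'   per input letter (unnamed inputs are taken in letter order).
#' @return Numeric vector of predictions.
#' @export
evaluate_expression <- function(model, inputs) {
  if (inherits(model, c("m5_ruleset", "m5_node")))
    return(predict_m5(model, inputs))
  stopifnot(inherits(model, "model_expression"))
  inputs <- .as_input_matrix(inputs, model$vars)
  env <- new.env(parent = .protected_env())
  for (v in model$vars) assign(v, inputs[, v], envir = env)
  as.numeric(eval(model$expr, env))
}

.as_input_matrix <- function(inputs, vars) {
  if (is.data.frame(inputs)) inputs <- as.matrix(inputs)
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1,
                                             dimnames = list(NULL, names(inputs)))
  if (is.null(colnames(inputs))) {
    if (ncol(inputs) < length(vars)) stop("not enough input columns")
    colnames(inputs) <- c(vars, rep("", ncol(inputs) - length(vars)))[
      seq_len(ncol(inputs))]
  }
  missing <- setdiff(vars, colnames(inputs))
  if (length(missing)) stop("missing inputs: ", paste(missing, collapse = ","))
  inputs
}

#' Render / parse canonical infix text
#'
#' `render_expression_text()` serializes a model to one line of infix text
#' with explicit function names; `parse_expression_text()` is its inverse.
#' Round-tripping evaluates identically.
#'
#' @param model A `model_expression`.
#' @return A single string.
#' @export
render_expression_text <- function(model) {
  stopifnot(inherits(model, "model_expression"))
  paste(deparse(model$expr, width.cutoff = 500L), collapse = " ")
}

#' @rdname render_expression_text
#' @param text Infix text to parse.
#' @param vars Allowed input letters.
#' @export
parse_expression_text <- function(text, vars = LETTERS[1:6]) {
  expr <- str2lang(text)
  used <- setdiff(all.names(expr), c(.expr_symbols, vars))
  if (length(used))
    stop("disallowed symbols in model text: ", paste(used, collapse = ", "))
  expr
}

#' Write / read model files
#'
#' One expression per line of canonical infix text; `#`-prefixed header lines
#' carry provenance. A sidecar JSON (same path + `.json`) stores metadata.
#'
#' @param model A `model_expression`.
#' @param path Output path.
#' @param metadata Named list stored as JSON alongside.
#' @export
write_model_text <- function(model, path, metadata = list()) {
  lines <- c(paste0("# provenance: ", model$provenance),
             render_expression_text(model))
  writeLines(lines, path, useBytes = TRUE)
  if (length(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_text
#' @export
read_model_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prov <- sub("^# provenance: ", "", grep("^# provenance:", lines, value = TRUE))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("no expression found in ", path)
  model_expression(body[[1]],
                   provenance = if (length(prov)) prov[[1]] else "file")
}
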