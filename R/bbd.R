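#' Factor specification for a three-level design
#'
#' Describes one medium component varied in the experiment: its name, the
#' actual-unit levels corresponding to coded -1 / 0 / +1, and its units
#' (a multiple of the standard MS formulation, or mg/l for the hormones).
#'
#' @param name Factor name.
#' @param low,mid,high Actual-unit levels for codes -1, 0, +1. Must be
#'   strictly increasing.
#' @param units Unit label, e.g. `"xMS"` or `"mg/l"`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("KNO3", 0.5, 1.25, 2, "xMS")
#' @export
factor_spec <- function(name, low, mid, high, units = "xMS") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(low) && is.numeric(mid) && is.numeric(high)))
    stop("levels must be numeric")
  if (!(low < mid && mid < high))
    stop("factor levels must satisfy low < mid < high")
  structure(list(name = name, low = low, mid = mid, high = high,
                 units = units),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s [%g / %g / %g] %s\n",
              x$name, x$low, x$mid, x$high, x$units))
  invisible(x)
}

#' The six pear-medium factors
#'
#' The six components varied in the pear-rootstock proliferation experiments,
#' with their three coded levels. KNO3 and NH4NO3 are varied individually;
#' the meso-nutrients (CaCl2, KH2PO4, MgSO4) and micro-nutrients move as one
#' grouped multiplier each; BA (cytokinin) and IBA (auxin) are in mg/l.
#'
#' The printed mid level of IBA is 0.13; the exact midpoint of the 0.05--0.2
#' range is 0.125, and that exact value is used by default so that coded/actual
#' conversion is symmetric (set `iba_mid` to 0.13 to reproduce the printed
#' rounding instead).
#'
#' @param iba_mid Mid level used for IBA (default exact midpoint 0.125).
#' @return Named list of six [factor_spec()] objects in the order
#'   KNO3, NH4NO3, Mesos, Micros, BA, IBA.
#' @export
pear_factors <- function(iba_mid = 0.125) {
  list(
    KNO3   = factor_spec("KNO3",   0.5,  1.25, 2,    "xMS"),
    NH4NO3 = factor_spec("NH4NO3", 0.5,  1.25, 2,    "xMS"),
    Mesos  = factor_spec("Mesos",  0.5,  1.5,  2.5,  "xMS"),
    Micros = factor_spec("Micros", 0.5,  2.25, 4,    "xMS"),
    BA     = factor_spec("BA",     0.5,  1.75, 3,    "mg/l"),
    IBA    = factor_spec("IBA",    0.05, iba_mid, 0.2, "mg/l")
  )
}

# Three-factor blocks of the 6-factor Box-Behnken construction. Each triple is
# crossed over {-1,+1}^3 with the remaining factors held at 0; this incidence
# set reproduces the published 48-run table exactly (checked in the tests).
.bbd6_blocks <- list(c(2, 5, 6), c(1, 2, 4), c(2, 3, 5),
                     c(1, 3, 6), c(3, 4, 6), c(1, 4, 5))

# Standard balanced-incomplete-block constructions for the supported sizes.
.bbd_blocks <- function(n_factors) {
  switch(as.character(n_factors),
    "3" = list(c(1, 2), c(1, 3), c(2, 3)),
    "4" = list(c(1, 2), c(3, 4), c(1, 4), c(2, 3), c(1, 3), c(2, 4)),
    "5" = utils::combn(5, 2, simplify = FALSE),
    "6" = .bbd6_blocks,
    "7" = list(c(4, 5, 6), c(1, 6, 7), c(2, 5, 7), c(1, 2, 4),
               c(3, 4, 7), c(1, 3, 5), c(2, 3, 6)),
    stop("Box-Behnken construction not available for ", n_factors,
         " factors (supported: 3-7)")
  )
}

#' Generate a three-level Box-Behnken design
#'
#' Builds the coded run matrix of a Box-Behnken design: each block of factors
#' is crossed over all +/-1 sign combinations while the remaining factors sit
#' at their mid level (code 0). For six factors this gives the 48 edge runs
#' used for the pear-media experiments; optional centre replicates (all-zero
#' rows) are appended at the end.
#'
#' @param n_factors Number of factors, between 3 and 7.
#' @param center_replicates Number of all-zero centre runs appended
#'   (default 0, matching the published 48-run table).
#' @param factor_specs Optional list of [factor_spec()]; defaults to
#'   [pear_factors()] when `n_factors == 6`, otherwise generic specs on
#'   \eqn{[-1, 1]}.
#' @return A `design_table`: list with `codes` (runs x factors integer matrix
#'   with entries -1/0/+1) and `factor_specs`.
#' @examples
#' d <- generate_bbd(6)
#' nrow(d$codes)           # 48
#' rowSums(d$codes != 0)   # every edge run has exactly three active factors
#' @export
generate_bbd <- function(n_factors, center_replicates = 0,
                         factor_specs = NULL) {
  stopifnot(length(n_factors) == 1L, n_factors == as.integer(n_factors))
  if (center_replicates < 0) stop("center_replicates must be >= 0")
  blocks <- .bbd_blocks(n_factors)
  rows <- lapply(blocks, function(b) {
    signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), length(b))))
    m <- matrix(0L, nrow(signs), n_factors)
    m[, b] <- signs
    m
  })
  codes <- do.call(rbind, rows)
  if (center_replicates > 0)
    codes <- rbind(codes, matrix(0L, center_replicates, n_factors))
  if (is.null(factor_specs)) {
    factor_specs <- if (n_factors == 6) pear_factors() else
      lapply(seq_len(n_factors), function(i)
        factor_spec(paste0("X", i), -1, 0, 1, ""))
  }
  if (length(factor_specs) != n_factors)
    stop("factor_specs must have one entry per factor")
  rownames(codes) <- NULL
  colnames(codes) <- unname(vapply(factor_specs, `[[`, "", "name"))
  structure(list(codes = codes, factor_specs = factor_specs),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d runs x %d factors (%d centre)\n",
              nrow(x$codes), ncol(x$codes), sum(rowSums(x$codes != 0) == 0)))
  invisible(x)
}

#' Convert a coded level to actual units
#'
#' Piecewise-linear interpolation about the mid point, so asymmetric
#' low/mid/high triples (such as the micro-nutrient 0.5/2.25/4) are handled:
#' code c >= 0 maps to mid + c (high - mid), c < 0 to mid + c (mid - low).
#'
#' @param code Coded level(s) in \eqn{[-1, 1]}.
#' @param spec A [factor_spec()].
#' @return Actual-unit value(s).
#' @export
code_to_actual <- function(code, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  if (any(code < -1 | code > 1)) stop("coded level outside [-1, 1]")
  ifelse(code >= 0,
         spec$mid + code * (spec$high - spec$mid),
         spec$mid + code * (spec$mid - spec$low))
}

#' Convert an actual-unit value to its coded level
#'
#' Inverse of [code_to_actual()]; exact on the grid points.
#'
#' @param value Actual-unit value(s) within `[low, high]`.
#' @param spec A [factor_spec()].
#' @return Coded level(s) in \eqn{[-1, 1]}.
#' @export
actual_to_code <- function(value, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  if (any(value < spec$low | value > spec$high))
    stop("value outside [", spec$low, ", ", spec$high, "] for ", spec$name)
  ifelse(value >= spec$mid,
         (value - spec$mid) / (spec$high - spec$mid),
         (value - spec$mid) / (spec$mid - spec$low))
}

#' Actual-unit run matrix of a design
#'
#' @param design A `design_table`.
#' @return Numeric matrix of the runs in actual units.
#' @export
design_actual <- function(design) {
  stopifnot(inherits(design, "design_table"))
  out <- design$codes * 0
  for (j in seq_along(design$factor_specs))
    out[, j] <- code_to_actual(design$codes[, j], design$factor_specs[[j]])
  out
}

#' Write / read a design table as CSV
#'
#' Columns: `run_id`, one coded column per factor, and (write only, optional)
#' one `<name>_actual` column per factor. Header row mandatory, UTF-8.
#'
#' @param design A `design_table`.
#' @param path File path.
#' @param actual Also write actual-unit columns?
#' @export
write_design_csv <- function(design, path, actual = TRUE) {
  stopifnot(inherits(design, "design_table"))
  df <- data.frame(run_id = seq_len(nrow(design$codes)), design$codes,
                   check.names = FALSE)
  if (actual) {
    act <- design_actual(design)
    colnames(act) <- paste0(colnames(act), "_actual")
    df <- cbind(df, act)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_csv
#' @param factor_specs Factor specs to attach on read; defaults to
#'   [pear_factors()] for six-factor files.
#' @export
read_design_csv <- function(path, factor_specs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"run_id" %in% names(df)) stop("design CSV must have a run_id column")
  fac_cols <- setdiff(names(df), c("run_id", grep("_actual$", names(df),
                                                  value = TRUE)))
  codes <- as.matrix(df[fac_cols])
  storage.mode(codes) <- "integer"
  if (is.null(factor_specs) && length(fac_cols) == 6) {
    factor_specs <- pear_factors()
    names(factor_specs) <- fac_cols
    for (i in seq_along(factor_specs)) factor_specs[[i]]$name <- fac_cols[i]
  }
  if (is.null(factor_specs))
    factor_specs <- lapply(fac_cols, function(nm) factor_spec(nm, -1, 0, 1, ""))
  structure(list(codes = codes, factor_specs = factor_specs),
            class = "design_table")
}
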