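# Gamma test: near-neighbour estimation of the noise variance of
# y = f(x) + eps for smooth unknown f, and the leave-one-out input-ranking
# procedure built on it.

#' Gamma statistic for one input combination
#'
#' For each k = 1..p, computes the mean squared distance to the k-th nearest
#' neighbour in input space, `delta(k) = mean(|x_N(i,k) - x_i|^2)`, and the
#' corresponding half mean squared output difference
#' `gamma(k) = mean(|y_N(i,k) - y_i|^2) / 2`, then regresses gamma on delta.
#' The intercept Gamma estimates the variance of the noise on the output;
#' the slope A indexes model complexity. Negative intercepts are legitimate
#' sampling outcomes and are not clamped.
#'
#' Input columns are min-max standardized to \[0, 1\] before the distance
#' computation (the convention of the Gamma-test literature); the output is
#' left unscaled so Gamma is in output-variance units.
#'
#' @param X Input matrix (M x d) or data.frame.
#' @param y Response vector of length M.
#' @param p Number of near neighbours (default 10).
#' @param mask Optional logical/0-1 vector selecting input columns.
#' @param allow_ties Permit duplicate input rows (resolved by row order)?
#'   Default FALSE: duplicates raise an error, as coincident points make the
#'   k-th neighbour ill-defined.
#' @return A `gamma_result`: list with `gamma` (intercept), `gradient`
#'   (slope A), `se` (standard error of the intercept), `mask`, `p`, `M`,
#'   and the `(delta, gamma)` pairs.
#' @export
gamma_statistic <- function(X, y, p = 10, mask = NULL, allow_ties = FALSE) {
  X <- as.matrix(X)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (!any(mask)) stop("empty mask: at least one input must be selected")
    X <- X[, mask, drop = FALSE]
  }
  M <- nrow(X)
  if (length(y) != M) stop("y must align with rows of X")
  if (M <= p) stop("insufficient sample: need M > p")
  # standardize inputs to [0,1] per column
  Xs <- apply(X, 2, function(col) {
    r <- range(col)
    if (r[1] == r[2]) rep(0, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  d2 <- as.matrix(stats::dist(Xs))^2
  diag(d2) <- Inf
  if (!allow_ties && any(d2 == 0))
    stop("duplicate input rows after standardization; set allow_ties = TRUE ",
         "for deterministic index-order tie-breaking")
  # k nearest neighbours per row, ties broken by row index (stable order)
  ord <- apply(d2, 1, order, simplify = FALSE)
  delta <- numeric(p); gam <- numeric(p)
  for (k in seq_len(p)) {
    nb <- vapply(seq_len(M), function(i) ord[[i]][k], 0L)
    delta[k] <- mean(d2[cbind(seq_len(M), nb)])
    gam[k]   <- mean((y[nb] - y)^2) / 2
  }
  fit <- stats::lm(gam ~ delta)
  sm <- summary(fit)$coefficients
  structure(list(gamma = unname(stats::coef(fit)[1]),
                 gradient = unname(stats::coef(fit)[2]),
                 se = unname(sm[1, 2]),
                 mask = if (is.null(mask)) rep(TRUE, ncol(X)) else mask,
                 p = p, M = M, delta = delta, gamma_k = gam),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> Gamma=%.4f A=%.4f SE=%.4f (M=%d, p=%d, mask=%s)\n",
              x$gamma, x$gradient, x$se, x$M, x$p,
              paste(as.integer(x$mask), collapse = "")))
  invisible(x)
}

#' Gamma statistics for a list of input masks
#'
#' @param X Input matrix; `y` response; `p` neighbour count.
#' @param masks List of logical/0-1 vectors over the columns of `X`.
#' @inheritParams gamma_statistic
#' @return A `mask_scan`: list of `gamma_result`s (one per mask, in order)
#'   with the mask strings as names.
#' @export
mask_scan <- function(X, y, masks, p = 10, allow_ties = FALSE) {
  res <- lapply(masks, function(m)
    gamma_statistic(X, y, p = p, mask = m, allow_ties = allow_ties))
  names(res) <- vapply(masks, function(m)
    paste(as.integer(as.logical(m)), collapse = ""), "")
  structure(res, class = "mask_scan")
}

#' Leave-one-out mask set
#'
#' The full mask plus the d masks dropping one input each — the combination
#' set used to rank input importance.
#'
#' @param d Number of inputs.
#' @return List of d + 1 logical vectors (full mask first).
#' @export
loo_masks <- function(d) {
  c(list(rep(TRUE, d)),
    lapply(seq_len(d), function(j) { m <- rep(TRUE, d); m[j] <- FALSE; m }))
}

#' Rank inputs by leave-one-out Gamma
#'
#' An input whose removal increases the Gamma statistic most is most
#' important (its information cannot be recovered from the remaining
#' inputs). Requires a scan holding the full mask and all d leave-one-out
#' masks; ties are broken by input index.
#'
#' @param scan A `mask_scan`.
#' @param input_names Optional names for the inputs.
#' @return Data frame ordered most to least important, with the
#'   leave-one-out Gamma for each input.
#' @export
rank_inputs <- function(scan, input_names = NULL) {
  d <- length(scan[[1]]$mask)
  full <- paste(rep("1", d), collapse = "")
  if (!full %in% names(scan)) stop("incomplete scan: full mask missing")
  loo_gamma <- numeric(d)
  for (j in seq_len(d)) {
    m <- rep(1L, d); m[j] <- 0L
    key <- paste(m, collapse = "")
    if (!key %in% names(scan))
      stop("incomplete scan: leave-one-out mask ", key, " missing")
    loo_gamma[j] <- scan[[key]]$gamma
  }
  if (is.null(input_names)) input_names <- LETTERS[seq_len(d)]
  ord <- order(-loo_gamma, seq_len(d))
  data.frame(input = input_names[ord], index = ord,
             loo_gamma = loo_gamma[ord],
             full_gamma = scan[[full]]$gamma,
             row.names = NULL)
}

#' Write a Gamma-test report
#'
#' Per-output table mirroring the published layout: combination label, mask
#' string, Gamma, gradient and SE, as CSV.
#'
#' @param scan A `mask_scan`.
#' @param path Output CSV path.
#' @param input_names Input names used for the combination labels.
#' @export
write_gamma_report <- function(scan, path, input_names = NULL) {
  d <- length(scan[[1]]$mask)
  if (is.null(input_names)) input_names <- LETTERS[seq_len(d)]
  lab <- vapply(scan, function(r) {
    out <- which(!r$mask)
    if (!length(out)) "All inputs" else
      paste0("All inputs - ", paste(input_names[out], collapse = ","))
  }, "")
  df <- data.frame(combination = lab, mask = names(scan),
                   gamma = vapply(scan, `[[`, 0, "gamma"),
                   gradient = vapply(scan, `[[`, 0, "gradient"),
                   se = vapply(scan, `[[`, 0, "se"), row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
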