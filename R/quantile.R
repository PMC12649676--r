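#' Fit a population-level linear quantile regression (pinball loss)
#'
#' Minimises the check (pinball) loss
#' \eqn{\sum_i \rho_\tau(y_i - b_0 - b_1 x_i)} with
#' \eqn{\rho_\tau(r) = r(\tau - 1\{r<0\})} over intercept and slope. The
#' solver runs an iteratively reweighted least-squares pass on a smoothed
#' loss and then polishes to an exact linear-programming basic solution by
#' enumerating candidate lines through pairs of near-active points (an
#' optimum of this LP always passes through at least two data points in
#' general position), keeping the line with the smallest exact loss.
#'
#' @param x numeric predictor (age in days for the fasting threshold).
#' @param y numeric response (daily feed intake or feeding duration).
#' @param tau quantile level in (0, 1); default 0.05 (the population
#'   5th-percentile line under which days count as fasting days).
#' @param n_candidates number of near-active points used in the polish step.
#' @return object of class `quantile_line`: list `tau`, `intercept`,
#'   `slope`, `objective`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rep(90:150, 20); y <- 2 + 0.02 * x + rnorm(length(x), 0, 0.4)
#' fit_quantile_line(x, y, tau = 0.05)
fit_quantile_line <- function(x, y, tau = 0.05, n_candidates = 40) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2) {
    if (n >= 1 && length(unique(y)) == 1)
      return(structure(list(tau = tau, intercept = y[1], slope = 0,
                            objective = 0, n = n), class = "quantile_line"))
    stop("need at least 2 points with distinct x", call. = FALSE)
  }

  pinball <- function(b0, b1) {
    r <- y - b0 - b1 * x
    sum(r * (tau - (r < 0)))
  }

  ## IRLS on smoothed loss
  b <- stats::coef(stats::lm.fit(cbind(1, x), y))
  eps <- 1e-6 * max(stats::sd(y), 1e-8)
  for (it in 1:60) {
    r <- y - b[1] - b[2] * x
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    bn <- stats::coef(stats::lm.wfit(cbind(1, x), y, w))
    if (max(abs(bn - b)) < 1e-10 * (1 + max(abs(b)))) { b <- bn; break }
    b <- bn
  }

  ## polish: exact basic solutions through pairs of near-active points
  r <- y - b[1] - b[2] * x
  cand <- order(abs(r))[seq_len(min(n_candidates, n))]
  best <- list(obj = pinball(b[1], b[2]), b0 = b[1], b1 = b[2])
  cp <- utils::combn(cand, 2)
  for (k in seq_len(ncol(cp))) {
    i <- cp[1, k]; j <- cp[2, k]
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    o <- pinball(b0, b1)
    if (o < best$obj - 1e-12) best <- list(obj = o, b0 = b0, b1 = b1)
  }
  structure(list(tau = tau, intercept = unname(best$b0),
                 slope = unname(best$b1), objective = unname(best$obj),
                 n = n),
            class = "quantile_line")
}

#' @export
print.quantile_line <- function(x, ...) {
  cat(sprintf("<quantile_line> tau = %.3g: y = %.5g %+.5g x  (n = %d, loss = %.5g)\n",
              x$tau, x$intercept, x$slope, x$n, x$objective))
  invisible(x)
}

#' Predict from a fitted quantile line
#'
#' @param object a `quantile_line`.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @export
predict.quantile_line <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}
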