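#' OLS regression RMSE of a daily trait on age
#'
#' Fits ordinary least squares of the trait values on age and returns the
#' root mean square error with divisor `n` (the literal root of the mean
#' squared residual; configurable). Large RMSE means large day-to-day
#' deviation from the animal's own trajectory, i.e. low resilience.
#'
#' @param ages integer ages in days.
#' @param values daily trait values (same length).
#' @param divisor `"n"` (default) or `"n-2"` (the regression error variance
#'   convention).
#' @return list `slope`, `intercept`, `rmse`, `n`.
#' @export
ols_rmse <- function(ages, values, divisor = c("n", "n-2")) {
  divisor <- match.arg(divisor)
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(ages)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(ages)) < 2)
    stop("degenerate design: all ages equal", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ages), values)
  den <- if (divisor == "n") n else n - 2
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rmse = sqrt(sum(fit$residuals^2) / den), n = n)
}

#' RMSE of the cumulative trait curve
#'
#' Accumulates the daily values over the in-window days (restarting at the
#' window start), fits OLS of the cumulative curve on age, and returns the
#' RMSE. Illness episodes flatten the cumulative curve and inflate this
#' deviation measure.
#'
#' @inheritParams ols_rmse
#' @export
cumulative_rmse <- function(ages, values, divisor = c("n", "n-2")) {
  ok <- is.finite(ages) & is.finite(values)
  o <- order(ages[ok])
  ols_rmse(ages[ok][o], cumsum(values[ok][o]), divisor = match.arg(divisor))
}

#' Percentage of fasting days below a population quantile line
#'
#' A day counts as a fasting day when the animal's daily value falls
#' strictly below the population-level `tau`-quantile regression line
#' evaluated at that age.
#'
#' @param ages,values one animal's daily series.
#' @param line a fitted [fit_quantile_line()] for the same trait.
#' @return percentage of recorded days below the line (0-100).
#' @export
fasting_percent <- function(ages, values, line) {
  stopifnot(inherits(line, "quantile_line"))
  ok <- is.finite(ages) & is.finite(values)
  100 * mean(values[ok] < predict(line, ages[ok]))
}

#' Compute the six resilience traits for a cohort
#'
#' From QC'd daily series, computes per animal the OLS-regression RMSE of
#' daily feed intake and feeding duration on age (RMSE_FI, RMSE_FD), the
#' RMSE of the cumulative intake and duration curves (RMSE_CFI, RMSE_CFD),
#' and the percentage of fasting days below the population `tau`-quantile
#' regression line (QR_FI, QR_FD). The two quantile lines are fitted once on
#' the pooled animal-day panel per trait.
#'
#' @param daily QC'd daily series (columns `animal_id`, `age_days`,
#'   `fi_kg`, `fd_min`).
#' @param tau quantile level of the population fasting threshold.
#' @param divisor RMSE divisor convention, see [ols_rmse()].
#' @return data.frame with columns `animal_id`, `RMSE_FI`, `RMSE_FD`,
#'   `RMSE_CFI`, `RMSE_CFD`, `QR_FI`, `QR_FD`, plus attribute
#'   `quantile_lines` (the two fitted lines).
#' @export
resilience_traits <- function(daily, tau = 0.05, divisor = "n") {
  stopifnot(all(c("animal_id", "age_days", "fi_kg", "fd_min") %in% names(daily)))
  line_fi <- fit_quantile_line(daily$age_days, daily$fi_kg, tau = tau)
  line_fd <- fit_quantile_line(daily$age_days, daily$fd_min, tau = tau)
  sp <- split(seq_len(nrow(daily)), daily$animal_id)
  rows <- lapply(names(sp), function(id) {
    d <- daily[sp[[id]], ]
    tryCatch(
      data.frame(
        animal_id = id,
        RMSE_FI = ols_rmse(d$age_days, d$fi_kg, divisor)$rmse,
        RMSE_FD = ols_rmse(d$age_days, d$fd_min, divisor)$rmse,
        RMSE_CFI = cumulative_rmse(d$age_days, d$fi_kg, divisor)$rmse,
        RMSE_CFD = cumulative_rmse(d$age_days, d$fd_min, divisor)$rmse,
        QR_FI = fasting_percent(d$age_days, d$fi_kg, line_fi),
        QR_FD = fasting_percent(d$age_days, d$fd_min, line_fd),
        stringsAsFactors = FALSE),
      error = function(e)
        stop("resilience traits failed for animal ", id, ": ",
             conditionMessage(e), call. = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quantile_lines") <- list(FI = line_fi, FD = line_fd)
  out
}
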