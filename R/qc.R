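#' Aggregate feeder visits into per-animal daily records
#'
#' Sums per-visit consumption (initial minus final trough weight, g) and
#' occupation time over each calendar day, takes the day's median of visit
#' body weights, and computes age in days from the birth date. Days with no
#' visits yield no record (a gap, not a zero). Visits with negative
#' consumption are flagged and excluded from the intake sum (their duration
#' still counts as occupation time is measured independently of the scale).
#'
#' @param visits data.frame of visit records (see [read_visits()]); the
#'   timestamp columns may be POSIXct or parseable character.
#' @param birthdates data.frame `animal_id`, `birth_date` (Date or
#'   parseable character).
#' @return list with `daily` (data.frame `animal_id`, `date`, `age_days`,
#'   `fi_kg`, `fd_min`, `weight_kg`, `n_visits`) and `flagged` (the visits
#'   with negative consumption).
#' @export
aggregate_daily <- function(visits, birthdates) {
  v <- data.table::as.data.table(visits)
  if (!inherits(v$start_ts, "POSIXct")) v[, start_ts := as.POSIXct(start_ts, tz = "UTC")]
  if (!inherits(v$end_ts, "POSIXct")) v[, end_ts := as.POSIXct(end_ts, tz = "UTC")]
  if (any(v$end_ts < v$start_ts))
    stop("visit end time before start time", call. = FALSE)
  v[, cons_g := trough_in_g - trough_out_g]
  flagged <- as.data.frame(v[cons_g < 0])
  v[, date := as.Date(start_ts, tz = "UTC")]
  daily <- v[, .(
    fi_kg = sum(pmax(cons_g, 0) * (cons_g >= 0)) / 1000,
    fd_min = as.numeric(sum(difftime(end_ts, start_ts, units = "mins"))),
    weight_kg = stats::median(weight_kg),
    n_visits = .N), by = .(animal_id, date)]

  bd <- data.table::as.data.table(birthdates)
  bd[, birth_date := as.Date(birth_date)]
  daily <- merge(daily, bd[, .(animal_id, birth_date)], by = "animal_id")
  if (anyNA(daily$birth_date))
    stop("birth date missing for some animals", call. = FALSE)
  daily[, age_days := as.integer(date - birth_date)]
  daily[, birth_date := NULL]
  data.table::setorder(daily, animal_id, age_days)
  list(daily = as.data.frame(daily), flagged = flagged)
}

#' Drop animals with too few daily records
#'
#' @param daily daily-record data.frame (from [aggregate_daily()]).
#' @param min_records minimum number of daily records to retain an animal.
#' @return list `daily` (retained rows), `excluded` (animal ids removed),
#'   `counts` (in/out/excluded animal counts).
#' @export
exclude_sparse <- function(daily, min_records = 60) {
  n_rec <- table(daily$animal_id)
  keep <- names(n_rec)[n_rec >= min_records]
  excluded <- setdiff(names(n_rec), keep)
  list(daily = daily[daily$animal_id %in% keep, , drop = FALSE],
       excluded = excluded,
       counts = c(animals_in = length(n_rec), animals_out = length(keep),
                  animals_excluded = length(excluded)))
}

#' Mask upper-tail outliers in daily intake and duration
#'
#' For feed intake and feeding duration independently, values strictly
#' exceeding that animal's own mean by more than `k` standard deviations are
#' set to missing; the pre-masking value is retained alongside so that runs
#' of consecutive missing days can later be restored. The rule is one-sided:
#' low values are the biological fasting signal the resilience traits
#' measure and are never masked.
#'
#' @param daily daily-record data.frame.
#' @param k SD multiplier (default 4).
#' @return daily data.frame with `fi_kg`/`fd_min` possibly NA and companion
#'   columns `fi_orig`, `fd_orig`, `fi_masked`, `fd_masked`.
#' @export
mask_outliers <- function(daily, k = 4) {
  d <- data.table::as.data.table(daily)
  if (!"fi_orig" %in% names(d)) d[, `:=`(fi_orig = fi_kg, fd_orig = fd_min)]
  mask1 <- function(x) {
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(FALSE, length(x)))
    !is.na(x) & x > mu + k * s
  }
  d[, fi_masked := mask1(fi_kg), by = animal_id]
  d[, fd_masked := mask1(fd_min), by = animal_id]
  d[fi_masked == TRUE, fi_kg := NA_real_]
  d[fd_masked == TRUE, fd_min := NA_real_]
  as.data.frame(d)
}

#' Impute isolated masked values with a centred 5-day rolling average
#'
#' Each isolated missing value is replaced by the mean of the available
#' (non-missing) days inside a centred `window`-day window; for runs of two
#' or more consecutive missing days the pre-masking original values are
#' restored, as they are for missing days whose window holds no usable
#' neighbour. Only masked outliers are eligible: calendar gaps with no
#' visits are not records and are never fabricated.
#'
#' @param daily daily data.frame as returned by [mask_outliers()].
#' @param window odd window width in days (default 5).
#' @return daily data.frame with `fi_kg`/`fd_min` completed and logical
#'   `fi_imputed`/`fd_imputed` flags.
#' @export
impute_rolling <- function(daily, window = 5) {
  stopifnot(window >= 3, window %% 2 == 1)
  half <- (window - 1) / 2
  d <- data.table::as.data.table(daily)
  fill1 <- function(age, x, orig) {
    miss <- which(is.na(x))
    imputed <- rep(FALSE, length(x))
    if (!length(miss)) return(list(x = x, imputed = imputed))
    ## runs of >= 2 consecutive missing ages: restore originals
    run <- cumsum(c(1, diff(miss) != 1 | diff(age[miss]) != 1))
    for (r in unique(run)) {
      i <- miss[run == r]
      if (length(i) >= 2) {
        x[i] <- orig[i]
      } else {
        nb <- which(!is.na(x) & abs(age - age[i]) <= half & age != age[i])
        if (length(nb)) {
          x[i] <- mean(x[nb])
          imputed[i] <- TRUE
        } else {
          x[i] <- orig[i]
        }
      }
    }
    list(x = x, imputed = imputed)
  }
  d[, c("fi_kg", "fi_imputed") := fill1(age_days, fi_kg, fi_orig), by = animal_id]
  d[, c("fd_min", "fd_imputed") := fill1(age_days, fd_min, fd_orig), by = animal_id]
  as.data.frame(d)
}

#' Restrict daily records to an on-test age window
#'
#' Records with age outside the closed interval `[lo, hi]` are dropped and
#' animals are re-checked against the minimum-record rule afterwards.
#'
#' @param daily daily data.frame.
#' @param lo,hi window bounds in days (closed interval).
#' @param min_records re-applied minimum daily-record count (NULL to skip).
#' @return list `daily`, `excluded` (animals failing the re-check),
#'   `counts`.
#' @export
window_age <- function(daily, lo = 90, hi = 150, min_records = 60) {
  d <- daily[daily$age_days >= lo & daily$age_days <= hi, , drop = FALSE]
  if (is.null(min_records))
    return(list(daily = d, excluded = character(0),
                counts = c(animals_in = length(unique(daily$animal_id)),
                           animals_out = length(unique(d$animal_id)),
                           animals_excluded = 0)))
  ex <- exclude_sparse(d, min_records)
  ex$counts["animals_in"] <- length(unique(daily$animal_id))
  ex$counts["animals_excluded"] <-
    ex$counts["animals_in"] - ex$counts["animals_out"]
  ex
}

#' Full feeder quality-control chain
#'
#' Runs, in order: visit-to-day aggregation, exclusion of animals with fewer
#' than `min_records` daily records, one-sided `k`-SD outlier masking,
#' rolling-average imputation, and the age-window filter with a final
#' re-check of the minimum-record rule. The chain is idempotent and every
#' exclusion is accounted for in the report.
#'
#' @param visits visit records (data.frame or CSV path).
#' @param birthdates birth dates (data.frame or CSV path).
#' @param min_records minimum daily records per animal (default 60).
#' @param sd_k outlier masking multiplier (default 4).
#' @param window age window `c(lo, hi)` in days (default `c(90, 150)`).
#' @param rolling rolling-average window width in days (default 5).
#' @return list `daily` (clean per-animal series), `report` (per-rule
#'   bookkeeping: counts in, out and excluded, masked and imputed cells,
#'   flagged visits).
#' @export
qc_feeder <- function(visits, birthdates, min_records = 60, sd_k = 4,
                      window = c(90, 150), rolling = 5) {
  if (is.character(visits)) visits <- read_visits(visits)
  if (is.character(birthdates))
    birthdates <- as.data.frame(data.table::fread(birthdates))
  agg <- aggregate_daily(visits, birthdates)
  sp <- exclude_sparse(agg$daily, min_records)
  mk <- mask_outliers(sp$daily, k = sd_k)
  im <- impute_rolling(mk, window = rolling)
  wn <- window_age(im, window[1], window[2], min_records)
  report <- list(
    n_visits = nrow(visits),
    n_flagged_visits = nrow(agg$flagged),
    aggregate = c(animals = length(unique(agg$daily$animal_id)),
                  records = nrow(agg$daily)),
    exclude_sparse = sp$counts,
    sparse_excluded = sp$excluded,
    masked = c(fi = sum(mk$fi_masked), fd = sum(mk$fd_masked)),
    imputed = c(fi = sum(im$fi_imputed), fd = sum(im$fd_imputed)),
    window = wn$counts,
    window_excluded = wn$excluded,
    final = c(animals = length(unique(wn$daily$animal_id)),
              records = nrow(wn$daily)))
  list(daily = wn$daily, report = report)
}

utils::globalVariables(c(
  "cons_g", "animal_id", "birth_date", "age_days", "fi_kg", "fd_min",
  "fi_orig", "fd_orig", "fi_masked", "fd_masked", "date"))
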