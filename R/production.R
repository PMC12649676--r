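#' Average daily gain over the on-test window
#'
#' Body-weight difference between the maximum and minimum recorded in-window
#' age divided by the age difference.
#'
#' @param ages ages in days with a recorded weight.
#' @param weights body weights in kg.
#' @return kg/day, or NA if fewer than two weights are available.
#' @export
adg <- function(ages, weights) {
  ok <- is.finite(ages) & is.finite(weights)
  ages <- ages[ok]; weights <- weights[ok]
  if (length(ages) < 2 || max(ages) == min(ages)) return(NA_real_)
  (weights[which.max(ages)] - weights[which.min(ages)]) /
    (max(ages) - min(ages))
}

#' Adjust age and backfat to a 100-kg body-weight basis
#'
#' Standard swine performance-test adjustments with breed- and sex-specific
#' correction coefficients `A` (days) and `B` (kg):
#' \deqn{AGE_{100} = age + (W - 100)(age - A)/W}
#' \deqn{BF_{100} = bf + (W - 100)\, bf / (W - B)}
#' Both formulas are the identity at `W = 100` for any coefficients. The
#' sign convention of the weight deviation is switchable because the NSIF
#' convention writes the correction with `(100 - W)`.
#'
#' @param age measured age (days).
#' @param weight measured body weight (kg), > 0.
#' @param bf measured backfat (mm).
#' @param A age coefficient (days); breed/sex specific.
#' @param B backfat coefficient (kg); must differ from `weight`.
#' @param convention `"measured-minus-100"` (default) or `"100-minus-measured"`.
#' @return list `age100` (days), `bf100` (mm).
#' @export
adjust_100kg <- function(age, weight, bf, A = 50.775, B = 0,
                         convention = c("measured-minus-100",
                                        "100-minus-measured")) {
  convention <- match.arg(convention)
  if (any(weight <= 0, na.rm = TRUE)) stop("weight must be > 0", call. = FALSE)
  if (any(weight == B, na.rm = TRUE))
    stop("backfat adjustment undefined at weight == B", call. = FALSE)
  dev <- if (convention == "measured-minus-100") weight - 100 else 100 - weight
  list(age100 = age + dev * (age - A) / weight,
       bf100  = bf + dev * bf / (weight - B))
}

#' Compute production traits for a cohort
#'
#' From the QC'd daily series (and one backfat measurement per animal),
#' computes average daily gain (ADG, kg/d), age and backfat adjusted to
#' 100 kg (AGE, days; BF, mm), average daily feed intake and feeding
#' duration (ADFI kg/d, ADFD min/d), feed conversion ratio
#' (FCR = ADFI/ADG), metabolic body weight (MBW, mid-test weight^0.75 with
#' the mid-window weight interpolated between the two nearest weighings)
#' and residual feed intake (RFI, kg/d): the residual of the cohort OLS
#' regression of ADFI on ADG and MBW with an intercept, so that RFI
#' averages exactly zero over the fitted cohort.
#'
#' @param daily QC'd daily series (`animal_id`, `age_days`, `fi_kg`,
#'   `fd_min`, `weight_kg`).
#' @param backfat data.frame `animal_id`, `bf_mm` (one row per animal), or
#'   NULL to skip the adjusted traits.
#' @param A,B,convention 100-kg adjustment coefficients, see
#'   [adjust_100kg()].
#' @param rfi_mode `"intercept"` (default: OLS with intercept) or
#'   `"centered"` (no intercept on centred predictors; same residuals).
#' @return data.frame `animal_id`, `ADG`, `AGE`, `BF`, `ADFI`, `ADFD`,
#'   `FCR`, `RFI`, `MBW`.
#' @export
production_traits <- function(daily, backfat = NULL, A = 50.775, B = 0,
                              convention = "measured-minus-100",
                              rfi_mode = c("intercept", "centered")) {
  rfi_mode <- match.arg(rfi_mode)
  sp <- split(seq_len(nrow(daily)), daily$animal_id)
  mid <- mean(range(daily$age_days))
  rows <- lapply(names(sp), function(id) {
    d <- daily[sp[[id]], ]
    adfi <- mean(d$fi_kg, na.rm = TRUE)
    adfd <- mean(d$fd_min, na.rm = TRUE)
    g <- adg(d$age_days, d$weight_kg)
    ok <- is.finite(d$weight_kg)
    w_mid <- if (sum(ok) >= 2)
      stats::approx(d$age_days[ok], d$weight_kg[ok], xout = mid, rule = 2)$y
    else NA_real_
    last <- which.max(d$age_days)
    data.frame(animal_id = id, ADG = g, ADFI = adfi, ADFD = adfd,
               MBW = w_mid^0.75,
               last_age = d$age_days[last], last_w = d$weight_kg[last],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$FCR <- ifelse(is.finite(out$ADG) & out$ADG > 0, out$ADFI / out$ADG, NA)
  if (any(!is.na(out$ADG) & out$ADG <= 0))
    warning("non-positive ADG for some animals; FCR set to NA")

  out$AGE <- NA_real_; out$BF <- NA_real_
  if (!is.null(backfat)) {
    i <- match(out$animal_id, backfat$animal_id)
    adj <- adjust_100kg(out$last_age, out$last_w, backfat$bf_mm[i],
                        A = A, B = B, convention = convention)
    out$AGE <- adj$age100
    out$BF <- adj$bf100
  }
  out$RFI <- rfi(out$ADFI, out$ADG, out$MBW, mode = rfi_mode)
  out <- out[order(out$animal_id),
             c("animal_id", "ADG", "AGE", "BF", "ADFI", "ADFD", "FCR",
               "RFI", "MBW")]
  rownames(out) <- NULL
  out
}

#' Residual feed intake
#'
#' Residuals of the cohort-level OLS regression
#' `ADFI ~ b0 + b1 ADG + b2 MBW`. With an intercept (or equivalently with
#' centred predictors and no intercept) the residuals average exactly zero
#' and are orthogonal to ADG and MBW.
#'
#' @param adfi,adg,mbw per-animal vectors.
#' @param mode `"intercept"` or `"centered"`.
#' @return per-animal RFI (kg/d); NA where any input is missing.
#' @export
rfi <- function(adfi, adg, mbw, mode = c("intercept", "centered")) {
  mode <- match.arg(mode)
  ok <- is.finite(adfi) & is.finite(adg) & is.finite(mbw)
  if (sum(ok) < 3) stop("need at least 3 complete animals", call. = FALSE)
  out <- rep(NA_real_, length(adfi))
  if (mode == "intercept") {
    X <- cbind(1, adg[ok], mbw[ok]); y <- adfi[ok]
  } else {
    X <- cbind(adg[ok] - mean(adg[ok]), mbw[ok] - mean(mbw[ok]))
    y <- adfi[ok] - mean(adfi[ok])
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient RFI design (ADG and MBW collinear)", call. = FALSE)
  out[ok] <- stats::lm.fit(X, y)$residuals
  out
}
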