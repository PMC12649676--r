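mk_visits <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(animal_id = r[[1]], start_ts = r[[2]], end_ts = r[[3]],
               trough_in_g = as.integer(r[[4]]),
               trough_out_g = as.integer(r[[5]]),
               weight_kg = as.numeric(r[[6]]), stringsAsFactors = FALSE)))
}

test_that("daily aggregation sums intake and duration per calendar day", {
  v <- mk_visits(list(
    list("a1", "2024-05-01 08:00:00", "2024-05-01 08:03:00", 4500, 4000, 50),
    list("a1", "2024-05-01 12:00:00", "2024-05-01 12:02:00", 4250, 4000, 50.4),
    list("a1", "2024-05-03 09:00:00", "2024-05-03 09:05:00", 4100, 4000, 51)))
  out <- aggregate_daily(v, data.frame(animal_id = "a1",
                                       birth_date = "2024-01-22"))
  d <- out$daily
  expect_equal(nrow(d), 2)  # no record fabricated for 2024-05-02
  expect_equal(d$fi_kg[1], 0.750)
  expect_equal(d$fd_min[1], 5.0)
  expect_equal(d$weight_kg[1], 50.2)
  expect_equal(d$age_days, c(100L, 102L))
})

test_that("negative-consumption visits are flagged and excluded from intake", {
  v <- mk_visits(list(
    list("a1", "2024-05-01 08:00:00", "2024-05-01 08:03:00", 4500, 4000, 50),
    list("a1", "2024-05-01 09:00:00", "2024-05-01 09:01:00", 4000, 4200, 50)))
  out <- aggregate_daily(v, data.frame(animal_id = "a1",
                                       birth_date = "2024-01-22"))
  expect_equal(nrow(out$flagged), 1)
  expect_equal(out$daily$fi_kg, 0.5)
})

test_that("sparse-animal exclusion uses an inclusive 60-record boundary", {
  d <- data.frame(animal_id = rep(c("a", "b", "c"), c(59, 60, 61)),
                  age_days = c(1:59, 1:60, 1:61),
                  fi_kg = 2, fd_min = 50, weight_kg = 60)
  out <- exclude_sparse(d, 60)
  expect_identical(out$excluded, "a")
  expect_setequal(unique(out$daily$animal_id), c("b", "c"))
  expect_equal(unname(out$counts), c(3, 2, 1))
})

test_that("outlier masking is one-sided, per-animal, strict at mean + 4 SD", {
  set.seed(1)
  x <- rnorm(60, 2.5, 0.1)
  x[30] <- 5.0
  d <- data.frame(animal_id = "a", age_days = 1:60, fi_kg = x,
                  fd_min = 50, weight_kg = 60)
  m <- mask_outliers(d, k = 4)
  expect_identical(which(is.na(m$fi_kg)), 30L)
  expect_equal(m$fi_orig[30], 5.0)
  expect_false(any(m$fd_masked))

  # a constant series masks nothing (zero SD)
  d2 <- d; d2$fi_kg <- 2.5
  expect_false(any(is.na(mask_outliers(d2, 4)$fi_kg)))

  # a value exactly at mean + 4 SD is retained (strict inequality);
  # solve for the value that lands exactly on the threshold of its own series
  base <- rep(c(1.9, 2.1), 25)
  f <- function(v) {
    z <- c(base, v)
    v - (mean(z) + 4 * sd(z))
  }
  v_star <- uniroot(f, c(2.2, 10), tol = 1e-12)$root
  d3 <- data.frame(animal_id = "a", age_days = seq_len(51),
                   fi_kg = c(base, v_star), fd_min = 50, weight_kg = 60)
  expect_false(any(is.na(mask_outliers(d3, k = 4)$fi_kg)))
  d4 <- d3; d4$fi_kg[51] <- v_star + 1e-4
  expect_identical(which(is.na(mask_outliers(d4, k = 4)$fi_kg)), 51L)
})

test_that("isolated missing values get the rolling mean; runs are restored", {
  d <- data.frame(animal_id = "a", age_days = 1:5,
                  fi_kg = c(2.0, 2.2, NA, 2.4, 2.6),
                  fd_min = 50, weight_kg = 60,
                  fi_orig = c(2.0, 2.2, 9.9, 2.4, 2.6),
                  fd_orig = 50, fi_masked = c(F, F, T, F, F),
                  fd_masked = FALSE)
  out <- impute_rolling(d)
  expect_equal(out$fi_kg[3], 2.3)
  expect_true(out$fi_imputed[3])

  d2 <- d
  d2$fi_kg[3:4] <- NA; d2$fi_orig[3:4] <- c(9.9, 8.8)
  out2 <- impute_rolling(d2)
  expect_equal(out2$fi_kg[3:4], c(9.9, 8.8))  # originals retained
  expect_false(any(out2$fi_imputed))

  # no missing values: identity
  d3 <- d; d3$fi_kg[3] <- 2.35
  expect_equal(impute_rolling(d3)$fi_kg, d3$fi_kg)
})

test_that("age windowing uses a closed interval and re-checks the minimum", {
  d <- data.frame(animal_id = rep("a", 70), age_days = 85:154,
                  fi_kg = 2, fd_min = 50, weight_kg = 60)
  out <- window_age(d, 90, 150, min_records = 60)
  expect_equal(range(out$daily$age_days), c(90, 150))
  expect_equal(nrow(out$daily), 61)

  # 70 records but only 50 in-window: the animal is excluded
  d2 <- data.frame(animal_id = rep("b", 70), age_days = 51:120,
                   fi_kg = 2, fd_min = 50, weight_kg = 60)
  out2 <- window_age(d2, 90, 150, min_records = 60)
  expect_identical(out2$excluded, "b")
  expect_equal(nrow(out2$daily), 0)
})

test_that("the full QC chain is idempotent", {
  sim <- small_sim(n_animals = 25, n_snps = 20, seed = 42,
                   illness_rate = 0.03)
  qc1 <- qc_feeder(sim$feeder$visits, sim$feeder$birthdates)
  once <- qc1$daily
  # re-apply the series-level chain to the already-clean series
  twice <- window_age(impute_rolling(mask_outliers(once, 4)), 90, 150, 60)$daily
  cols <- c("animal_id", "age_days", "fi_kg", "fd_min", "weight_kg")
  expect_equal(twice[cols], once[cols], ignore_attr = TRUE)
})

test_that("QC bookkeeping accounts for every animal", {
  sim <- small_sim(n_animals = 30, n_snps = 20, seed = 7)
  qc <- qc_feeder(sim$feeder$visits, sim$feeder$birthdates)
  r <- qc$report
  expect_equal(unname(r$exclude_sparse["animals_in"]),
               unname(r$exclude_sparse["animals_out"]) +
                 unname(r$exclude_sparse["animals_excluded"]))
  expect_equal(unname(r$window["animals_in"]),
               unname(r$window["animals_out"]) +
                 unname(r$window["animals_excluded"]))
  expect_equal(unname(r$final["animals"]),
               unname(r$window["animals_out"]))
})
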