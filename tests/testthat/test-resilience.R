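test_that("ols_rmse matches an independent normal-equations oracle", {
  # brute-force oracle: solve the 2x2 normal equations directly
  ols_oracle <- function(x, y) {
    XtX <- matrix(c(length(x), sum(x), sum(x), sum(x^2)), 2)
    b <- solve(XtX, c(sum(y), sum(x * y)))
    r <- y - b[1] - b[2] * x
    sqrt(mean(r^2))
  }
  f <- ols_rmse(c(1, 2, 3), c(0, 1, 0))
  expect_equal(f$rmse, ols_oracle(c(1, 2, 3), c(0, 1, 0)))
  expect_equal(f$rmse, sqrt(2 / 3) / sqrt(3))  # residuals (-1/3, 2/3, -1/3)

  set.seed(2)
  for (i in 1:5) {
    x <- sample(90:150, 20); y <- rnorm(20, 2, 0.5)
    expect_equal(ols_rmse(x, y)$rmse, ols_oracle(x, y))
  }
})

test_that("ols_rmse is translation invariant and degree-1 homogeneous", {
  set.seed(3)
  x <- 90:120; y <- 2 + 0.02 * x + rnorm(31, 0, 0.3)
  r0 <- ols_rmse(x, y)$rmse
  expect_equal(ols_rmse(x, y + 5)$rmse, r0)
  expect_equal(ols_rmse(x, 3 * y)$rmse, 3 * r0)
  expect_equal(ols_rmse(x, 2 + 0.02 * x)$rmse, 0, tolerance = 1e-12)
  expect_error(ols_rmse(rep(100, 5), rnorm(5)), "degenerate")
})

test_that("cumulative RMSE is zero for constant intake, matches the oracle", {
  expect_equal(cumulative_rmse(1:10, rep(2.5, 10))$rmse, 0, tolerance = 1e-10)
  # daily (1,1,4) at ages (1,2,3) -> cumulative (1,2,6)
  o <- lm(c(1, 2, 6) ~ c(1, 2, 3))
  expect_equal(cumulative_rmse(1:3, c(1, 1, 4))$rmse,
               sqrt(mean(residuals(o)^2)))
})

test_that("an illness dip inflates the cumulative RMSE", {
  ages <- 90:150
  flat <- rep(2.5, 61)
  dip <- flat; dip[25:29] <- 0.5
  expect_gt(cumulative_rmse(ages, dip)$rmse, cumulative_rmse(ages, flat)$rmse)
})

test_that("fasting percentage counts strict exceedances below the line", {
  line <- structure(list(tau = 0.05, intercept = 1, slope = 0, objective = 0,
                         n = 10), class = "quantile_line")
  vals <- rep(2, 60); vals[c(10, 20)] <- 0.5
  expect_equal(fasting_percent(1:60, vals, line), 100 * 2 / 60)
  expect_equal(fasting_percent(1:60, rep(2, 60), line), 0)
  expect_equal(fasting_percent(1:60, rep(1, 60), line), 0)  # on the line
})

test_that("cohort resilience traits: shape, order invariance, coverage", {
  sim <- small_sim(n_animals = 40, n_snps = 50, seed = 42)
  qc <- qc_feeder(sim$feeder$visits, sim$feeder$birthdates)
  res <- resilience_traits(qc$daily, tau = 0.05)
  expect_named(res, c("animal_id", "RMSE_FI", "RMSE_FD", "RMSE_CFI",
                      "RMSE_CFD", "QR_FI", "QR_FD"))
  expect_equal(nrow(res), length(unique(qc$daily$animal_id)))
  expect_true(all(res$RMSE_FI >= 0 & res$QR_FI >= 0 & res$QR_FI <= 100))

  # permuting the input rows leaves every trait unchanged
  set.seed(1)
  perm <- qc$daily[sample(nrow(qc$daily)), ]
  res2 <- resilience_traits(perm, tau = 0.05)
  expect_equal(res2, res, ignore_attr = TRUE)

  # balanced panel: the animal-mean of QR equals 100 * overall below-line rate
  line <- attr(res, "quantile_lines")$FI
  below <- mean(qc$daily$fi_kg < predict(line, qc$daily$age_days))
  expect_equal(mean(res$QR_FI), 100 * below, tolerance = 1e-8)
})

test_that("stronger illness pressure raises the fasting percentage", {
  # strata must share one pooled quantile line: a line refitted within each
  # cohort re-normalises coverage to tau by construction
  ill <- small_sim(n_animals = 60, n_snps = 20, seed = 77,
                   illness_rate = 0.05, illness_depth = 0.7)
  calm <- small_sim(n_animals = 60, n_snps = 20, seed = 77,
                    illness_rate = 0)
  q_ill <- qc_feeder(ill$feeder$visits, ill$feeder$birthdates)$daily
  q_calm <- qc_feeder(calm$feeder$visits, calm$feeder$birthdates)$daily
  q_calm$animal_id <- paste0(q_calm$animal_id, "_calm")
  pooled <- rbind(q_ill, q_calm)
  r <- resilience_traits(pooled)
  is_ill <- !grepl("_calm$", r$animal_id)
  expect_gt(mean(r$QR_FI[is_ill]), mean(r$QR_FI[!is_ill]))
})
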