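test_that("REML recovers nothing from pure noise (null heritability)", {
  sim <- small_sim(n_animals = 300, n_snps = 50, seed = 42)
  set.seed(11)
  ph <- sim$pop$covariates
  ph$y <- rnorm(nrow(ph))
  f <- fit_animal_model(ph, "y", pedigree_A(sim$pop$pedigree),
                        fixed = c("breed", "sex"))
  expect_lt(f$h2, max(0.12, 2 * f$se_h2))
})

test_that("REML estimates transform correctly under shift and scale of y", {
  sim <- small_sim(n_animals = 200, n_snps = 50, seed = 42)
  A <- pedigree_A(sim$pop$pedigree)
  ph <- sim$pop$covariates
  ph$y <- sim$pop$truth$latent_score[ph$animal_id]
  f0 <- fit_animal_model(ph, "y", A, fixed = "breed")
  ph$y_shift <- ph$y + 100
  ph$y_scale <- 3 * ph$y
  f1 <- fit_animal_model(ph, "y_shift", A, fixed = "breed")
  f2 <- fit_animal_model(ph, "y_scale", A, fixed = "breed")
  expect_equal(f1$sigma2_a, f0$sigma2_a, tolerance = 1e-4)
  expect_equal(f1$h2, f0$h2, tolerance = 1e-4)
  expect_equal(f2$sigma2_a, 9 * f0$sigma2_a, tolerance = 1e-3)
  expect_equal(f2$h2, f0$h2, tolerance = 1e-3)
  expect_true(f0$h2 >= 0 && f0$h2 <= 1)
})

test_that("REML optimum beats a dense grid search at n = 30", {
  cfg <- sim_config(n_animals = 30, n_snps = 20, seed = 77)
  pop <- simulate_population(cfg)
  A <- pedigree_A(pop$pedigree)
  ids <- pop$covariates$animal_id
  ph <- pop$covariates
  ph$y <- pop$truth$latent_score[ids]
  f <- fit_animal_model(ph, "y", A, fixed = character(0))

  li <- ph$litter
  structures <- list(A[ids, ids], outer(li, li, "==") * 1)
  X <- matrix(1, 30, 1)
  grid <- expand.grid(a = seq(0.0005, 0.15, length.out = 14),
                      l = seq(0.0001, 0.05, length.out = 8),
                      e = seq(0.001, 0.12, length.out = 12))
  vals <- apply(grid, 1, function(th)
    reml_loglik_direct(th, ph$y, X, structures))
  expect_gte(f$loglik, max(vals) - 1e-4)
})

test_that("bivariate REML: identical traits give a genetic correlation of 1", {
  sim <- small_sim(n_animals = 250, n_snps = 40, seed = 56)
  A <- pedigree_A(sim$pop$pedigree)
  ids <- sim$pop$covariates$animal_id
  set.seed(21)
  L <- t(chol(A[ids, ids]))
  u <- as.numeric(L %*% rnorm(length(ids))) * sqrt(0.3)
  ph <- sim$pop$covariates
  ph$t1 <- u + rnorm(length(ids), 0, sqrt(0.7))
  ph$t1b <- ph$t1
  fit <- genetic_correlation(ph, "t1", "t1b", A, fixed = character(0),
                             litter = NULL)
  expect_equal(fit$rg, 1, tolerance = 0.01)
})

test_that("bivariate REML: genetically independent traits give rg near 0", {
  sim <- small_sim(n_animals = 400, n_snps = 40, seed = 58)
  A <- pedigree_A(sim$pop$pedigree)
  ids <- sim$pop$covariates$animal_id
  set.seed(31)
  L <- t(chol(A[ids, ids]))
  n <- length(ids)
  ph <- sim$pop$covariates
  ph$t1 <- as.numeric(L %*% rnorm(n)) * sqrt(0.4) + rnorm(n, 0, sqrt(0.6))
  ph$t2 <- as.numeric(L %*% rnorm(n)) * sqrt(0.4) + rnorm(n, 0, sqrt(0.6))
  fit <- genetic_correlation(ph, "t1", "t2", A, fixed = character(0),
                             litter = NULL)
  expect_lt(abs(fit$rg), max(0.25, 2.5 * fit$se))
})
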