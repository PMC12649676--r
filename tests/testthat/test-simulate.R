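test_that("sim_config validates variance fractions and MAF range", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(h2_resilience = 0.8, litter_var_frac = 0.3),
               "exceed 1")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.05, 0.6)), "maf_range")
  expect_error(sim_config(illness_depth = 1.5), "\\[0, 1\\]")
})

test_that("population simulation is deterministic under a fixed seed", {
  s1 <- simulate_population(sim_config(n_animals = 30, n_snps = 100, seed = 5))
  s2 <- simulate_population(sim_config(n_animals = 30, n_snps = 100, seed = 5))
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth$latent_score, s2$truth$latent_score)
  s3 <- simulate_population(sim_config(n_animals = 30, n_snps = 100, seed = 6))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("genotypes are 0/1/2, Mendelian-consistent, founder freqs in range", {
  sim <- small_sim(n_animals = 60, n_snps = 300, seed = 42)
  G <- sim$pop$genotypes
  expect_true(all(G %in% 0:2))
  ped <- sim$pop$pedigree
  off <- ped[ped$sire != "0", ]
  # offspring dosage never exceeds what two parental gametes can supply
  for (i in sample(nrow(off), 20)) {
    gs <- G[off$sire[i], ]; gd <- G[off$dam[i], ]; go <- G[off$id[i], ]
    expect_true(all(go >= (gs == 2) + (gd == 2)))
    expect_true(all(go <= 2 - ((gs == 0) + (gd == 0))))
  }
  founders <- ped$id[ped$sire == "0"]
  pf <- colMeans(G[founders, , drop = FALSE]) / 2
  # pooled founder frequency tracks the ancestral draw up to breed divergence
  expect_true(mean(pf >= 0.05 - 0.25 & pf <= 0.5 + 0.25) > 0.95)
})

test_that("zero heritability yields zero breeding values", {
  pop <- simulate_population(sim_config(n_animals = 40, n_snps = 50,
                                        seed = 3, h2_resilience = 0))
  expect_true(all(pop$truth$true_breeding_values == 0))
  expect_equal(nrow(pop$truth$causal_snps), 0)
})

test_that("a single large causal SNP drives the breeding values", {
  pop <- simulate_population(sim_config(n_animals = 500, n_snps = 100,
                                        seed = 11, n_causal = 1,
                                        causal_frac = 1))
  idx <- pop$truth$causal_snps$snp
  ids <- pop$covariates$animal_id
  r <- cor(pop$genotypes[ids, idx], pop$truth$true_breeding_values[ids])
  expect_gt(abs(r), 0.5)
})

test_that("breed clusters separate on the top-2 GRM principal components", {
  pop <- simulate_population(sim_config(n_animals = 150, n_snps = 800,
                                        seed = 21))
  ids <- pop$covariates$animal_id
  K <- suppressWarnings(grm(pop$genotypes[ids, ]))  # fixed alleles may occur
  pc <- pca_grm(K, 2)
  xy <- pc$vectors
  breed <- pop$covariates$breed
  cent <- apply(xy, 2, tapply, breed, mean)
  assigned <- rownames(cent)[apply(xy, 1, function(v)
    which.min(colSums((t(cent) - v)^2)))]
  expect_gt(mean(assigned == breed), 0.95)
})

test_that("visit grams sum exactly to the generated daily totals", {
  sim <- small_sim(n_animals = 40, n_snps = 50, seed = 42)
  v <- sim$feeder$visits
  v$date <- as.Date(substr(v$start_ts, 1, 10))
  got <- aggregate((trough_in_g - trough_out_g) ~ animal_id + date, v, sum)
  names(got)[3] <- "grams"
  truth <- sim$feeder$daily_truth
  truth$grams_true <- round(truth$fi_kg * 1000)
  mg <- merge(got, truth, by.x = c("animal_id", "date"),
              by.y = c("animal_id", "date"))
  expect_equal(nrow(mg), nrow(truth))
  expect_true(all(abs(mg$grams - mg$grams_true) <= 1))
})

test_that("feeder series is deterministic and noise-free in the noiseless limit", {
  cfg <- sim_config(n_animals = 10, n_snps = 20, seed = 8, illness_rate = 0)
  pop <- simulate_population(cfg)
  f1 <- simulate_feeder_series(cfg, pop)
  f2 <- simulate_feeder_series(cfg, pop)
  expect_identical(f1$visits, f2$visits)

  f0 <- simulate_feeder_series(cfg, pop, noise_sd_scale = 0)
  qc <- qc_feeder(f0$visits, f0$birthdates)
  res <- resilience_traits(qc$daily)
  # daily FI on the line up to the 1-g rounding of the feeder
  expect_true(all(res$RMSE_FI < 0.002))
})

test_that("illness episodes depress intake on affected days", {
  cfg <- sim_config(n_animals = 30, n_snps = 20, seed = 13,
                    illness_rate = 0.05, illness_depth = 0.6)
  pop <- simulate_population(cfg)
  fe <- simulate_feeder_series(cfg, pop, noise_sd_scale = 0)
  dt <- fe$daily_truth
  expect_gt(sum(dt$ill), 0)
  expect_lt(mean(dt$fi_kg[dt$ill]), 0.6 * mean(dt$fi_kg[!dt$ill]))
})
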