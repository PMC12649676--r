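test_that("PCA of a block-diagonal GRM separates the blocks; eigenvectors orthonormal", {
  K <- matrix(0.02, 90, 90)
  for (b in 0:2) {
    i <- b * 30 + 1:30
    K[i, i] <- 0.8
  }
  diag(K) <- 1
  rownames(K) <- colnames(K) <- paste0("a", 1:90)
  pc <- pca_grm(K, 5)
  grp <- rep(1:3, each = 30)
  cent <- apply(pc$vectors[, 1:2], 2, tapply, grp, mean)
  assigned <- apply(pc$vectors[, 1:2], 1, function(v)
    which.min(colSums((t(cent) - v)^2)))
  expect_equal(assigned, grp, ignore_attr = TRUE)
  expect_equal(crossprod(pc$vectors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$values) <= 1e-8))
  expect_error(pca_grm(K, 100), "exceeds")

  # reconstruction at full rank
  e <- eigen(K, symmetric = TRUE)
  expect_equal(e$vectors %*% diag(e$values) %*% t(e$vectors), unname(K),
               tolerance = 1e-8)
})

test_that("genomic inflation factor: definition, null behaviour, monotonicity", {
  # hand check on 5 fixed p-values via the chi-square quantile transform
  p5 <- c(0.8, 0.5, 0.3, 0.2, 0.05)
  lam5 <- suppressWarnings(genomic_inflation(p5))
  expect_equal(lam5, qchisq(0.3, 1, lower.tail = FALSE) / qchisq(0.5, 1))

  set.seed(12)
  p <- runif(5e4)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.03)
  expect_gt(genomic_inflation(p / 2), genomic_inflation(p))
})

test_that("FDR-proportional threshold arithmetic", {
  p <- c(rep(5e-4, 2), runif(98, 0.01, 1))
  fd <- fdr_threshold(p, fdr = 0.001)
  expect_equal(fd$threshold_p, 0.001 * 2 / 100)
  expect_equal(fd$n, 2)
  expect_equal(fd$m, 100)
  expect_equal(sum(fd$significant), sum(p <= 2e-5))

  expect_warning(fd0 <- fdr_threshold(runif(50, 0.01, 1)), "threshold is 0")
  expect_equal(fd0$threshold_p, 0)
  expect_false(any(fd0$significant))
})

test_that("LMM association matches a direct GLS oracle at small n", {
  set.seed(61)
  n <- 40; m <- 15
  G <- sapply(runif(m, 0.2, 0.45), function(p) rbinom(n, 2, p))
  K <- grm(G) + diag(1e-4, n)
  W <- cbind(1, rnorm(n))
  y <- 0.3 * G[, 4] + as.numeric(t(chol(K)) %*% rnorm(n)) * 0.5 + rnorm(n)
  res <- suppressWarnings(lmm_assoc(y, W, K, G))
  for (j in seq_len(m)) {
    lam <- res$snps$lambda[j]
    V <- lam * K + diag(n)
    Vi <- solve(V)
    X <- cbind(W, G[, j])
    C <- solve(t(X) %*% Vi %*% X)
    b <- C %*% t(X) %*% Vi %*% y
    Pm <- Vi - Vi %*% X %*% C %*% t(X) %*% Vi
    tau_inv <- as.numeric(t(y) %*% Pm %*% y) / (n - ncol(X))
    se <- sqrt(diag(C)[3] * tau_inv)
    expect_equal(res$snps$beta[j], as.numeric(b[3]), tolerance = 1e-6)
    expect_equal(res$snps$se[j], unname(se), tolerance = 1e-6)
    expect_equal(res$snps$p_wald[j],
                 pchisq((b[3] / se)^2, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("p-values are uniform under a pure-noise null with K = I", {
  set.seed(62)
  n <- 60; m <- 10000
  G <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  res <- suppressWarnings(
    lmm_assoc(y, NULL, diag(n), G, per_snp_lambda = FALSE))
  keep <- !res$snps$monomorphic
  ks <- ks.test(res$snps$p_wald[keep], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("SNP order permutation permutes results identically; monomorphic flagged", {
  set.seed(63)
  n <- 50; m <- 12
  G <- sapply(runif(m, 0.2, 0.45), function(p) rbinom(n, 2, p))
  G[, 5] <- 1  # monomorphic
  K <- grm(G[, -5]) + diag(1e-4, n)
  y <- rnorm(n)
  r1 <- suppressWarnings(lmm_assoc(y, NULL, K, G))
  perm <- sample(m)
  r2 <- suppressWarnings(lmm_assoc(y, NULL, K, G[, perm]))
  expect_equal(r2$snps$p_wald, r1$snps$p_wald[perm])
  expect_equal(r2$snps$beta, r1$snps$beta[perm])
  expect_true(r1$snps$monomorphic[5])
  expect_equal(r1$snps$p_wald[5], 1)
  # deterministic: same input, same output
  r3 <- suppressWarnings(lmm_assoc(y, NULL, K, G))
  expect_identical(r1$snps, r3$snps)
})

test_that("Manhattan/QQ export is complete and internally consistent", {
  set.seed(64)
  n <- 50; m <- 30
  G <- sapply(runif(m, 0.2, 0.45), function(p) rbinom(n, 2, p))
  map <- data.frame(snp = paste0("s", 1:m), chrom = rep(1:3, 10), pos = 1:m)
  res <- suppressWarnings(lmm_assoc(rnorm(n), NULL, grm(G) + diag(1e-4, n),
                                    G, map = map))
  dir <- withr::local_tempdir()
  files <- qq_manhattan_export(res, dir)
  man <- read.csv(files["manhattan"])
  qq <- read.csv(files["qq"])
  expect_equal(nrow(man), m)
  expect_equal(nrow(qq), m)
  expect_true(all(man$p[man$significant] <= res$threshold_p))
  expect_equal(sort(man$p), sort(res$snps$p_wald))
})
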