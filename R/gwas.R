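#' Principal components of a relationship matrix
#'
#' Top-k eigenpairs of the (symmetric) kinship or genomic relationship
#' matrix, used as ancestry covariates and for population-structure plots.
#' Eigenvector signs follow a deterministic convention: the loading of
#' largest magnitude is made positive.
#'
#' @param K symmetric relationship matrix.
#' @param k number of components (default 5).
#' @return list of class `grm_pca`: `vectors` (n x k, rownames kept),
#'   `values` (all eigenvalues, descending), `k`.
#' @export
pca_grm <- function(K, k = 5) {
  stopifnot(isSymmetric(unname(K), tol = 1e-8))
  n <- nrow(K)
  if (k > n) stop("k exceeds matrix dimension", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(K)
  colnames(V) <- paste0("PC", seq_len(k))
  structure(list(vectors = V, values = e$values, k = k), class = "grm_pca")
}

#' Genomic inflation factor
#'
#' Median of the chi-square(1) statistics implied by the p-values, divided
#' by the null median 0.4549 (qchisq(0.5, 1)).
#'
#' @param pvals vector of p-values.
#' @return lambda_gc.
#' @export
genomic_inflation <- function(pvals) {
  p <- pvals[is.finite(pvals)]
  if (length(p) < 100)
    warning("genomic inflation estimated from fewer than 100 p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' FDR-proportional significance threshold
#'
#' The threshold p-value is `fdr * n / m`, with `n` the number of observed
#' p-values below 0.001 and `m` the total number of SNPs tested. This is
#' the proportional rule as printed (not Benjamini-Hochberg); a BH option
#' is available for comparison via [stats::p.adjust()].
#'
#' @param pvals vector of p-values (finite).
#' @param fdr nominal false discovery rate (default 0.001).
#' @return list `threshold_p`, `n` (count of p < 0.001), `m`, `significant`
#'   (logical, p <= threshold).
#' @export
fdr_threshold <- function(pvals, fdr = 0.001) {
  stopifnot(all(is.finite(pvals)))
  n <- sum(pvals < 0.001)
  m <- length(pvals)
  thr <- fdr * n / m
  if (n == 0) warning("no p-values below 0.001; threshold is 0")
  list(threshold_p = thr, n = n, m = m,
       significant = pvals <= thr & thr > 0)
}

#' Univariate linear mixed-model association scan
#'
#' Single-SNP association under
#' \eqn{y = W\alpha + x\beta + u + \epsilon}, with
#' \eqn{u \sim MVN(0, \lambda \tau^{-1} K)} and
#' \eqn{\epsilon \sim MVN(0, \tau^{-1} I)}. The kinship matrix is
#' eigendecomposed once; for each SNP the variance ratio \eqn{\lambda} is
#' re-estimated by profiling the restricted likelihood over
#' \eqn{\log \lambda} on a bracketed grid in \eqn{[10^{-5}, 10^5]} followed
#' by Brent refinement (set `per_snp_lambda = FALSE` for the faster
#' null-model approximation that fixes \eqn{\lambda} once). The SNP effect
#' and its standard error come from GLS at the profiled optimum and are
#' tested with a Wald chi-square on 1 df. Monomorphic SNPs are flagged and
#' reported with `beta = 0`, `p = 1`.
#'
#' Missing dosages are mean-imputed per SNP; `y` and `W` must be complete.
#'
#' @param y phenotype vector.
#' @param W covariate matrix including the intercept (defaults to an
#'   intercept-only matrix). Typical columns: birth year-season, breed, top
#'   principal components of the GRM.
#' @param K relationship matrix conformable with `y`.
#' @param G dosage matrix (animals x SNPs).
#' @param map optional data.frame `snp`, `chrom`, `pos` aligned to the
#'   columns of `G`.
#' @param fdr nominal FDR for the proportional threshold.
#' @param per_snp_lambda re-estimate lambda per SNP (default TRUE).
#' @return object of class `gwas_result`: data.frame `snps` (`snp`,
#'   `chrom`, `pos`, `beta`, `se`, `p_wald`, `lambda`, `monomorphic`,
#'   `significant`), plus `lambda_gc`, `threshold_p`, `n_below_1e3`, `m`.
#' @export
lmm_assoc <- function(y, W = NULL, K, G, map = NULL, fdr = 0.001,
                      per_snp_lambda = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must be complete", call. = FALSE)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  if (anyNA(W)) stop("W must be complete", call. = FALSE)
  if (qr(W)$rank < ncol(W)) stop("W is rank deficient", call. = FALSE)
  stopifnot(nrow(W) == n, nrow(K) == n, nrow(G) == n)

  eK <- eigen(K, symmetric = TRUE)
  D <- pmax(eK$values, 0)
  U <- eK$vectors
  yt <- crossprod(U, y)
  Wt <- crossprod(U, W)

  ## negative restricted log-likelihood profile in log10(lambda)
  neg_reml <- function(l10, Xt) {
    v <- 10^l10 * D + 1
    M <- crossprod(Xt, Xt / v)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(1e30)
    bv <- crossprod(Xt, yt / v)
    quad <- sum(yt^2 / v) - sum(backsolve(ch, bv, transpose = TRUE)^2)
    if (quad <= 0) return(1e30)
    0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) +
             (n - ncol(Xt)) * log(quad))
  }
  profile_lambda <- function(Xt) {
    grid <- seq(-5, 5, by = 0.5)
    vals <- vapply(grid, neg_reml, numeric(1), Xt = Xt)
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(neg_reml, c(lo, hi), Xt = Xt, tol = 1e-6)
    10^opt$minimum
  }
  gls_at <- function(lambda, Xt) {
    v <- lambda * D + 1
    M <- crossprod(Xt, Xt / v)
    Mi <- solve(M)
    bhat <- Mi %*% crossprod(Xt, yt / v)
    quad <- sum(yt^2 / v) - drop(crossprod(crossprod(Xt, yt / v), bhat))
    tau_inv <- quad / (n - ncol(Xt))
    list(beta = drop(bhat), se = sqrt(diag(Mi) * tau_inv))
  }

  lambda0 <- profile_lambda(Wt)
  m <- ncol(G)
  beta <- se <- pv <- lam <- numeric(m)
  mono <- logical(m)
  for (j in seq_len(m)) {
    x <- G[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::var(x) == 0) {
      beta[j] <- 0; se[j] <- NA; pv[j] <- 1; lam[j] <- NA; mono[j] <- TRUE
      next
    }
    Xt <- cbind(Wt, crossprod(U, x))
    lj <- if (per_snp_lambda) profile_lambda(Xt) else lambda0
    g <- gls_at(lj, Xt)
    k <- ncol(Xt)
    beta[j] <- g$beta[k]; se[j] <- g$se[k]; lam[j] <- lj
    pv[j] <- stats::pchisq((beta[j] / se[j])^2, df = 1, lower.tail = FALSE)
  }
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)

  fd <- fdr_threshold(pv, fdr = fdr)
  snps <- data.frame(
    snp = if (!is.null(map)) map$snp else paste0("snp", seq_len(m)),
    chrom = if (!is.null(map)) map$chrom else NA,
    pos = if (!is.null(map)) map$pos else NA,
    beta = beta, se = se, p_wald = pv, lambda = lam,
    monomorphic = mono, significant = fd$significant,
    stringsAsFactors = FALSE)
  structure(list(snps = snps,
                 lambda_gc = genomic_inflation(pv),
                 threshold_p = fd$threshold_p,
                 n_below_1e3 = fd$n, m = fd$m, fdr = fdr,
                 lambda_null = lambda0),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> m = %d SNPs, lambda_gc = %.3f, threshold p = %.3g (%d significant)\n",
              x$m, x$lambda_gc, x$threshold_p, sum(x$snps$significant)))
  invisible(x)
}

#' Export Manhattan and Q-Q plot data
#'
#' Writes tidy CSVs: per-SNP `chrom`, `pos`, `p`, `neglog10_p`,
#' `significant`, and the observed-vs-expected -log10 quantile table for a
#' Q-Q plot.
#'
#' @param result a `gwas_result`.
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
qq_manhattan_export <- function(result, dir) {
  stopifnot(inherits(result, "gwas_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- file.path(dir, "manhattan.csv")
  qq <- file.path(dir, "qq.csv")
  s <- result$snps
  data.table::fwrite(data.frame(
    chrom = s$chrom, pos = s$pos, p = s$p_wald,
    neglog10_p = -log10(s$p_wald), significant = s$significant), man)
  po <- sort(s$p_wald)
  data.table::fwrite(data.frame(
    expected = -log10(stats::ppoints(length(po))),
    observed = -log10(po)), qq)
  invisible(c(manhattan = man, qq = qq))
}
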