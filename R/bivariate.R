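#' Genetic correlation between two traits (bivariate animal model)
#'
#' Fits a two-trait animal model by average-information REML over 2 x 2
#' genetic, optional litter, and residual (co)variance blocks:
#' the stacked phenotype has covariance
#' \eqn{V = \Sigma_a \otimes K + \Sigma_{litter} \otimes L +
#' \Sigma_e \otimes I}. Each block is projected to the nearest positive
#' semi-definite matrix whenever an update leaves the parameter space (the
#' projection is recorded in the returned object). The genetic correlation
#' is \eqn{r_g = \sigma_{a,12} / \sqrt{\sigma_{a,1}^2 \sigma_{a,2}^2}},
#' clamped to \[-1, 1\], with a delta-method standard error from the inverse
#' average-information matrix.
#'
#' @param pheno data.frame with `animal_id`, both trait columns and
#'   covariates; rows with a missing value in either trait are dropped.
#' @param trait1,trait2 trait column names.
#' @param K relationship matrix with animal-id dimnames.
#' @param fixed fixed-effect factor columns (applied to both traits).
#' @param litter litter column name or NULL.
#' @param max_iter,tol_loglik iteration controls.
#' @return list of class `genetic_correlation`: `rg`, `se`, `blocks`
#'   (named list of fitted 2 x 2 covariance matrices), `loglik`, `n`,
#'   `iterations`, `n_projections`.
#' @export
genetic_correlation <- function(pheno, trait1, trait2, K,
                                fixed = c("pen_batch", "breed", "sex"),
                                litter = "litter",
                                max_iter = 100, tol_loglik = 1e-8) {
  stopifnot(all(c(trait1, trait2, "animal_id") %in% names(pheno)))
  d <- pheno[!is.na(pheno[[trait1]]) & !is.na(pheno[[trait2]]), , drop = FALSE]
  ids <- as.character(d$animal_id)
  n <- nrow(d)
  y1 <- d[[trait1]]; y2 <- d[[trait2]]
  X1 <- if (length(fixed)) {
    f <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
    stats::model.matrix(f, data = as.data.frame(
      lapply(d[fixed], function(col) factor(col))))
  } else matrix(1, n, 1)
  qrX <- qr(X1)
  X1 <- X1[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X <- rbind(cbind(X1, matrix(0, n, ncol(X1))),
             cbind(matrix(0, n, ncol(X1)), X1))

  Cs <- list(additive = K[ids, ids])
  use_litter <- !is.null(litter) && litter %in% names(d)
  if (use_litter) {
    li <- as.character(d[[litter]])
    Cs$litter <- outer(li, li, "==") * 1
  }
  Cs$residual <- diag(n)
  nc <- length(Cs)

  ## univariate starting values + empirical cross-trait correlation
  f1 <- fit_animal_model(d, trait1, K, fixed = fixed,
                         litter = if (use_litter) litter else NULL)
  f2 <- fit_animal_model(d, trait2, K, fixed = fixed,
                         litter = if (use_litter) litter else NULL)
  r0 <- stats::cor(stats::lm.fit(X1, y1)$residuals,
                   stats::lm.fit(X1, y2)$residuals)
  r0 <- max(min(r0, 0.8), -0.8)
  blocks <- list()
  s1 <- f1$reml$sigma2; s2 <- f2$reml$sigma2
  for (cn in names(Cs)) {
    v1 <- unname(s1[if (cn == "residual") "residual" else cn])
    v2 <- unname(s2[if (cn == "residual") "residual" else cn])
    blocks[[cn]] <- matrix(c(v1, r0 * sqrt(v1 * v2) * 0.5,
                             r0 * sqrt(v1 * v2) * 0.5, v2), 2, 2)
  }

  y <- c(y1, y2)
  vy <- stats::var(y)
  floor_ <- 1e-8 * vy
  n_proj <- 0L
  proj_psd <- function(M, fl) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    if (all(e$values >= fl)) return(M)
    n_proj <<- n_proj + 1L
    e$vectors %*% diag(pmax(e$values, fl), 2) %*% t(e$vectors)
  }
  blocks <- lapply(blocks, proj_psd, fl = floor_)

  E <- list(`11` = matrix(c(1, 0, 0, 0), 2),
            `12` = matrix(c(0, 1, 1, 0), 2),
            `22` = matrix(c(0, 0, 0, 1), 2))
  theta_of <- function(bl) unlist(lapply(bl, function(M)
    c(M[1, 1], M[1, 2], M[2, 2])))
  blocks_of <- function(th) {
    bl <- vector("list", nc); names(bl) <- names(Cs)
    for (i in seq_len(nc)) {
      v <- th[(i - 1) * 3 + 1:3]
      bl[[i]] <- matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
    }
    bl
  }
  build_V <- function(bl) {
    V <- matrix(0, 2 * n, 2 * n)
    for (i in seq_len(nc)) {
      B <- bl[[i]]; C <- Cs[[i]]
      i1 <- seq_len(n); i2 <- n + i1
      V[i1, i1] <- V[i1, i1] + B[1, 1] * C
      V[i2, i2] <- V[i2, i2] + B[2, 2] * C
      V[i1, i2] <- V[i1, i2] + B[1, 2] * C
      V[i2, i1] <- V[i2, i1] + B[1, 2] * C
    }
    V
  }
  eval_state <- function(bl) {
    V <- build_V(bl)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chC <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chC)) return(NULL)
    P <- Vi - ViX %*% chol2inv(chC) %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chC))) +
                    sum(y * Py))
    list(P = P, Py = Py, loglik = ll)
  }

  mult_z <- function(ci, e, z) {
    z1 <- z[seq_len(n)]; z2 <- z[n + seq_len(n)]
    C <- Cs[[ci]]
    if (e == "11") c(C %*% z1, numeric(n))
    else if (e == "22") c(numeric(n), C %*% z2)
    else c(C %*% z2, C %*% z1)
  }
  tr_P <- function(P, ci, e) {
    i1 <- seq_len(n); i2 <- n + i1
    C <- Cs[[ci]]
    if (e == "11") sum(P[i1, i1] * C)
    else if (e == "22") sum(P[i2, i2] * C)
    else 2 * sum(P[i1, i2] * C)
  }

  st <- eval_state(blocks)
  if (is.null(st)) stop("initial covariance matrix not positive definite",
                        call. = FALSE)
  pars <- expand.grid(e = c("11", "12", "22"), ci = names(Cs),
                      stringsAsFactors = FALSE)[, c("ci", "e")]
  pars <- pars[order(match(pars$ci, names(Cs))), ]
  np <- nrow(pars)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    U <- matrix(0, 2 * n, np)
    trPV <- numeric(np)
    for (k in seq_len(np)) {
      U[, k] <- mult_z(pars$ci[k], pars$e[k], st$Py)
      trPV[k] <- tr_P(st$P, pars$ci[k], pars$e[k])
    }
    yPVPy <- as.numeric(crossprod(U, st$Py))
    grad <- -0.5 * (trPV - yPVPy)
    AI <- 0.5 * crossprod(U, st$P %*% U)
    if (sqrt(sum(grad^2)) < 1e-6) { converged <- TRUE; break }
    delta <- tryCatch(solve(AI, grad), error = function(e) NULL)
    theta <- theta_of(blocks)
    new_st <- NULL; new_blocks <- NULL
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:10) {
        bl <- lapply(blocks_of(theta + step * delta), proj_psd, fl = floor_)
        bl$residual <- proj_psd(bl$residual, 1e-6 * vy)
        cst <- eval_state(bl)
        if (!is.null(cst) && cst$loglik >= st$loglik - 1e-10) {
          new_st <- cst; new_blocks <- bl; break
        }
        step <- step / 2
      }
    }
    if (is.null(new_st)) {
      ## scaled-gradient fallback
      sc <- 0.1 * max(abs(theta)) / max(abs(grad))
      for (h in 1:10) {
        bl <- lapply(blocks_of(theta + sc * grad), proj_psd, fl = floor_)
        bl$residual <- proj_psd(bl$residual, 1e-6 * vy)
        cst <- eval_state(bl)
        if (!is.null(cst) && cst$loglik > st$loglik) {
          new_st <- cst; new_blocks <- bl; break
        }
        sc <- sc / 2
      }
    }
    if (is.null(new_st)) { converged <- TRUE; break }  # no ascent possible
    dll <- new_st$loglik - st$loglik
    blocks <- new_blocks; st <- new_st
    if (abs(dll) < tol_loglik) { converged <- TRUE; break }
  }
  if (!converged)
    stop("bivariate REML did not converge in ", max_iter, " iterations",
         call. = FALSE)

  A <- blocks$additive
  rg <- A[1, 2] / sqrt(A[1, 1] * A[2, 2])
  rg <- max(min(rg, 1), -1)

  ## delta-method SE on (a11, a12, a22)
  U <- matrix(0, 2 * n, np)
  for (k in seq_len(np)) U[, k] <- mult_z(pars$ci[k], pars$e[k], st$Py)
  AI <- 0.5 * crossprod(U, st$P %*% U)
  se <- NA_real_
  ai_inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(ai_inv)) {
    ia <- which(pars$ci == "additive")
    Va <- ai_inv[ia, ia]
    a <- A[1, 1]; b <- A[2, 2]; cc <- A[1, 2]
    g <- c(-cc / (2 * a^1.5 * sqrt(b)), 1 / sqrt(a * b),
           -cc / (2 * b^1.5 * sqrt(a)))
    v <- drop(t(g) %*% Va %*% g)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  structure(list(rg = rg, se = se, blocks = blocks, loglik = st$loglik,
                 n = n, iterations = it, n_projections = n_proj),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("<genetic_correlation> rg = %.3f (SE %s), n = %d, loglik = %s\n",
              x$rg, if (is.na(x$se)) "NA" else sprintf("%.3f", x$se),
              x$n, format(x$loglik)))
  invisible(x)
}
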