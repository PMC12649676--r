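#' Restricted maximum likelihood for a variance-component mixed model
#'
#' Average-information REML for the model
#' \eqn{y = X\beta + \sum_k u_k + e}, where each random term has covariance
#' \eqn{\sigma_k^2 V_k} (supplied as dense structure matrices, e.g. a
#' relationship matrix for the additive term or a litter-incidence
#' cross-product) and \eqn{e \sim N(0, \sigma_e^2 I)}. AI updates are taken
#' with step halving; when an update would leave the parameter space or
#' decrease the restricted likelihood, the iteration falls back to the EM
#' fixed-point update, which cannot go negative. Components are constrained
#' non-negative, with a small floor relative to `var(y)` acting as the
#' boundary.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix (full column rank; default
#'   intercept only).
#' @param random named list of n x n PSD structure matrices.
#' @param init optional starting values (one per random term + residual).
#' @param max_iter maximum iterations.
#' @param tol_loglik convergence threshold on the restricted log-likelihood
#'   change (default 1e-8).
#' @param tol_grad convergence threshold on the gradient norm.
#' @param verbose print per-iteration progress.
#' @return list of class `reml_fit`: `sigma2` (named vector incl.
#'   `residual`), `loglik`, `ai_inv` (asymptotic covariance of the
#'   estimates), `iterations`, `converged`, `trajectory`, `n`, `Py`, `V_logdet`.
#' @export
reml_fit <- function(y, X = NULL, random, init = NULL, max_iter = 100,
                     tol_loglik = 1e-8, tol_grad = 1e-6, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must not contain missing values", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  stopifnot(nrow(X) == n, all(vapply(random, function(M)
    all(dim(M) == c(n, n)), logical(1))))

  K <- length(random)
  nm <- c(names(random), "residual")
  vy <- stats::var(y)
  floor_ <- 1e-6 * vy
  theta <- if (is.null(init)) rep(vy / (K + 1), K + 1) else as.numeric(init)
  theta <- pmax(theta, floor_)

  eval_state <- function(theta) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * random[[k]]
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
    list(P = P, Py = Py, loglik = ll, V_logdet = 2 * sum(log(diag(ch))))
  }

  st <- eval_state(theta)
  if (is.null(st)) stop("initial variance matrix not positive definite",
                        call. = FALSE)
  traj <- st$loglik
  converged <- FALSE
  it <- 0

  for (it in seq_len(max_iter)) {
    ## gradient and AI matrix
    U <- matrix(0, n, K + 1)        # V_k P y
    trPV <- numeric(K + 1)
    for (k in seq_len(K)) {
      U[, k] <- random[[k]] %*% st$Py
      trPV[k] <- sum(st$P * random[[k]])
    }
    U[, K + 1] <- st$Py
    trPV[K + 1] <- sum(diag(st$P))
    yPVPy <- as.numeric(crossprod(U, st$Py))
    grad <- -0.5 * (trPV - yPVPy)
    AI <- 0.5 * crossprod(U, st$P %*% U)

    ## boundary-aware gradient test: a component pinned at its floor with a
    ## negative gradient is at the constrained optimum, not a failure
    free <- !(theta <= floor_ * 1.001 & grad < 0)
    if (sqrt(sum(grad[free]^2)) < tol_grad) { converged <- TRUE; break }

    ## AI step over the free components only (boundary components stay
    ## pinned), with halving and an EM fallback
    delta <- tryCatch({
      d <- numeric(K + 1)
      d[free] <- solve(AI[free, free, drop = FALSE], grad[free])
      d
    }, error = function(e) NULL)
    new_st <- NULL; new_theta <- NULL
    ai_step <- FALSE
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:8) {
        cand <- pmax(theta + step * delta, floor_)
        cst <- eval_state(cand)
        if (!is.null(cst) && cst$loglik >= st$loglik - 1e-10) {
          new_st <- cst; new_theta <- cand; ai_step <- TRUE; break
        }
        step <- step / 2
      }
    }
    if (is.null(new_st)) {
      ## EM fixed point: sigma_k^2 <- sigma_k^2 * yPVPy_k / tr(P V_k)
      cand <- pmax(theta * yPVPy / pmax(trPV, 1e-12), floor_)
      cst <- eval_state(cand)
      if (is.null(cst))
        stop("REML failed: non-positive-definite update at iteration ", it,
             "; trajectory: ", paste(signif(traj, 8), collapse = ", "),
             call. = FALSE)
      new_st <- cst; new_theta <- cand
    }
    dll <- new_st$loglik - st$loglik
    dtheta <- max(abs(new_theta - theta))
    theta <- new_theta; st <- new_st
    traj <- c(traj, st$loglik)
    if (verbose)
      message(sprintf("iter %d  loglik %.6f  theta %s", it, st$loglik,
                      paste(signif(theta, 4), collapse = " ")))
    ## EM steps converge only linearly: a small likelihood change after one
    ## does not certify an optimum, so only AI steps can stop the iteration
    if ((ai_step && abs(dll) < tol_loglik) || dtheta < 1e-12 * vy) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter, " iterations; trajectory: ",
         paste(signif(utils::tail(traj, 5), 8), collapse = ", "),
         call. = FALSE)

  ## refresh AI at the optimum for standard errors; components pinned at the
  ## boundary are treated as known (zero rows/cols in the covariance)
  U <- matrix(0, n, K + 1)
  for (k in seq_len(K)) U[, k] <- random[[k]] %*% st$Py
  U[, K + 1] <- st$Py
  AI <- 0.5 * crossprod(U, st$P %*% U)
  free <- theta > floor_ * 1.001
  ai_inv <- matrix(0, K + 1, K + 1, dimnames = list(nm, nm))
  ai_free <- tryCatch(solve(AI[free, free, drop = FALSE]),
                      error = function(e) NULL)
  if (is.null(ai_free)) {
    ai_inv[] <- NA_real_
  } else {
    ai_inv[free, free] <- ai_free
  }

  structure(list(sigma2 = stats::setNames(theta, nm), loglik = st$loglik,
                 ai_inv = ai_inv, iterations = it, converged = converged,
                 trajectory = traj, n = n, Py = as.numeric(st$Py),
                 V_logdet = st$V_logdet),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> n =", x$n, " loglik =", format(x$loglik), "\n")
  print(signif(x$sigma2, 5))
  invisible(x)
}

#' Fit the animal model for one trait and report heritability
#'
#' Single-trait animal model with fixed effects (by default pen x batch,
#' breed and sex), a random additive-genetic effect with covariance
#' proportional to the supplied relationship matrix, an optional random
#' litter effect, and a residual. Narrow-sense heritability is
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_{litter}^2 + \sigma_e^2)};
#' its standard error comes from the delta method on the inverse
#' average-information matrix.
#'
#' @param pheno data.frame with `animal_id`, the trait column and covariate
#'   columns.
#' @param trait name of the trait column.
#' @param K relationship matrix (pedigree A or genomic G) with animal ids
#'   as dimnames; may be larger than the phenotyped set.
#' @param fixed character vector of fixed-effect columns (factors); use
#'   `character(0)` for an intercept-only model.
#' @param litter name of the litter column, or NULL to omit.
#' @param ... passed to [reml_fit()].
#' @return list of class `animal_model_fit`: `sigma2_a`, `sigma2_litter`,
#'   `sigma2_e`, `h2`, `se_h2`, `loglik`, `n`, `reml`.
#' @export
fit_animal_model <- function(pheno, trait, K,
                             fixed = c("pen_batch", "breed", "sex"),
                             litter = "litter", ...) {
  stopifnot(trait %in% names(pheno), "animal_id" %in% names(pheno))
  d <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  ids <- as.character(d$animal_id)
  miss <- setdiff(ids, rownames(K))
  if (length(miss))
    stop("animals absent from relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  y <- d[[trait]]
  X <- if (length(fixed)) {
    f <- stats::as.formula(paste("~", paste(fixed, collapse = " + ")))
    stats::model.matrix(f, data = as.data.frame(
      lapply(d[fixed], function(col) factor(col))))
  } else matrix(1, length(y), 1)

  random <- list(additive = K[ids, ids])
  if (!is.null(litter) && litter %in% names(d)) {
    li <- as.character(d[[litter]])
    random$litter <- outer(li, li, "==") * 1
  }
  fit <- reml_fit(y, X, random, ...)
  s <- fit$sigma2
  tot <- sum(s)
  h2 <- unname(s["additive"] / tot)
  g <- rep(-s["additive"] / tot^2, length(s))
  g[1] <- (tot - s["additive"]) / tot^2
  se_h2 <- if (!anyNA(fit$ai_inv)) sqrt(drop(t(g) %*% fit$ai_inv %*% g)) else NA
  structure(list(sigma2_a = unname(s["additive"]),
                 sigma2_litter = unname(s["litter"]),
                 sigma2_e = unname(s["residual"]),
                 h2 = h2, se_h2 = se_h2, loglik = fit$loglik,
                 n = fit$n, reml = fit),
            class = "animal_model_fit")
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat(sprintf("<animal_model_fit> n = %d  h2 = %.3f (SE %.3f)\n",
              x$n, x$h2, x$se_h2))
  cat(sprintf("  sigma2: additive %.4g  litter %s  residual %.4g\n",
              x$sigma2_a,
              if (is.na(x$sigma2_litter)) "-" else signif(x$sigma2_litter, 4),
              x$sigma2_e))
  invisible(x)
}
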