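# Shared fixtures, built in code at test time.

# cross-test scratch space (e.g. a cohort reused by consecutive checks)
.fixture_cache <- new.env(parent = emptyenv())

# small population + feeder run, memoised within a test session
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(n_animals = 40, n_snps = 200, seed = 42, ...) {
    key <- paste(n_animals, n_snps, seed, ...)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(n_animals = n_animals, n_snps = n_snps, seed = seed, ...)
    pop <- simulate_population(cfg)
    feeder <- simulate_feeder_series(cfg, pop)
    cache[[key]] <- list(cfg = cfg, pop = pop, feeder = feeder)
    cache[[key]]
  }
})

# exact pinball loss, used by quantile-regression oracles
pinball_loss <- function(b0, b1, x, y, tau) {
  r <- y - b0 - b1 * x
  sum(r * (tau - (r < 0)))
}

# brute-force quantile line: enumerate all lines through point pairs
# (the basic solutions of the LP) and return the minimal loss
pair_enum_quantile <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b1 <- (y[j] - y[i]) / (x[j] - x[i])
    b0 <- y[i] - b1 * x[i]
    best <- min(best, pinball_loss(b0, b1, x, y, tau))
  }
  best
}

# recursive-definition oracle for the numerator relationship matrix;
# pedigree rows must be parent-before-offspring, parents NA when unknown
recursive_A <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  s <- idx[ped$sire]; d <- idx[ped$dam]
  memo <- new.env(parent = emptyenv())
  a <- function(i, j) {
    if (i > j) return(a(j, i))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * a(s[i], d[i]) else 0
    } else {
      # j is the younger animal by construction (i <= j)
      0.5 * ((if (!is.na(s[j])) a(i, s[j]) else 0) +
               (if (!is.na(d[j])) a(i, d[j]) else 0))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# random acyclic pedigree of n animals (parents always earlier or unknown)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ped <- data.frame(id = paste0("p", seq_len(n)),
                    sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in 3:n) {
    if (runif(1) < 0.7) {
      pr <- sample(i - 1, 2)
      ped$sire[i] <- ped$id[pr[1]]
      ped$dam[i] <- ped$id[pr[2]]
    }
  }
  ped
}

# restricted log-likelihood evaluated from first principles (dense algebra,
# generic solve); independent of the package's REML internals
reml_loglik_direct <- function(theta, y, X, structures) {
  n <- length(y)
  V <- theta[length(theta)] * diag(n)
  for (k in seq_along(structures)) V <- V + theta[k] * structures[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}
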