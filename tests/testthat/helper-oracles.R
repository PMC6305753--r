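# Independent oracles used across the test suite.  These deliberately avoid
# the package's own computational paths.

# all-pairs leaf distances by Floyd-Warshall over the tree graph
brute_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  d <- matrix(Inf, nn, nn)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1L]; j <- tree$edge[e, 2L]
    d[i, j] <- d[j, i] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) for (j in seq_len(nn))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  out <- d[seq_len(nt), seq_len(nt)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# dense grid search for the scalar MCP subproblem
grid_argmin_scalar <- function(a, b, lambda1, gamma,
                               lo = -10, hi = 10, step = 2e-5) {
  t <- seq(lo, hi, by = step)
  f <- a / 2 * t^2 - b * t + mcp_penalty(t, lambda1, gamma)
  t[which.min(f)]
}

# term-by-term naive recomputation of the penalized objective
naive_objective <- function(intercept, beta, Xs, y, family,
                            lambda1, gamma, lambda2, Omega) {
  n <- length(y)
  loss <- 0
  for (i in seq_len(n)) {
    eta <- intercept + sum(Xs[i, ] * beta)
    loss <- loss + if (family == "gaussian") (y[i] - eta)^2 / 2
                   else log(1 + exp(eta)) - y[i] * eta
  }
  pen <- 0
  for (j in seq_along(beta)) {
    t <- abs(beta[j])
    pen <- pen + if (t <= gamma * lambda1) lambda1 * t - t^2 / (2 * gamma)
                 else gamma * lambda1^2 / 2
  }
  quad <- 0
  if (lambda2 > 0)
    for (j in seq_along(beta)) for (k in seq_along(beta))
      quad <- quad + lambda2 * beta[j] * Omega[j, k] * beta[k]
  loss / n + pen + quad
}

# multi-start general-purpose optimizer for the same objective
optim_objective <- function(Xs, y, family, lambda1, gamma, lambda2, Omega,
                            starts = NULL) {
  p <- ncol(Xs)
  obj <- function(th) penalized_objective(th[1L], th[-1L], Xs, y, family,
                                          lambda1, gamma, lambda2, Omega)
  if (is.null(starts)) {
    s0 <- rep(0, p + 1)
    s1 <- c(mean(y), rep(0.1, p))
    ridge <- solve(crossprod(Xs) + diag(p), crossprod(Xs, y - mean(y)))
    s2 <- c(mean(y), as.numeric(ridge))
    starts <- list(s0, s1, s2)
  }
  best <- Inf
  for (s in starts) {
    o <- optim(s, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# block-diagonal inverse-correlation matrix of disjoint cliques
clique_omega <- function(sizes, Omega0, kappa) {
  p <- sum(sizes)
  Om <- matrix(0, p, p)
  off <- 0
  for (g in seq_along(sizes)) {
    v <- sizes[g]
    idx <- off + seq_len(v)
    Om[idx, idx] <- -Omega0[g]
    diag(Om)[idx] <- kappa[g] * (v - 1) * Omega0[g]
    off <- off + v
  }
  Om
}

# grouping-bound factor (reconstructed reading of the printed formula)
xi_factor <- function(t, gamma) {
  if (gamma * t > 1)
    max(2 * gamma / (gamma * t - 1), (gamma * t + 1) / (t * (gamma * t - 1)),
        1 / t)
  else 1 / t
}

# largest within-clique coefficient spread of a fit
clique_spread <- function(beta, sizes) {
  off <- 0; mx <- 0
  for (v in sizes) {
    idx <- off + seq_len(v)
    mx <- max(mx, max(beta[idx]) - min(beta[idx]))
    off <- off + v
  }
  mx
}

# small random regression problem
rand_problem <- function(n, p, seed, family = "gaussian") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("OTU", seq_len(p))
  beta <- numeric(p)
  beta[seq_len(min(3, p))] <- c(1, -0.5, 0.25)[seq_len(min(3, p))]
  eta <- X %*% beta
  y <- if (family == "gaussian") as.numeric(eta + rnorm(n))
       else rbinom(n, 1L, plogis(as.numeric(eta)))
  list(X = X, y = y, beta = beta)
}
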