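test_that("standardization centers and scales to sum of squares n", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 0, 1))
  dm <- standardize(X)
  expect_equal(dm$X[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(colSums(dm$X), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(colSums(dm$X^2), c(a = 3, b = 3), tolerance = 1e-12)

  # idempotence on an already-standardized design
  expect_identical(standardize(dm), dm)

  set.seed(1)
  Xr <- matrix(rnorm(200), 20, 10)
  dmr <- standardize(Xr)
  expect_lt(max(abs(colSums(dmr$X))), 1e-8)
  expect_lt(max(abs(colSums(dmr$X^2) - 20)), 1e-8)

  Xc <- cbind(OTUa = rnorm(5), OTUbad = rep(2, 5))
  expect_error(standardize(Xc), "OTUbad")
  dmz <- standardize(Xc, constant = "zero")
  expect_equal(dmz$X[, "OTUbad"], rep(0, 5))
  expect_equal(dmz$constant, c(OTUbad = 2L))
})

test_that("MCP penalty has the piecewise closed form", {
  expect_equal(mcp_penalty(0, 1, 3), 0)
  expect_equal(mcp_penalty(1, 1, 3), 1 - 1 / 6)
  # saturation at gamma * lambda1^2 / 2 beyond gamma * lambda1
  expect_equal(mcp_penalty(5, 1, 3), 1.5)
  expect_equal(mcp_penalty(100, 1, 3), 1.5)
  expect_equal(mcp_penalty(-1, 1, 3), mcp_penalty(1, 1, 3))
  expect_error(mcp_penalty(1, 1, 1), "gamma")
})

test_that("quadratic penalty matches its Laplacian-plus-weighted-l2 split", {
  expect_equal(quadratic_penalty(numeric(3), diag(3), 1), 0)
  expect_equal(quadratic_penalty(c(1, 2), diag(2), 1), 5)
  expect_error(quadratic_penalty(c(1, 2), diag(3), 1), "dimensions")

  # beta' Omega beta = sum_i (Omega_ii - sum_{j != i} |Omega_ij|) beta_i^2
  #                  + sum_{j<k} |Omega_jk| (beta_j - s_jk beta_k)^2
  set.seed(2)
  for (rep in 1:100) {
    p <- sample(3:12, 1)
    tree <- simulate_tree(p)
    Om <- correlation_structure(patristic_distances(tree),
                                runif(1, 0.2, 3))$Omega
    beta <- rnorm(p)
    lhs <- quadratic_penalty(beta, Om, 1)
    w <- diag(Om) - (rowSums(abs(Om)) - abs(diag(Om)))
    rhs <- sum(w * beta^2)
    for (j in 1:(p - 1)) for (k in (j + 1):p) {
      s <- sign(-Om[j, k])
      rhs <- rhs + abs(Om[j, k]) * (beta[j] - s * beta[k])^2
    }
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("scalar update solves the one-dimensional subproblem", {
  expect_equal(scalar_update(1, 0.5, 1, 3), 0)           # dead zone
  expect_equal(scalar_update(1, 2, 1, 3), 1.5)           # firm threshold
  expect_equal(scalar_update(1, 4, 1, 3), 4.0)           # unpenalized region
  expect_error(scalar_update(0.2, 1, 1, 3), "1/gamma")

  set.seed(3)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 3)
    g <- runif(1, 1.5, 8)
    if (a <= 1 / g) next
    b <- runif(1, -5, 5)
    l1 <- runif(1, 0, 1.5)
    expect_equal(scalar_update(a, b, l1, g),
                 grid_argmin_scalar(a, b, l1, g), tolerance = 2e-4)
  }
})

test_that("penalized objective matches a naive term-by-term oracle", {
  set.seed(4)
  n <- 25; p <- 6
  pb <- rand_problem(n, p, 4)
  dm <- standardize(pb$X)
  # beta = 0 closed forms
  expect_equal(penalized_objective(mean(pb$y), numeric(p), dm, pb$y,
                                   "gaussian", 0.5, 3),
               mean((pb$y - mean(pb$y))^2) / 2)
  yb <- rbinom(n, 1, 0.5)
  expect_equal(penalized_objective(0, numeric(p), dm, yb, "binomial", 0.5, 30),
               log(2))
  # random configurations
  Om <- correlation_structure(patristic_distances(simulate_tree(p)), 1)$Omega
  for (rep in 1:5) {
    beta <- rnorm(p, sd = 0.5)
    b0 <- rnorm(1)
    expect_equal(
      penalized_objective(b0, beta, dm, pb$y, "gaussian", 0.3, 3, 0.7, Om),
      naive_objective(b0, beta, dm$X, pb$y, "gaussian", 0.3, 3, 0.7, Om),
      tolerance = 1e-10)
    expect_equal(
      penalized_objective(b0, beta, dm, yb, "binomial", 0.3, 30, 0.7, Om),
      naive_objective(b0, beta, dm$X, yb, "binomial", 0.3, 30, 0.7, Om),
      tolerance = 1e-10)
  }
  expect_error(penalized_objective(0, numeric(p), dm, pb$y + 0.5, "binomial",
                                   0.1, 30), "0/1")
})

test_that("the solver reproduces closed-form solutions", {
  pb <- rand_problem(50, 5, 11)
  # above lambda1_max with no smoothing: fully sparse solution
  lmax <- lambda1_max(pb$X, pb$y)
  f0 <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 1.01 * lmax)
  expect_equal(unname(f0$beta_std), rep(0, 5))
  expect_equal(f0$intercept_std, mean(pb$y))
  # unpenalized: ordinary least squares by normal equations
  f <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 0)
  dm <- standardize(pb$X)
  ols <- solve(crossprod(dm$X), crossprod(dm$X, pb$y - mean(pb$y)))
  expect_equal(unname(f$beta_std), as.numeric(ols), tolerance = 1e-6)
})

test_that("the objective is nonincreasing over sweeps and beats BFGS", {
  set.seed(12)
  tree <- simulate_tree(4)
  Om <- correlation_structure(patristic_distances(tree), 1)$Omega
  pb <- rand_problem(30, 4, 12)
  f <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 0.1, lambda2 = 0.5,
                structure = Om, trace = TRUE)
  expect_true(all(diff(f$objective_trace) <= 1e-12))
  dm <- standardize(pb$X)
  obj_cd <- penalized_objective(f$intercept_std, f$beta_std, dm, pb$y,
                                "gaussian", 0.1, 3, 0.5, Om)
  obj_opt <- optim_objective(dm$X, pb$y, "gaussian", 0.1, 3, 0.5, Om)
  expect_lt(obj_cd, obj_opt + 1e-5)
})

test_that("warm-started paths match cold starts and grow mostly monotonely", {
  pb <- rand_problem(40, 8, 13)
  ctl <- sics_control(tol = 1e-8)
  lmax <- lambda1_max(pb$X, pb$y)
  lam <- lambda1_sequence(lmax, 25, 0.05)
  pth <- fit_sics_path(pb$X, pb$y, "gaussian", lam, control = ctl)
  # single-element path identical to fit()
  f1 <- fit_sics(pb$X, pb$y, "gaussian", lam[10], control = ctl)
  cold <- sapply(seq_along(lam), function(l)
    fit_sics(pb$X, pb$y, "gaussian", lam[l], control = ctl)$beta_std)
  expect_lt(max(abs(pth$beta_std - cold)), 1e-5)
  expect_equal(pth$beta_std[, 10], f1$beta_std, tolerance = 1e-6)
  # support grows along the path in nearly all adjacent steps
  nnz <- colSums(pth$beta_std != 0)
  expect_gte(mean(diff(nnz) >= 0), 0.9)
  expect_error(fit_sics_path(pb$X, pb$y, "gaussian", rev(lam)), "decreasing")
})

test_that("predictions are consistent across scales and families", {
  pb <- rand_problem(40, 6, 14)
  f <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 0.05)
  # in-sample predictions equal standardized-scale fitted values
  dm <- standardize(pb$X)
  expect_equal(predict(f, pb$X),
               as.numeric(f$intercept_std + dm$X %*% f$beta_std),
               tolerance = 1e-10)
  # all-zero fit: constant prediction at the intercept
  lmax <- lambda1_max(pb$X, pb$y)
  f0 <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 2 * lmax)
  expect_equal(predict(f0, pb$X), rep(mean(pb$y), 40))
  # logistic: eta = 0 maps to probability one half
  pbb <- rand_problem(60, 4, 15, family = "binomial")
  fb <- fit_sics(pbb$X, pbb$y, "binomial", lambda1 = 0.05)
  zero_x <- matrix(0, 1, 4, dimnames = list(NULL, colnames(pbb$X)))
  eta0 <- predict(fb, zero_x, type = "link")
  expect_equal(predict(fb, zero_x), plogis(eta0))
  expect_error(predict(f, pb$X[, 1:3]), "columns")
})

test_that("unpenalized logistic fits agree with glm", {
  pbb <- rand_problem(80, 4, 16, family = "binomial")
  dm <- standardize(pbb$X)
  f <- fit_sics(pbb$X, pbb$y, "binomial", lambda1 = 0,
                control = sics_control(tol = 1e-7, max_outer = 500))
  g <- glm(pbb$y ~ dm$X, family = binomial)
  expect_equal(unname(f$beta_std), unname(coef(g)[-1]), tolerance = 1e-4)
  expect_equal(f$intercept_std, unname(coef(g)[1]), tolerance = 1e-4)
})

test_that("coefficients are not rescaled to undo l2 shrinkage", {
  # with structure = I the ridge component shrinks coefficients; an
  # Enet-style (1 + 2 lambda2) rescaling must NOT be applied
  pb <- rand_problem(50, 5, 17)
  lam2 <- 0.8
  f <- fit_sics(pb$X, pb$y, "gaussian", lambda1 = 0, lambda2 = lam2,
                structure = "identity")
  dm <- standardize(pb$X)
  raw <- solve(crossprod(dm$X) / 50 + diag(2 * lam2, 5),
               crossprod(dm$X, pb$y - mean(pb$y)) / 50)
  expect_equal(unname(f$beta_std), as.numeric(raw), tolerance = 1e-5)
  rescaled <- (1 + 2 * lam2) * raw
  expect_gt(max(abs(f$beta_std - rescaled)), 0.05 * max(abs(rescaled)))
})

test_that("constant-at-zero columns stay at exactly zero along the path", {
  pb <- rand_problem(30, 5, 18)
  X <- cbind(pb$X, OTUzero = 0)
  pth <- fit_sics_path(X, pb$y, "gaussian",
                       lambda1_sequence(lambda1_max(X, pb$y), 10, 0.05))
  expect_true(all(pth$beta_std["OTUzero", ] == 0))
  expect_true(all(pth$beta_orig["OTUzero", ] == 0))
})
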