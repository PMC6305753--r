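test_that("coalescent trees are reproducible, positive and ultrametric", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_gt(patristic_distances(tr2)[1, 2], 0)

  ta <- simulate_tree(200, seed = 5)
  tb <- simulate_tree(200, seed = 5)
  expect_identical(ta$tip.label, tb$tip.label)
  expect_equal(patristic_distances(ta), patristic_distances(tb))

  depths <- ape::node.depth.edgelength(ta)[seq_len(200)]
  expect_lt(diff(range(depths)), 1e-8)        # all tips equidistant from root
  D <- patristic_distances(ta)
  expect_true(all(is.finite(D)) && mean(D[upper.tri(D)]) > 0)
})

test_that("dirichlet-multinomial counts respect depth and composition", {
  set.seed(10)
  pars <- dm_params(setNames(lognormal_proportions(30, 1), paste0("OTU", 1:30)))
  sc <- sample_counts(pars, 50)
  expect_true(all(sc$counts >= 0))
  expect_true(all(abs(rowSums(sc$proportions) - 1) < 1e-12))
  expect_equal(rowSums(sc$counts), rowSums(sc$counts))  # integer conservation
  # depth model: mean 5000 within 1% over many samples
  big <- sample_counts(pars, 10000, seed = 2)
  expect_lt(abs(mean(rowSums(big$counts)) - 5000) / 5000, 0.01)
})

test_that("per-OTU mean proportions match the DM moments", {
  set.seed(12)
  p <- 25
  pars <- dm_params(setNames(lognormal_proportions(p, 1), paste0("OTU", 1:p)),
                    theta = 0.02)
  sc <- sample_counts(pars, 5000)
  phat <- colMeans(sc$proportions)
  N <- rowSums(sc$counts)
  # Var(p_ij) = pi (1 - pi) (theta + (1 - theta) E[1/N])
  vr <- pars$proportions * (1 - pars$proportions) *
    (pars$theta + (1 - pars$theta) * mean(1 / N))
  se <- sqrt(vr / 5000)
  expect_true(all(abs(phat - pars$proportions) < 3 * se))
})

test_that("DM parameters are recovered by the moment estimator", {
  set.seed(11)
  pi0 <- setNames(lognormal_proportions(50, 1), paste0("OTU", 1:50))
  cnt <- sample_counts(dm_params(pi0, theta = 0.02), 2000)$counts
  est <- estimate_dm_params(cnt)
  expect_lt(abs(est$theta - 0.02) / 0.02, 0.2)
  expect_lt(max(abs(est$proportions - pi0)), 0.005)

  # multinomial limit: dispersion estimate collapses to (near) zero
  cnt0 <- sample_counts(dm_params(pi0, theta = 1e-6), 2000)$counts
  expect_lte(estimate_dm_params(cnt0)$theta, 0.005)

  expect_error(estimate_dm_params(matrix(5, 3, 1)), "at least 2")
  expect_error(estimate_dm_params(matrix(0L, 4, 4)), "zero")
})

test_that("PAM partitions match exhaustive medoid search on small problems", {
  D1 <- patristic_distances(simulate_tree(7, seed = 3))
  expect_equal(unname(pam_partition(D1, 1)), rep(1L, 7))
  expect_error(pam_partition(D1, 10), "exceed")

  # two well-separated clades: clusters recover the clades
  tr <- ape::read.tree(
    text = "((A:.1,B:.1):5,(C:.1,(D:.1,E:.1):.1):5);")
  D2 <- patristic_distances(tr)
  cl <- pam_partition(D2, 2)
  expect_length(unique(cl[c("A", "B")]), 1)
  expect_length(unique(cl[c("C", "D", "E")]), 1)
  expect_false(cl["A"] == cl["C"])

  # exhaustive two-medoid oracle on p = 8
  D3 <- patristic_distances(simulate_tree(8, seed = 9))
  cl3 <- pam_partition(D3, 2)
  cost_impl <- sum(vapply(unique(cl3), function(g) {
    idx <- which(cl3 == g)
    min(colSums(D3[idx, idx, drop = FALSE]))
  }, numeric(1)))
  best <- Inf
  for (m1 in 1:7) for (m2 in (m1 + 1):8)
    best <- min(best, sum(pmin(D3[, m1], D3[, m2])))
  expect_equal(cost_impl, best, tolerance = 1e-10)
})

test_that("scenarios place associated OTUs per their contracts", {
  set.seed(13)
  tree <- simulate_tree(200)
  labels <- pam_partition(patristic_distances(tree), 20)

  s1 <- designate_aotus(labels, "S1", seed = 1)
  expect_length(s1$A, 12)
  expect_length(unique(labels[s1$A]), 1)
  expect_true(all(s1$signs == 1) && all(s1$magnitudes == 1))

  s2 <- designate_aotus(labels, "S2", seed = 1)
  expect_length(unique(labels[s2$A]), 1)
  expect_true(all(s2$magnitudes >= 0.5 & s2$magnitudes <= 1.5))
  expect_gt(diff(range(s2$magnitudes)), 0)

  s3 <- designate_aotus(labels, "S3", seed = 1)
  expect_length(unique(labels[s3$A]), 12)

  s4 <- designate_aotus(labels, "S4", seed = 1)
  expect_equal(sum(s4$signs == 1), 6)
  expect_equal(sum(s4$signs == -1), 6)

  # unsatisfiable constraints fail loudly
  expect_error(designate_aotus(setNames(1:30, paste0("OTU", 1:30)), "S1"),
               "no cluster")
  expect_error(designate_aotus(setNames(rep(1:2, 15), paste0("OTU", 1:30)),
                               "S3"), "clusters")
})

test_that("outcome generation calibrates the signal strength exactly", {
  set.seed(14)
  x <- sample_counts(dm_params(setNames(lognormal_proportions(40, 1),
                                        paste0("OTU", 1:40))), 80)$proportions
  A <- c(3, 7, 11, 20)
  # continuous: sd(eta) / sigma equals the requested level
  out <- generate_outcome(x, A, rep(1, 4), rep(1, 4), "gaussian", 2.0)
  expect_equal(out$realized_signal, 2.0, tolerance = 1e-8)
  expect_equal(sd(out$beta0 + x %*% out$beta_true) / out$sigma_eps, 2.0,
               tolerance = 1e-8)
  expect_true(all(out$beta_true[-A] == 0))
  # binary: sum var(x_j) beta_j^2 equals the requested level
  outb <- generate_outcome(x, A, c(1, 1, -1, 1), rep(1, 4), "binomial", 20)
  vx <- apply(x[, A], 2, var)
  expect_equal(sum(vx * outb$beta_true[A]^2), 20, tolerance = 1e-8)
  expect_equal(outb$realized_signal, 20, tolerance = 1e-8)
  expect_true(all(outb$y %in% c(0, 1)))
  # empty-effect control: pure noise
  out0 <- generate_outcome(x, A, rep(0, 4), rep(0, 4), "gaussian", 2.0)
  expect_equal(out0$realized_signal, 0)
  expect_true(all(out0$beta_true == 0))
})

test_that("end-to-end datasets have the standard study dimensions", {
  sim <- make_dataset("S1", "gaussian", "L", seed = 17)
  expect_equal(dim(sim$proportions_train), c(100, 200))
  expect_equal(dim(sim$proportions_test), c(200, 200))
  expect_length(sim$A, 12)
  expect_equal(sum(sim$beta_true != 0), 12)
  expect_equal(sim$realized_signal, 2.0, tolerance = 1e-8)

  simb <- make_dataset("S1", "binomial", "M", seed = 18)
  expect_equal(sum(simb$y_train == 1), 50)
  expect_equal(sum(simb$y_train == 0), 50)
  expect_equal(sum(simb$y_test == 1), 100)
  expect_equal(sum(simb$y_test == 0), 100)
  expect_equal(simb$realized_signal, 10, tolerance = 1e-8)

  # identical seeds give bitwise-identical datasets
  a <- make_dataset("S3", "gaussian", "S", seed = 19)
  b <- make_dataset("S3", "gaussian", "S", seed = 19)
  expect_identical(a$counts_train, b$counts_train)
  expect_identical(a$y_test, b$y_test)
  expect_identical(a$A, b$A)

  # scenario contract: S3 spans 12 clusters, S1 spans one
  expect_length(unique(a$cluster_labels[a$A]), 12)
  expect_length(unique(sim$cluster_labels[sim$A]), 1)
})
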