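#' Simulate a random coalescent phylogeny
#'
#' Random coalescent tree with exponential waiting times (via
#' \code{ape::rcoal}), the standard null model for an OTU phylogeny in
#' simulation studies.  Tips are labelled \code{OTU1..OTUp}.
#'
#' @param p number of leaves (>= 2).
#' @param seed optional integer seed.
#' @export
simulate_tree <- function(p, seed = NULL) {
  if (p < 2) stop("`p` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(p, tip.label = paste0("OTU", seq_len(p)))
}

#' Dirichlet-multinomial parameter set
#'
#' Container for the count simulator: mean OTU proportions, an
#' overdispersion parameter \code{theta} in (0, 1), and a negative-binomial
#' sequencing-depth model with defaults mean 5,000 and dispersion 25
#' (a typical targeted-sequencing depth).
#'
#' @param proportions mean proportion vector, must sum to 1.
#' @param theta Dirichlet-multinomial overdispersion in (0, 1).
#' @param depth_mean,depth_dispersion negative-binomial library-size
#'   parameters (mean and size).
#' @export
dm_params <- function(proportions, theta = 0.02,
                      depth_mean = 5000, depth_dispersion = 25) {
  if (abs(sum(proportions) - 1) > 1e-10)
    stop("`proportions` must sum to 1")
  if (any(proportions <= 0)) stop("`proportions` must be strictly positive")
  if (theta <= 0 || theta >= 1) stop("`theta` must be in (0, 1)")
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop("depth parameters must be positive")
  structure(list(proportions = proportions, theta = theta,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion),
            class = "dm_params")
}

#' Default mean-proportion profile
#'
#' A log-normal abundance profile (log-sd 1.5, normalized to the simplex),
#' emulating the skewed mean abundances of the 200 most abundant OTUs of a
#' real upper-respiratory-tract community.  When a tree is supplied, the
#' log-abundances are drawn from a Brownian-motion model on it, so that
#' phylogenetically close OTUs have similar mean abundances — abundance is a
#' conserved trait, and profiles estimated from real communities carry this
#' autocorrelation; without it, a "phylogeny-informative" signal placed on a
#' clade would not actually be informative.  The marginal distribution is
#' log-normal with the same log-sd either way.  Random given the current RNG
#' state; use \code{estimate_dm_params} to substitute estimates from a real
#' count table.
#'
#' @param p number of OTUs (ignored when \code{tree} is given).
#' @param meanlog_sd marginal log-scale standard deviation of the profile.
#' @param tree optional \code{phylo} tree whose Brownian correlation shapes
#'   the profile.
#' @export
lognormal_proportions <- function(p, meanlog_sd = 1.5, tree = NULL) {
  if (is.null(tree)) {
    lw <- rnorm(p, 0, meanlog_sd)
  } else {
    R <- stats::cov2cor(ape::vcv.phylo(tree))
    p <- nrow(R)
    ch <- chol(R + diag(1e-10, p))
    lw <- meanlog_sd * as.numeric(crossprod(ch, rnorm(p)))
    names(lw) <- rownames(R)
    lw <- lw[tree$tip.label]
  }
  w <- exp(lw)
  w / sum(w)
}

#' Estimate Dirichlet-multinomial parameters from counts
#'
#' Method-of-moments: mean proportions from the pooled relative abundances;
#' the overdispersion \code{theta} from the DM identity
#' \eqn{Var(\hat p_{ij}) = \pi_j (1 - \pi_j)(\theta + (1 - \theta)/N_i)}
#' aggregated over OTUs.
#'
#' @param counts count matrix, samples x OTUs.
#' @return a \code{dm_params} object (depth model fitted by moments too).
#' @export
estimate_dm_params <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 samples and 2 OTUs")
  N <- rowSums(counts)
  if (all(N == 0)) stop("all-zero count table")
  if (any(N == 0)) stop("samples with zero total count: ",
                        paste(which(N == 0), collapse = ", "))
  pi_hat <- colSums(counts) / sum(counts)
  P <- counts / N
  V <- apply(P, 2L, var)
  mbar <- mean(1 / N)
  denom <- pi_hat * (1 - pi_hat)
  theta_hat <- (sum(V) - mbar * sum(denom)) / ((1 - mbar) * sum(denom))
  theta_hat <- min(max(theta_hat, 1e-8), 1 - 1e-8)
  # depth model by moments; fall back to a tiny floor if underdispersed
  size_hat <- if (var(N) > mean(N)) mean(N)^2 / (var(N) - mean(N)) else 1e6
  dm_params(proportions = pi_hat / sum(pi_hat), theta = theta_hat,
            depth_mean = mean(N), depth_dispersion = size_hat)
}

#' Sample OTU counts from the Dirichlet-multinomial model
#'
#' Per sample: a library size from the negative-binomial depth model, a
#' composition from Dirichlet(\eqn{\pi (1-\theta)/\theta}), and counts from
#' a multinomial at that depth.  Proportions are counts divided by the
#' library size.
#'
#' @param params a \code{dm_params} object.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return list with \code{counts} and \code{proportions}, both samples x
#'   OTUs with OTU names from \code{params$proportions}.
#' @export
sample_counts <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "dm_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(params$proportions)
  depth <- rnbinom(n, size = params$depth_dispersion, mu = params$depth_mean)
  depth <- pmax(depth, 1L)
  shape <- params$proportions * (1 - params$theta) / params$theta
  G <- matrix(rgamma(n * p, shape = rep(shape, each = n)), n, p)
  comp <- G / rowSums(G)
  counts <- t(vapply(seq_len(n),
                     function(i) rmultinom(1L, depth[i], comp[i, ])[, 1L],
                     integer(p)))
  colnames(counts) <- names(params$proportions)
  rownames(counts) <- sprintf("S%d", seq_len(n))
  prop <- counts / depth
  rownames(prop) <- rownames(counts)
  list(counts = counts, proportions = prop)
}

#' Partition OTUs by PAM on patristic distances
#'
#' Partitioning-around-medoids (build + swap) on the distance matrix,
#' labels aligned to the OTU order of \code{D}.
#'
#' @param D patristic distance matrix.
#' @param k number of clusters.
#' @param seed unused (PAM is deterministic given \code{D}); kept for
#'   interface symmetry.
#' @export
pam_partition <- function(D, k, seed = NULL) {
  check_distance_matrix(D)
  if (k > nrow(D)) stop("`k` cannot exceed the number of OTUs")
  cl <- cluster::pam(stats::as.dist(D), k, diss = TRUE, cluster.only = TRUE)
  stats::setNames(as.integer(cl), rownames(D))
}

#' Designate outcome-associated OTUs under a simulation scenario
#'
#' Four scenarios of signal placement on the tree:
#' \describe{
#'   \item{S1}{phylogeny-informative: all aOTUs in one cluster, equal
#'     magnitudes, same sign.}
#'   \item{S2}{as S1 but with heterogeneous magnitudes (Uniform(0.5, 1.5)).}
#'   \item{S3}{phylogeny-non-informative: aOTUs spread over distinct
#'     clusters, at most one per cluster.}
#'   \item{S4}{as S1 with the sign flipped for half of the aOTUs.}
#' }
#' For S1/S2/S4 the host cluster is the one whose size is smallest among
#' those of size >= \code{n_aotu}, with a random subset when larger.
#'
#' @param labels cluster labels from \code{\link{pam_partition}}.
#' @param scenario one of "S1", "S2", "S3", "S4".
#' @param n_aotu number of associated OTUs (default 12).
#' @param seed optional integer seed.
#' @return list with \code{A} (indices), \code{signs}, \code{magnitudes}
#'   (pre-calibration).
#' @export
designate_aotus <- function(labels, scenario = c("S1", "S2", "S3", "S4"),
                            n_aotu = 12L, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(labels)
  if (scenario %in% c("S1", "S2", "S4")) {
    ok <- sizes[sizes >= n_aotu]
    if (length(ok) == 0)
      stop(sprintf("no cluster of size >= %d (largest is %d); cannot place a %s signal",
                   n_aotu, max(sizes), scenario))
    host <- names(ok)[ok == min(ok)]
    if (length(host) > 1) host <- sample(host, 1L)
    members <- which(labels == as.integer(host))
    A <- if (length(members) > n_aotu) sort(sample(members, n_aotu)) else members
    signs <- rep(1, n_aotu)
    mags <- rep(1, n_aotu)
    if (scenario == "S2") mags <- runif(n_aotu, 0.5, 1.5)
    if (scenario == "S4") signs[sample(n_aotu, n_aotu %/% 2)] <- -1
  } else {
    clusters <- unique(labels)
    if (length(clusters) < n_aotu)
      stop(sprintf("S3 needs at least %d clusters, found %d",
                   n_aotu, length(clusters)))
    chosen <- sample(clusters, n_aotu)
    A <- sort(vapply(chosen, function(cl) {
      members <- which(labels == cl)
      if (length(members) == 1L) members else sample(members, 1L)
    }, integer(1)))
    signs <- rep(1, n_aotu)
    mags <- rep(1, n_aotu)
  }
  list(A = unname(A), signs = signs, magnitudes = mags)
}

#' Generate the outcome from the associated OTUs
#'
#' The linear predictor is \eqn{\eta_i = \beta_0 + \sum_{j \in A} \beta_j
#' x_{ij}} on the OTU proportions.  For a continuous outcome,
#' \eqn{y = \eta + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, with
#' \eqn{\sigma} calibrated on the supplied design so that the signal
#' strength \eqn{sd(\eta)/\sigma} equals \code{signal} exactly.  For a
#' binary outcome the coefficients are rescaled so that
#' \eqn{\sum_{j \in A} Var(x_j) \beta_j^2 = } \code{signal}, the intercept
#' centers \eqn{\eta}, and \eqn{y \sim Bernoulli(e^\eta / (1 + e^\eta))}.
#'
#' @param x proportion matrix (samples x OTUs) used both as design and as
#'   calibration set.
#' @param A indices of associated OTUs.
#' @param signs,magnitudes effect pattern from
#'   \code{\link{designate_aotus}}.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param signal requested signal strength.
#' @param beta0 intercept (continuous only; the binomial intercept is set by
#'   centering).
#' @param seed optional integer seed.
#' @return list with \code{y}, \code{beta_true} (length p, calibrated),
#'   \code{beta0}, \code{sigma_eps} (continuous), \code{realized_signal}.
#' @export
generate_outcome <- function(x, A, signs, magnitudes,
                             family = c("gaussian", "binomial"),
                             signal, beta0 = 0, seed = NULL) {
  family <- match.arg(family)
  if (length(A) == 0) stop("`A` must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  beta <- numeric(p)
  beta[A] <- signs * magnitudes
  if (all(beta == 0)) {
    # empty-effect control: pure noise outcome
    y <- if (family == "gaussian") rnorm(n, beta0, 1)
         else rbinom(n, 1L, 0.5)
    return(list(y = y, beta_true = beta, beta0 = beta0,
                sigma_eps = if (family == "gaussian") 1 else NA_real_,
                realized_signal = 0))
  }
  if (family == "gaussian") {
    eta <- as.numeric(beta0 + x %*% beta)
    s_eta <- sd(eta)
    if (s_eta < 1e-12)
      stop("zero-variance linear predictor: associated OTUs absent from the design")
    sigma <- s_eta / signal
    y <- eta + rnorm(n, 0, sigma)
    list(y = y, beta_true = beta, beta0 = beta0, sigma_eps = sigma,
         realized_signal = s_eta / sigma)
  } else {
    vx <- apply(x[, A, drop = FALSE], 2L, var)
    raw <- sum(vx * (signs * magnitudes)^2)
    if (raw < 1e-24)
      stop("zero-variance linear predictor: associated OTUs absent from the design")
    beta <- beta * sqrt(signal / raw)
    b0 <- -mean(x %*% beta)
    eta <- as.numeric(b0 + x %*% beta)
    pr <- plogis(eta)
    y <- rbinom(n, 1L, pr)
    list(y = y, beta_true = beta, beta0 = b0, sigma_eps = NA_real_,
         realized_signal = sum(vx * beta[A]^2))
  }
}

signal_level <- function(signal, family) {
  if (is.character(signal)) {
    lev <- if (family == "gaussian") c(S = 1.0, M = 1.5, L = 2.0)
           else c(S = 5, M = 10, L = 20)
    if (!signal %in% names(lev)) stop("`signal` must be S, M, L or numeric")
    unname(lev[signal])
  } else as.numeric(signal)
}

#' Simulate a complete phylogeny-structured dataset
#'
#' End-to-end generator: coalescent tree, patristic distances, PAM OTU
#' clusters, scenario-specific placement of associated OTUs,
#' Dirichlet-multinomial counts for training and test sets drawn from the
#' same parameters, and outcome generation with signal calibrated on the
#' training design (continuous) or on a 20x candidate pool from which cases
#' and controls are then drawn without replacement (binary).
#'
#' @param scenario "S1".."S4"; see \code{\link{designate_aotus}}.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param signal "S", "M", "L" (mapped to 1/1.5/2 continuous, 5/10/20
#'   binary) or a number.
#' @param n_train,n_test sample sizes; defaults 100/200, split equally into
#'   cases and controls for the binomial family.
#' @param p number of OTUs (default 200).
#' @param n_clusters PAM clusters (default 20).
#' @param n_aotu associated OTUs (default 12).
#' @param params optional \code{dm_params}; by default a log-normal profile
#'   with theta = 0.02 and the 5,000/25 depth model.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return object of class \code{sics_sim}.
#' @export
make_dataset <- function(scenario = "S1",
                         family = c("gaussian", "binomial"),
                         signal = "L", n_train = 100L, n_test = 200L,
                         p = 200L, n_clusters = 20L, n_aotu = 12L,
                         params = NULL, seed = NULL) {
  family <- match.arg(family)
  sig <- signal_level(signal, family)
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(p)
  D <- patristic_distances(tree)
  if (is.null(params))
    params <- dm_params(stats::setNames(lognormal_proportions(p, tree = tree),
                                        tree$tip.label))
  labels <- pam_partition(D, n_clusters)
  des <- designate_aotus(labels, scenario, n_aotu)

  if (family == "gaussian") {
    tr <- sample_counts(params, n_train)
    te <- sample_counts(params, n_test)
    out_tr <- generate_outcome(tr$proportions, des$A, des$signs,
                               des$magnitudes, "gaussian", sig)
    eta_te <- out_tr$beta0 +
      as.numeric(te$proportions %*% out_tr$beta_true)
    y_te <- eta_te + rnorm(n_test, 0, out_tr$sigma_eps)
    res <- list(counts_train = tr$counts, counts_test = te$counts,
                proportions_train = tr$proportions,
                proportions_test = te$proportions,
                y_train = out_tr$y, y_test = y_te,
                sigma_eps = out_tr$sigma_eps,
                beta0 = out_tr$beta0, beta_true = out_tr$beta_true,
                realized_signal = out_tr$realized_signal)
  } else {
    n_need_case <- ceiling(n_train / 2) + ceiling(n_test / 2)
    n_need_ctrl <- floor(n_train / 2) + floor(n_test / 2)
    n_pool <- 20L * (n_train + n_test)
    pool <- sample_counts(params, n_pool)
    out <- generate_outcome(pool$proportions, des$A, des$signs,
                            des$magnitudes, "binomial", sig)
    cases <- which(out$y == 1L); ctrls <- which(out$y == 0L)
    if (length(cases) < n_need_case || length(ctrls) < n_need_ctrl)
      stop(sprintf("candidate pool too small: %d cases / %d controls drawn, need %d / %d",
                   length(cases), length(ctrls), n_need_case, n_need_ctrl))
    pick_case <- sample(cases, n_need_case)
    pick_ctrl <- sample(ctrls, n_need_ctrl)
    tr_idx <- c(pick_case[seq_len(ceiling(n_train / 2))],
                pick_ctrl[seq_len(floor(n_train / 2))])
    te_idx <- c(pick_case[-seq_len(ceiling(n_train / 2))],
                pick_ctrl[-seq_len(floor(n_train / 2))])
    res <- list(counts_train = pool$counts[tr_idx, , drop = FALSE],
                counts_test = pool$counts[te_idx, , drop = FALSE],
                proportions_train = pool$proportions[tr_idx, , drop = FALSE],
                proportions_test = pool$proportions[te_idx, , drop = FALSE],
                y_train = out$y[tr_idx], y_test = out$y[te_idx],
                sigma_eps = NA_real_,
                beta0 = out$beta0, beta_true = out$beta_true,
                realized_signal = out$realized_signal)
  }
  res <- c(res, list(tree = tree, D = D, cluster_labels = labels,
                     A = des$A, signs = des$signs,
                     scenario = scenario, family = family,
                     signal = sig, params = params, seed = seed))
  class(res) <- "sics_sim"
  res
}

#' @export
print.sics_sim <- function(x, ...) {
  cat(sprintf("simulated dataset: scenario %s, %s outcome, signal %.3g\n",
              x$scenario, x$family, x$signal))
  cat(sprintf("  %d train / %d test samples, %d OTUs, %d associated\n",
              nrow(x$counts_train), nrow(x$counts_test),
              ncol(x$counts_train), length(x$A)))
  invisible(x)
}
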