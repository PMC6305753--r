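#' Standardize a design matrix
#'
#' Centers each column to mean zero and scales it so that the column sum of
#' squares equals \code{n} (the solver's standardization convention).  The
#' centering and scaling constants are stored so coefficients can be mapped
#' back to the original abundance scale.
#'
#' @param X numeric matrix (samples x OTUs), or an already-standardized
#'   \code{design_matrix} (returned unchanged).
#' @param constant what to do with zero-variance columns: \code{"error"}
#'   (default; callers should prevalence-filter first) or \code{"zero"},
#'   which keeps them as all-zero columns with unit scale so the solver
#'   leaves their coefficients at exactly zero (an OTU absent from every
#'   training sample carries no information).
#' @return object of class \code{design_matrix}: list with \code{X},
#'   \code{center}, \code{scale}, \code{standardized}, \code{constant}
#'   (indices of zero-variance columns).
#' @export
standardize <- function(X, constant = c("error", "zero")) {
  if (inherits(X, "design_matrix")) return(X)
  constant <- match.arg(constant)
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples to standardize")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sc <- sqrt(colSums(Xc^2) / n)
  zero <- sc < 1e-12
  if (any(zero)) {
    if (constant == "error") {
      nm <- colnames(X)
      if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
      stop("constant columns cannot be standardized: ",
           paste(nm[zero], collapse = ", "))
    }
    sc[zero] <- 1
    Xc[, zero] <- 0
  }
  Xs <- sweep(Xc, 2L, sc, "/")
  structure(list(X = Xs, center = ctr, scale = sc, standardized = TRUE,
                 constant = which(zero)),
            class = "design_matrix")
}

#' Minimax concave penalty
#'
#' \eqn{\rho(t; \lambda_1, \gamma) = \lambda_1 \int_0^{|t|}
#' (1 - x/(\gamma\lambda_1))_+ dx}, i.e. \eqn{\lambda_1 |t| - t^2/(2\gamma)}
#' for \eqn{|t| \le \gamma\lambda_1} and the constant
#' \eqn{\gamma\lambda_1^2/2} beyond.  Vectorized over \code{t}.
#'
#' @param t coefficient value(s).
#' @param lambda1 nonnegative penalty level.
#' @param gamma concavity parameter, \code{> 1}.
#' @export
mcp_penalty <- function(t, lambda1, gamma) {
  if (lambda1 < 0) stop("`lambda1` must be nonnegative")
  if (gamma <= 1) stop("`gamma` must exceed 1")
  at <- abs(t)
  ifelse(at <= gamma * lambda1,
         lambda1 * at - at^2 / (2 * gamma),
         0.5 * gamma * lambda1^2)
}

#' Quadratic structure (smoothness) penalty
#'
#' \eqn{\lambda_2 \beta^T \Sigma \beta} for a symmetric positive
#' semi-definite structure matrix \eqn{\Sigma} (the inverse correlation
#' \eqn{\Omega}, a graph Laplacian, or the identity).
#'
#' @param beta coefficient vector.
#' @param structure p x p symmetric matrix.
#' @param lambda2 nonnegative penalty level.
#' @export
quadratic_penalty <- function(beta, structure, lambda2) {
  if (lambda2 < 0) stop("`lambda2` must be nonnegative")
  if (!is.matrix(structure) || nrow(structure) != length(beta) ||
      ncol(structure) != length(beta))
    stop("`structure` dimensions do not match `beta`")
  as.numeric(lambda2 * crossprod(beta, structure %*% beta))
}

#' Closed-form scalar MCP coordinate update
#'
#' Minimizer of the one-dimensional subproblem
#' \eqn{(a/2)t^2 - b t + \rho(|t|; \lambda_1, \gamma)} arising in each
#' coordinate-descent step: 0 inside the threshold, a firm-thresholded value
#' for moderate \code{|b|}, and the unpenalized \code{b/a} beyond
#' \eqn{a\gamma\lambda_1}.
#'
#' @param a curvature, must exceed \code{1/gamma} for the subproblem to be
#'   convex.
#' @param b linear term.
#' @inheritParams mcp_penalty
#' @export
scalar_update <- function(a, b, lambda1, gamma) {
  if (gamma <= 1) stop("`gamma` must exceed 1")
  if (a <= 1 / gamma)
    stop("curvature a <= 1/gamma: increase gamma or the smoothness penalty lambda2")
  ab <- abs(b)
  if (ab <= lambda1) return(0)
  if (ab <= a * gamma * lambda1) return(sign(b) * (ab - lambda1) / (a - 1 / gamma))
  b / a
}

#' Penalized negative log-likelihood
#'
#' The objective minimized by the solver:
#' \deqn{\frac{1}{n}\sum_i -l(\beta_0, \beta; y_i, x_i)
#'   + \sum_j \rho(|\beta_j|; \lambda_1, \gamma)
#'   + \lambda_2 \beta^T \Omega \beta,}
#' with the Gaussian loss \eqn{-l = (y - \beta_0 - x^T\beta)^2/2} and the
#' logistic loss \eqn{-l = \log(1 + e^{\eta}) - y\eta}.
#'
#' @param intercept scalar \eqn{\beta_0}.
#' @param beta length-p coefficient vector (standardized scale).
#' @param X \code{design_matrix} or standardized numeric matrix.
#' @param y response; numeric for \code{"gaussian"}, 0/1 for
#'   \code{"binomial"}.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param lambda1,gamma,lambda2 penalty parameters.
#' @param structure structure matrix for the quadratic penalty, or
#'   \code{NULL} when \code{lambda2 = 0}.
#' @export
penalized_objective <- function(intercept, beta, X, y,
                                family = c("gaussian", "binomial"),
                                lambda1, gamma, lambda2 = 0, structure = NULL) {
  family <- match.arg(family)
  Xs <- if (inherits(X, "design_matrix")) X$X else X
  eta <- as.numeric(intercept + Xs %*% beta)
  n <- length(y)
  if (family == "gaussian") {
    loss <- sum((y - eta)^2) / (2 * n)
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial family requires a 0/1 response")
    loss <- sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) / n
  }
  pen <- sum(mcp_penalty(beta, lambda1, gamma))
  quad <- if (lambda2 > 0 && !is.null(structure))
    quadratic_penalty(beta, structure, lambda2) else 0
  loss + pen + quad
}

#' Solver convergence settings
#'
#' Convergence is declared when the largest coefficient change over a full
#' sweep (Gaussian) or outer iteration (binomial) falls below
#' \code{tol * max(1, max|beta|)}.
#'
#' @param tol relative coefficient-change tolerance.
#' @param max_sweeps coordinate sweeps (Gaussian family).
#' @param max_outer outer majorize-minimize iterations (binomial family).
#' @param max_inner coordinate sweeps per outer iteration (binomial).
#' @export
sics_control <- function(tol = 1e-4, max_sweeps = 1000L, max_outer = 100L,
                         max_inner = 50L) {
  list(tol = tol, max_sweeps = as.integer(max_sweeps),
       max_outer = as.integer(max_outer), max_inner = as.integer(max_inner))
}

resolve_structure <- function(structure, p) {
  if (is.null(structure)) return(NULL)
  if (inherits(structure, "correlation_structure")) structure <- structure$Omega
  else if (inherits(structure, "laplacian_structure")) structure <- structure$L
  if (identical(structure, "identity")) structure <- diag(p)
  if (!is.matrix(structure) || nrow(structure) != p || ncol(structure) != p)
    stop("`structure` must be a p x p matrix (or correlation/laplacian structure)")
  structure
}

default_gamma <- function(family) if (family == "gaussian") 3 else 30

#' Fit the SICS penalized GLM along a lambda1 path
#'
#' Solves the MCP + quadratic-smoothness penalized likelihood by cyclic
#' coordinate descent (Gaussian family) or IRLS with an inner weighted
#' coordinate descent (binomial family), warm-starting each solution at the
#' previous point of the strictly decreasing \code{lambda1} sequence (the
#' first at zero).  The intercept is never penalized.  Special cases: pure
#' MCP at \code{lambda2 = 0}; Lasso additionally letting
#' \code{gamma -> infinity}; Mnet with \code{structure = "identity"}; Sparse
#' Laplacian Shrinkage with a \code{laplacian_structure}.
#'
#' @param X raw numeric matrix (samples x OTUs) or a \code{design_matrix}.
#' @param y response vector.
#' @param family \code{"gaussian"} (identity link) or \code{"binomial"}
#'   (logit link, 0/1 response).
#' @param lambda1 strictly decreasing vector of sparsity penalty levels.
#' @param lambda2 smoothness penalty level.
#' @param structure structure matrix: a \code{correlation_structure}, a
#'   \code{laplacian_structure}, the string \code{"identity"}, a p x p
#'   matrix, or \code{NULL} (ignored when \code{lambda2 = 0}).
#' @param gamma MCP concavity; defaults to 3 (Gaussian) / 30 (binomial).
#' @param control convergence settings from \code{sics_control()}.
#' @param trace record the objective after every sweep (Gaussian) or outer
#'   iteration (binomial).
#' @return object of class \code{sics_path}: coefficient matrix on both the
#'   standardized and original scales, intercepts, convergence diagnostics.
#' @export
fit_sics_path <- function(X, y, family = c("gaussian", "binomial"),
                          lambda1, lambda2 = 0, structure = NULL,
                          gamma = NULL, control = sics_control(),
                          trace = FALSE) {
  family <- match.arg(family)
  dm <- standardize(X, constant = "zero")
  n <- nrow(dm$X); p <- ncol(dm$X)
  if (length(y) != n) stop("length of `y` does not match rows of `X`")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 response")
  if (is.null(gamma)) gamma <- default_gamma(family)
  if (gamma <= 1) stop("`gamma` must exceed 1")
  if (any(lambda1 < 0)) stop("`lambda1` must be nonnegative")
  if (length(lambda1) > 1L && any(diff(lambda1) >= 0))
    stop("`lambda1` must be strictly decreasing")
  if (lambda2 < 0) stop("`lambda2` must be nonnegative")
  Om <- resolve_structure(structure, p)
  if (lambda2 > 0 && is.null(Om))
    stop("`structure` is required when lambda2 > 0")
  res <- if (family == "gaussian") {
    cd_gaussian_path(dm$X, as.numeric(y), Om, as.numeric(lambda1),
                     lambda2, gamma, control$tol, control$max_sweeps, trace)
  } else {
    cd_binomial_path(dm$X, as.numeric(y), Om, as.numeric(lambda1),
                     lambda2, gamma, control$tol, control$max_outer,
                     control$max_inner, trace)
  }
  beta_std <- res$beta
  beta_orig <- beta_std / dm$scale
  int_orig <- res$intercept - as.numeric(crossprod(beta_orig, dm$center))
  nm <- colnames(if (is.matrix(X)) X else dm$X)
  rownames(beta_std) <- rownames(beta_orig) <- nm
  out <- list(family = family, lambda1 = lambda1, lambda2 = lambda2,
              gamma = gamma, beta_std = beta_std, beta_orig = beta_orig,
              intercept_std = res$intercept, intercept = int_orig,
              n_iter = res$n_iter, converged = res$converged,
              center = dm$center, scale = dm$scale,
              objective_trace = if (trace) res$objective_trace else NULL)
  if (any(!res$converged))
    warning(sprintf("%d of %d path fits did not converge",
                    sum(!res$converged), length(lambda1)))
  class(out) <- "sics_path"
  out
}

#' Fit the SICS penalized GLM at a single penalty configuration
#'
#' @inheritParams fit_sics_path
#' @param lambda1 single sparsity penalty level.
#' @return object of class \code{sics_fit} with \code{intercept},
#'   \code{beta_std} / \code{beta_orig}, convergence diagnostics and (when
#'   \code{trace = TRUE}) the per-sweep objective trace.
#' @export
fit_sics <- function(X, y, family = c("gaussian", "binomial"),
                     lambda1, lambda2 = 0, structure = NULL, gamma = NULL,
                     control = sics_control(), trace = FALSE) {
  if (length(lambda1) != 1L) stop("`lambda1` must be a single value; see fit_sics_path()")
  path <- fit_sics_path(X, y, family = family, lambda1 = lambda1,
                        lambda2 = lambda2, structure = structure,
                        gamma = gamma, control = control, trace = trace)
  path_extract(path, 1L)
}

# internal: one path point as a sics_fit
path_extract <- function(path, l) {
  out <- list(family = path$family, lambda1 = path$lambda1[l],
              lambda2 = path$lambda2, gamma = path$gamma,
              beta_std = path$beta_std[, l], beta_orig = path$beta_orig[, l],
              intercept_std = path$intercept_std[l],
              intercept = path$intercept[l],
              n_iter = path$n_iter[l], converged = path$converged[l],
              center = path$center, scale = path$scale,
              objective_trace = if (!is.null(path$objective_trace))
                path$objective_trace[[l]] else NULL)
  class(out) <- "sics_fit"
  out
}

#' @export
print.sics_fit <- function(x, ...) {
  cat(sprintf("SICS fit (%s): lambda1 = %.4g, lambda2 = %.4g, gamma = %g\n",
              x$family, x$lambda1, x$lambda2, x$gamma))
  cat(sprintf("  %d nonzero coefficients of %d; converged: %s (%d iterations)\n",
              sum(x$beta_std != 0), length(x$beta_std), x$converged, x$n_iter))
  invisible(x)
}

#' @export
coef.sics_fit <- function(object, scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  if (scale == "original") c(`(Intercept)` = object$intercept, object$beta_orig)
  else c(`(Intercept)` = object$intercept_std, object$beta_std)
}

#' Predict from a SICS fit
#'
#' @param object a \code{sics_fit}.
#' @param newdata matrix on the original abundance scale, columns in the
#'   training OTU order.
#' @param type \code{"response"}: fitted means (probabilities for the
#'   binomial family); \code{"link"}: linear predictor.
#' @param ... unused.
#' @export
predict.sics_fit <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta_orig))
    stop("`newdata` has ", ncol(newdata), " columns but the model has ",
         length(object$beta_orig), " OTUs")
  nm_fit <- names(object$beta_orig); nm_new <- colnames(newdata)
  if (!is.null(nm_fit) && !is.null(nm_new) && !identical(nm_fit, nm_new))
    stop("`newdata` column names do not match the training OTU order")
  eta <- as.numeric(object$intercept + newdata %*% object$beta_orig)
  if (type == "link" || object$family == "gaussian") return(eta)
  plogis(eta)
}

#' @export
predict.sics_path <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  eta <- sweep(newdata %*% object$beta_orig, 2L, object$intercept, "+")
  if (type == "link" || object$family == "gaussian") return(eta)
  plogis(eta)
}

#' Smallest sparsity penalty giving the all-zero solution
#'
#' Path anchor \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / n} on the
#' standardized design (\eqn{\bar y} is the case fraction for the binomial
#' family); fitting at \code{lambda1 >= lambda1_max} with \code{lambda2 = 0}
#' returns the null model.
#'
#' @inheritParams fit_sics_path
#' @export
lambda1_max <- function(X, y, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  dm <- standardize(X, constant = "zero")
  if (var(y) == 0) stop("`y` is constant")
  max(abs(crossprod(dm$X, y - mean(y)))) / nrow(dm$X)
}

#' Log-spaced lambda1 path
#'
#' @param lmax path anchor, typically \code{lambda1_max()}.
#' @param length number of path points.
#' @param min_ratio ratio of the smallest to the largest value.
#' @export
lambda1_sequence <- function(lmax, length = 100L, min_ratio = 0.01) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = length))
}
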