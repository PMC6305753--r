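#' Predicted mean squared error / Brier score
#'
#' Mean of squared differences between observations and predictions; with
#' probability predictions of a binary outcome this is the Brier score.
#'
#' @param y_obs,y_pred equal-length numeric vectors.
#' @export
pmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  mean((y_obs - y_pred)^2)
}

#' Squared correlation between observed and predicted values
#'
#' Squared Pearson correlation; defined as 0 (with a warning) when the
#' predictions are constant.
#'
#' @inheritParams pmse
#' @export
r_squared <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  if (sd(y_pred) < 1e-12) {
    warning("constant predictions: R^2 defined as 0")
    return(0)
  }
  cor(y_obs, y_pred)^2
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random case scores
#' above a random control, with ties counting one half.
#'
#' @param y_binary 0/1 outcome with both classes present.
#' @param scores predicted scores or probabilities.
#' @export
auc <- function(y_binary, scores) {
  if (length(y_binary) != length(scores)) stop("length mismatch")
  n1 <- sum(y_binary == 1); n0 <- sum(y_binary == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_binary == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Variable-selection sensitivity and specificity
#'
#' Sensitivity: fraction of truly associated OTUs selected; specificity:
#' fraction of irrelevant OTUs not selected.
#'
#' @param selected integer indices of selected OTUs.
#' @param truth integer indices of truly associated OTUs (nonempty).
#' @param p total number of OTUs.
#' @export
selection_metrics <- function(selected, truth, p) {
  if (length(truth) == 0) stop("`truth` must be nonempty")
  if (any(c(selected, truth) < 1) || any(c(selected, truth) > p))
    stop("indices must lie in 1..p")
  sens <- length(intersect(selected, truth)) / length(truth)
  nontruth <- setdiff(seq_len(p), truth)
  spec <- length(setdiff(nontruth, selected)) / length(nontruth)
  c(sensitivity = sens, specificity = spec)
}

#' Coefficient estimation mean squared error
#'
#' @param beta_hat,beta_true equal-length coefficient vectors.
#' @export
coefficient_mse <- function(beta_hat, beta_true) {
  if (length(beta_hat) != length(beta_true)) stop("length mismatch")
  mean((beta_hat - beta_true)^2)
}

# selected set of a fit: nonzero coefficients beyond a numerical zero
selected_otus <- function(fit, tol = 1e-8) which(abs(fit$beta_std) > tol)

#' Repeated-split benchmarking of prediction methods
#'
#' Repeatedly splits the data into training and test portions, tunes each
#' method by internal cross-validation on the training portion only,
#' evaluates predictions on the test portion, and compares every method to
#' the first (reference) by paired two-sided Wilcoxon signed-rank tests
#' (exact distribution up to 25 splits, normal approximation with
#' continuity correction beyond).
#'
#' Methods are supplied as a named list.  Each element is either a preset
#' string — \code{"sics"}, \code{"sls"}, \code{"mcp"}, \code{"lasso"},
#' \code{"enet"}, \code{"null"} — or a function
#' \code{f(X_train, y_train, X_test, D, family)} returning a numeric vector
#' of test-set predictions (this is how externally produced predictions,
#' e.g. from Random Forest, enter the comparison).
#'
#' @param X abundance matrix (samples x OTUs).
#' @param y outcome.
#' @param D patristic distance matrix (needed by tree-aware presets).
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param methods named list of presets and/or prediction functions; the
#'   first is the reference.
#' @param n_splits number of random splits.
#' @param train_frac fraction of samples used for training in each split.
#' @param seed integer seed governing the splits.
#' @param grid tuning grid for the CV-tuned presets.
#' @param nfolds folds of the internal CV.
#' @return object of class \code{metrics_report}: per-split metric
#'   \code{table}, \code{summary} (mean, se) and Wilcoxon \code{p_values}
#'   against the reference.
#' @export
benchmark <- function(X, y, D = NULL, family = c("gaussian", "binomial"),
                      methods = list(sics = "sics", mcp = "mcp"),
                      n_splits = 10L, train_frac = 0.8, seed = NULL,
                      grid = default_grid(), nfolds = 5L) {
  family <- match.arg(family)
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("`methods` must be a named list")
  if (length(methods) < 2)
    stop("need at least two methods (a reference and a competitor)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  rows <- list()
  for (s in seq_len(n_splits)) {
    tr <- sort(sample(n, round(train_frac * n)))
    if (family == "binomial" &&
        (length(unique(y[tr])) < 2 || length(unique(y[-tr])) < 2)) {
      # re-stratify degenerate splits
      tr <- sort(c(sample(which(y == 1), round(train_frac * sum(y == 1))),
                   sample(which(y == 0), round(train_frac * sum(y == 0)))))
    }
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[-tr, , drop = FALSE]
    ytr <- y[tr]; yte <- y[-tr]
    for (m in names(methods)) {
      pred <- run_method(methods[[m]], Xtr, ytr, Xte, D, family, grid, nfolds)
      rows[[length(rows) + 1L]] <- data.frame(
        split = s, method = m,
        pmse = pmse(yte, pred),
        r2 = if (sd(pred) < 1e-12) 0 else r_squared(yte, pred),
        auc = if (family == "binomial") auc(yte, pred) else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  metrics <- c("pmse", "r2", if (family == "binomial") "auc")
  summ <- do.call(rbind, lapply(names(methods), function(m) {
    sub <- tab[tab$method == m, ]
    data.frame(method = m, metric = metrics,
               mean = vapply(metrics, function(k) mean(sub[[k]]), numeric(1)),
               se = vapply(metrics, function(k)
                 sd(sub[[k]]) / sqrt(n_splits), numeric(1)))
  }))
  ref <- names(methods)[1L]
  pvals <- do.call(rbind, lapply(setdiff(names(methods), ref), function(m) {
    data.frame(method = m, metric = metrics,
               p_value = vapply(metrics, function(k) {
                 a <- tab[[k]][tab$method == ref]
                 b <- tab[[k]][tab$method == m]
                 if (all(a == b)) return(1)
                 wilcox.test(a, b, paired = TRUE,
                             exact = n_splits <= 25,
                             correct = TRUE)$p.value
               }, numeric(1)))
  }))
  structure(list(table = tab, summary = summ, p_values = pvals,
                 reference = ref, family = family),
            class = "metrics_report")
}

run_method <- function(spec, Xtr, ytr, Xte, D, family, grid, nfolds) {
  if (is.function(spec)) return(spec(Xtr, ytr, Xte, D, family))
  if (!is.character(spec))
    stop("each method must be a preset string or a function")
  p <- ncol(Xtr)
  cv1 <- function(g = grid, ...) cv_sics(Xtr, ytr, D, family = family,
                                         grid = g, nfolds = nfolds, ...)
  sparse_grid <- default_grid(alpha_values = 0, lambda2_values = 0,
                              lambda1_path_length = grid$lambda1_path_length,
                              lambda1_min_ratio = grid$lambda1_min_ratio)
  fit <- switch(spec,
    sics = cv1()$fit,
    sls = cv1(structure_type = "laplacian")$fit,
    mcp = cv1(sparse_grid)$fit,
    lasso = cv1(sparse_grid, gamma = 1e6)$fit,
    enet = {
      # Lasso + l2 (structure = I): alpha -> infinity collapses C to the
      # identity, so feeding an all-ones off-diagonal distance matrix at a
      # huge alpha yields Omega = I
      g <- default_grid(alpha_values = 1e6,
                        lambda2_values = grid$lambda2_values,
                        lambda1_path_length = grid$lambda1_path_length,
                        lambda1_min_ratio = grid$lambda1_min_ratio)
      Did <- matrix(1, p, p); diag(Did) <- 0
      cv_sics(Xtr, ytr, Did, family = family, grid = g, nfolds = nfolds,
              gamma = 1e6)$fit
    },
    null = NULL,
    stop("unknown method preset: ", spec))
  if (is.null(fit)) rep(mean(ytr), nrow(Xte)) else predict(fit, Xte)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("benchmark over %d splits (reference: %s)\n",
              max(x$table$split), x$reference))
  print(x$summary, row.names = FALSE)
  cat("paired Wilcoxon signed-rank p-values vs reference:\n")
  print(x$p_values, row.names = FALSE)
  invisible(x)
}
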