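#' Default tuning grid for (alpha, lambda2, lambda1)
#'
#' The evolutionary-rate parameter \code{alpha} and the smoothness level
#' \code{lambda2} are both searched over \{0\} union \{2^k : k = -5..5\}
#' (12 values each); \code{lambda1} over a finer log-spaced path of
#' \code{lambda1_path_length} values from the all-zero anchor
#' \code{lambda1_max} down to \code{lambda1_max * lambda1_min_ratio}.
#' When \code{lambda1_min_ratio} is \code{NULL} it is resolved at fit time
#' to 0.01 for p > n and 1e-4 otherwise.
#'
#' @param alpha_values,lambda2_values grid values.
#' @param lambda1_path_length number of lambda1 path points.
#' @param lambda1_min_ratio smallest/largest lambda1 ratio, or \code{NULL}.
#' @export
default_grid <- function(alpha_values = c(0, 2^(-5:5)),
                         lambda2_values = c(0, 2^(-5:5)),
                         lambda1_path_length = 100L,
                         lambda1_min_ratio = NULL) {
  structure(list(alpha_values = alpha_values,
                 lambda2_values = lambda2_values,
                 lambda1_path_length = as.integer(lambda1_path_length),
                 lambda1_min_ratio = lambda1_min_ratio),
            class = "tuning_grid")
}

make_folds <- function(y, k, family) {
  n <- length(y)
  if (k < 2 || k > n) stop("`nfolds` must be between 2 and n")
  if (family == "binomial") {
    # stratified: preserve class proportions in every fold
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k)
        stop("cannot stratify: a class has fewer samples than folds")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  } else {
    sample(rep_len(seq_len(k), n))
  }
}

#' Cross-validated tuning of the SICS penalized GLM
#'
#' Tunes (alpha, lambda2, lambda1) by k-fold cross-validation.  For each
#' alpha the smoothness matrix is built once from the distance matrix and
#' shared across the lambda2 sub-grid; the lambda2 = 0 slice is computed
#' once and reused for every alpha (alpha has no effect there).  Within each
#' training fold, standardization and the lambda1 path anchor are computed
#' from the training portion only; fold criteria are aligned across folds by
#' path index.  The criterion is predicted mean squared error (Gaussian) or
#' per-fold-averaged AUC (binomial).  Ties are broken toward larger lambda1,
#' then larger alpha, then smaller lambda2 (sparser, more local models).
#' The final model is refit on all samples at the selected triple.
#'
#' @param X raw abundance matrix (samples x OTUs).
#' @param y response.
#' @param D patristic distance matrix (OTU order matching \code{X} columns).
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param grid a \code{tuning_grid}; see \code{\link{default_grid}}.
#' @param nfolds number of folds (default 5).
#' @param seed optional integer seed for the fold assignment.
#' @param structure_type smoothness matrix: inverse correlation (SICS) or
#'   sparsified graph Laplacian (SLS).
#' @param laplacian_sparsity sparsity level for \code{structure_type =
#'   "laplacian"}.
#' @param gamma MCP concavity (defaults per family).
#' @param control solver settings.
#' @return object of class \code{cv_sics}: the CV \code{table}, the selected
#'   \code{best} triple, the refit \code{fit} (a \code{sics_fit}),
#'   \code{criterion_name} and the fold assignment.
#' @export
cv_sics <- function(X, y, D, family = c("gaussian", "binomial"),
                    grid = default_grid(), nfolds = 5L, seed = NULL,
                    structure_type = c("inverse_correlation", "laplacian"),
                    laplacian_sparsity = 0.9, gamma = NULL,
                    control = sics_control()) {
  family <- match.arg(family)
  structure_type <- match.arg(structure_type)
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(gamma)) gamma <- default_gamma(family)
  min_ratio <- grid$lambda1_min_ratio
  if (is.null(min_ratio)) min_ratio <- if (p > n) 0.01 else 1e-4
  L <- grid$lambda1_path_length
  if (!is.null(seed)) set.seed(seed)
  fold <- make_folds(y, nfolds, family)

  crit_name <- if (family == "gaussian") "PMSE" else "AUC"
  minimize <- family == "gaussian"

  # per-fold lambda1 anchors (training portion only)
  fold_lmax <- vapply(seq_len(nfolds), function(f) {
    tr <- fold != f
    lambda1_max(X[tr, , drop = FALSE], y[tr], family)
  }, numeric(1))

  # criterion for one (lambda2, structure) setting: nfolds x L matrix
  run_folds <- function(lambda2, Om) {
    out <- matrix(NA_real_, nfolds, L)
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      lam1 <- lambda1_sequence(fold_lmax[f], L, min_ratio)
      path <- fit_sics_path(X[tr, , drop = FALSE], y[tr], family = family,
                            lambda1 = lam1, lambda2 = lambda2,
                            structure = Om, gamma = gamma, control = control)
      pred <- predict(path, X[!tr, , drop = FALSE])
      yte <- y[!tr]
      out[f, ] <- if (family == "gaussian")
        colMeans((yte - pred)^2)
      else
        apply(pred, 2L, function(s) auc(yte, s))
    }
    out
  }

  alphas <- grid$alpha_values
  lambda2s <- grid$lambda2_values
  rows <- list()
  fold_criteria <- list()
  add_rows <- function(alpha, lambda2, fmat) {
    fold_criteria[[sprintf("alpha=%g;lambda2=%g", alpha, lambda2)]] <<- fmat
    mean_crit <- colMeans(fmat)
    se_crit <- apply(fmat, 2L, sd) / sqrt(nfolds)
    data.frame(alpha = alpha, lambda2 = lambda2, index = seq_len(L),
               criterion = mean_crit, se = se_crit)
  }

  # lambda2 = 0 slice: alpha-independent, computed once
  if (any(lambda2s == 0)) {
    f0 <- run_folds(0, NULL)
    for (a in alphas) rows[[length(rows) + 1L]] <- add_rows(a, 0, f0)
  }
  for (a in alphas) {
    Om <- NULL
    pos <- lambda2s[lambda2s > 0]
    if (length(pos) > 0) {
      Om <- if (structure_type == "inverse_correlation")
        correlation_structure(D, a)$Omega
      else
        build_laplacian(phylo_correlation(D, a), laplacian_sparsity)$L
    }
    for (l2 in pos)
      rows[[length(rows) + 1L]] <- add_rows(a, l2, run_folds(l2, Om))
  }
  tab <- do.call(rbind, rows)

  # selection with tie-breaking: best criterion, then larger lambda1
  # (smaller path index), larger alpha, smaller lambda2
  score <- if (minimize) tab$criterion else -tab$criterion
  ord <- order(score, tab$index, -tab$alpha, tab$lambda2)
  best_row <- tab[ord[1L], ]

  # final refit on all samples at the selected triple
  lmax_all <- lambda1_max(X, y, family)
  lam1_all <- lambda1_sequence(lmax_all, L, min_ratio)
  Om_best <- if (best_row$lambda2 > 0) {
    if (structure_type == "inverse_correlation")
      correlation_structure(D, best_row$alpha)$Omega
    else
      build_laplacian(phylo_correlation(D, best_row$alpha),
                      laplacian_sparsity)$L
  } else NULL
  final_path <- fit_sics_path(X, y, family = family,
                              lambda1 = lam1_all[seq_len(best_row$index)],
                              lambda2 = best_row$lambda2,
                              structure = Om_best, gamma = gamma,
                              control = control)
  fit <- path_extract(final_path, best_row$index)

  structure(list(table = tab,
                 best = list(alpha = best_row$alpha,
                             lambda2 = best_row$lambda2,
                             lambda1 = lam1_all[best_row$index],
                             index = best_row$index,
                             criterion = best_row$criterion),
                 fit = fit, criterion_name = crit_name, folds = fold,
                 fold_criteria = fold_criteria,
                 structure_type = structure_type, gamma = gamma),
            class = "cv_sics")
}

#' @export
print.cv_sics <- function(x, ...) {
  cat(sprintf("cross-validated SICS (%s criterion)\n", x$criterion_name))
  cat(sprintf("  best: alpha = %.4g, lambda2 = %.4g, lambda1 = %.4g (%s = %.4g)\n",
              x$best$alpha, x$best$lambda2, x$best$lambda1,
              x$criterion_name, x$best$criterion))
  cat(sprintf("  %d OTUs selected\n", sum(x$fit$beta_std != 0)))
  invisible(x)
}

#' @export
predict.cv_sics <- function(object, newdata, ...) {
  predict(object$fit, newdata, ...)
}
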