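#' Patristic distance matrix of a phylogenetic tree
#'
#' Computes all pairwise leaf-to-leaf distances, i.e. the sum of branch
#' lengths along the unique path connecting each pair of tips.  These
#' distances are the input of the phylogeny-induced correlation model
#' \code{\link{phylo_correlation}}.
#'
#' @param tree an object of class \code{phylo} (rooted or unrooted) with
#'   branch lengths on every edge and unique tip labels.
#' @return a symmetric \code{p x p} numeric matrix with zero diagonal,
#'   dimnames equal to the tip labels in their input order.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' patristic_distances(tr)
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; every edge must carry a length")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    stop(sprintf("missing branch length on edge %d (%d -> %d)",
                 bad, tree$edge[bad, 1L], tree$edge[bad, 2L]))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  D <- ape::cophenetic.phylo(tree)
  # cophenetic.phylo returns tips in tree$tip.label order already, but be safe
  D <- D[tree$tip.label, tree$tip.label, drop = FALSE]
  D
}

# internal: validate a patristic/user distance matrix
check_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D)) stop("`D` must be a numeric matrix")
  if (nrow(D) != ncol(D)) stop("`D` must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("`D` must be symmetric")
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal")
  if (any(D < 0)) stop("`D` must be nonnegative")
  invisible(D)
}

#' Phylogeny-induced correlation matrix
#'
#' Under a trait-evolution model, the correlation between traits of two OTUs
#' decays exponentially with their patristic distance:
#' \eqn{c_{ij}(\alpha) = e^{-2\alpha d_{ij}}}.  \code{alpha = 0} gives the
#' all-ones matrix (no evolution, all traits identical); \code{alpha ->
#' infinity} gives the identity (independent evolution).  \code{alpha} thus
#' acts as a soft grouping parameter selecting the phylogenetic depth of
#' trait conservation.
#'
#' @param D patristic (or other pairwise) distance matrix, symmetric with
#'   zero diagonal.
#' @param alpha nonnegative evolutionary-rate parameter.
#' @return correlation matrix of the same dimension as \code{D}.
#' @export
phylo_correlation <- function(D, alpha) {
  check_distance_matrix(D)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single nonnegative number")
  C <- exp(-2 * alpha * D)
  diag(C) <- 1
  C
}

#' Inverse of a phylogeny-induced correlation matrix
#'
#' Builds the smoothness-penalty matrix \eqn{\Omega = C^{-1}}.  Because
#' \eqn{C(\alpha)} becomes singular as \code{alpha -> 0} (all entries tend
#' to 1), the inverse is stabilized with the smallest ridge \eqn{\epsilon}
#' from \code{ridge_ladder} for which \eqn{(C + \epsilon I)\Omega = I} holds
#' to within \code{residual_tol} in the max norm; the ridge actually used is
#' recorded.  Off-diagonal entries of \eqn{\Omega} are expected to be
#' nonpositive for tree-derived \eqn{C}; positive entries (which can arise
#' numerically, especially after ridge stabilization) are counted and
#' flagged, never clamped.
#'
#' @param C symmetric correlation matrix with unit diagonal.
#' @param alpha optional, the rate parameter used to build \code{C}
#'   (recorded only).
#' @param ridge_ladder increasing nonnegative ridge candidates.
#' @param residual_tol max-norm tolerance on \eqn{(C+\epsilon I)\Omega - I}.
#' @return an object of class \code{correlation_structure}: a list with
#'   elements \code{alpha}, \code{C}, \code{Omega}, \code{ridge_used},
#'   \code{labels} and \code{n_positive_offdiag}.
#' @export
inverse_correlation <- function(C, alpha = NA_real_,
                                ridge_ladder = c(0, 1e-8, 1e-6, 1e-4),
                                residual_tol = 1e-6) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("`C` must be a square matrix")
  if (max(abs(C - t(C))) > 1e-8) stop("`C` must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8) stop("`C` must have a unit diagonal")
  p <- nrow(C)
  Omega <- NULL
  ridge_used <- NA_real_
  for (eps in sort(ridge_ladder)) {
    Om <- tryCatch(solve(C + diag(eps, p)), error = function(e) NULL)
    if (is.null(Om) || anyNA(Om) || any(!is.finite(Om))) next
    resid <- max(abs((C + diag(eps, p)) %*% Om - diag(p)))
    if (resid < residual_tol) {
      Omega <- (Om + t(Om)) / 2     # symmetrize against round-off
      ridge_used <- eps
      break
    }
  }
  if (is.null(Omega))
    stop("correlation matrix could not be inverted at any ridge in the ladder")
  off <- Omega[upper.tri(Omega)]
  n_pos <- sum(off > residual_tol)
  structure(list(alpha = alpha, C = C, Omega = Omega, ridge_used = ridge_used,
                 labels = colnames(C), n_positive_offdiag = n_pos),
            class = "correlation_structure")
}

#' Correlation structure from distances
#'
#' Convenience wrapper: builds \eqn{C(\alpha)} from a distance matrix and
#' inverts it with ridge stabilization.
#'
#' @inheritParams phylo_correlation
#' @inheritParams inverse_correlation
#' @return see \code{\link{inverse_correlation}}.
#' @export
correlation_structure <- function(D, alpha,
                                  ridge_ladder = c(0, 1e-8, 1e-6, 1e-4),
                                  residual_tol = 1e-6) {
  C <- phylo_correlation(D, alpha)
  inverse_correlation(C, alpha = alpha, ridge_ladder = ridge_ladder,
                      residual_tol = residual_tol)
}

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("phylogeny-induced correlation structure: p = %d, alpha = %s\n",
              nrow(x$C), format(x$alpha)))
  cat(sprintf("  ridge used for inversion: %g\n", x$ridge_used))
  if (x$n_positive_offdiag > 0)
    cat(sprintf("  NOTE: %d positive off-diagonal entries in Omega\n",
                x$n_positive_offdiag))
  invisible(x)
}

#' Graph Laplacian from a phylogeny-induced correlation matrix
#'
#' Comparator structure for Sparse Laplacian Shrinkage: the correlation
#' matrix (diagonal zeroed) is used as the adjacency matrix and optionally
#' sparsified by zeroing its smallest off-diagonal entries, keeping symmetric
#' pairs together.  Entries tied at the sparsification threshold are all
#' retained (conservative), and the realized sparsity is reported.  The
#' Laplacian is the unnormalized \eqn{L = D_g - A} with \eqn{D_g} the degree
#' diagonal.
#'
#' @param C correlation (adjacency) matrix.
#' @param sparsity_level fraction in \code{[0, 1)} of off-diagonal entry
#'   pairs to zero out.
#' @return object of class \code{laplacian_structure}: list with
#'   \code{adjacency}, \code{L}, \code{sparsity_level},
#'   \code{realized_sparsity}.
#' @export
build_laplacian <- function(C, sparsity_level = 0) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("`C` must be a square matrix")
  if (sparsity_level < 0 || sparsity_level >= 1)
    stop("`sparsity_level` must be in [0, 1)")
  A <- C
  diag(A) <- 0
  up <- upper.tri(A)
  vals <- A[up]
  if (sparsity_level > 0) {
    k <- floor(sparsity_level * length(vals))
    if (k > 0) {
      # zero everything below the (k+1)-th smallest: exactly k entries when
      # values are distinct; a tie group straddling the cut is retained whole
      thr <- if (k < length(vals)) sort(vals, partial = k + 1)[k + 1] else Inf
      A[A < thr & row(A) != col(A)] <- 0
    }
  }
  realized <- mean(A[up] == 0)
  L <- diag(rowSums(A)) - A
  structure(list(adjacency = A, L = L, sparsity_level = sparsity_level,
                 realized_sparsity = realized),
            class = "laplacian_structure")
}
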