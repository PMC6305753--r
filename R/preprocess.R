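# Preprocessing of real OTU count tables (taxa x samples), in the fixed
# order: outlier flagging -> prevalence filter -> GMPR normalization ->
# winsorization -> square-root transform -> (outcome rank-normal transform).

#' Flag outlier samples by Bray-Curtis dissimilarity
#'
#' Each sample's outlier index is its median Bray-Curtis distance (on
#' relative abundances) to all other samples; samples whose index exceeds
#' mean + \code{threshold_sd} standard deviations are flagged.
#'
#' @param counts count matrix, taxa x samples.
#' @param threshold_sd flagging threshold in SD units (default 2.5).
#' @return named logical vector (TRUE = outlier) with the index as
#'   attribute \code{"index"}.
#' @export
flag_outlier_samples <- function(counts, threshold_sd = 2.5) {
  if (ncol(counts) < 3) stop("need at least 3 samples")
  rel <- sweep(counts, 2L, colSums(counts), "/")
  bc <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  idx <- vapply(seq_len(ncol(counts)),
                function(i) median(bc[i, -i]), numeric(1))
  flags <- idx > mean(idx) + threshold_sd * sd(idx)
  names(flags) <- colnames(counts)
  attr(flags, "index") <- idx
  flags
}

#' Remove rare OTUs by prevalence
#'
#' Keeps OTUs present (count > 0) in at least \code{min_prevalence} of the
#' samples; the boundary is inclusive (prevalence exactly at the threshold
#' is retained).
#'
#' @inheritParams flag_outlier_samples
#' @param min_prevalence minimum fraction of samples (default 0.10).
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.10) {
  prev <- rowMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("prevalence filter removed every OTU")
  counts[keep, , drop = FALSE]
}

#' GMPR size factors
#'
#' Geometric mean of pairwise ratios: for each pair of samples, the median
#' ratio of counts over their shared nonzero OTUs; a sample's size factor
#' is the geometric mean of its median ratios to all comparable samples.
#' Zero-robust alternative to the median-of-ratios factor for sparse count
#' tables.
#'
#' @inheritParams flag_outlier_samples
#' @return positive numeric vector of per-sample size factors.
#' @export
gmpr_size_factors <- function(counts) {
  ns <- ncol(counts)
  if (ns < 2) stop("need at least 2 samples")
  sf <- numeric(ns)
  for (i in seq_len(ns)) {
    logs <- numeric(0)
    ci <- counts[, i]
    for (j in seq_len(ns)[-i]) {
      shared <- ci > 0 & counts[, j] > 0
      if (any(shared))
        logs <- c(logs, log(median(ci[shared] / counts[shared, j])))
    }
    if (length(logs) == 0)
      stop("sample ", colnames(counts)[i] %||% i,
           " shares no nonzero OTU with any other sample")
    sf[i] <- exp(mean(logs))
  }
  names(sf) <- colnames(counts)
  sf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Winsorize abundances at an upper quantile
#'
#' Per OTU (across samples), values above the OTU's \code{quantile}
#' percentile (type-7) are replaced by the percentile value.  Set
#' \code{per_otu = FALSE} for a single global cap.
#'
#' @param abundances matrix, taxa x samples.
#' @param quantile capping quantile in (0.5, 1); default 0.97.
#' @param per_otu cap per OTU (default) or globally.
#' @export
winsorize <- function(abundances, quantile = 0.97, per_otu = TRUE) {
  if (quantile <= 0.5 || quantile >= 1) stop("`quantile` must be in (0.5, 1)")
  if (per_otu) {
    t(apply(abundances, 1L, function(v) pmin(v, stats::quantile(v, quantile, type = 7))))
  } else {
    pmin(abundances, stats::quantile(abundances, quantile, type = 7))
  }
}

#' Square-root transform
#'
#' Entrywise square root, reducing the influence of highly abundant
#' observations.
#'
#' @param abundances nonnegative matrix or vector.
#' @export
sqrt_transform <- function(abundances) {
  if (any(abundances < 0)) stop("negative entries cannot be square-rooted")
  sqrt(abundances)
}

#' Rank-based inverse-normal transform of a continuous outcome
#'
#' \eqn{\Phi^{-1}((rank - 0.5)/n)} with average ranks for ties, making the
#' outcome approximately standard normal.
#'
#' @param y continuous outcome, length >= 3, non-constant.
#' @export
quantile_normal_transform <- function(y) {
  if (length(y) < 3) stop("need at least 3 observations")
  if (var(y) == 0) stop("`y` is constant")
  qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: outlier-sample removal, prevalence filtering, GMPR
#' normalization, winsorization, square-root transform, and (optionally)
#' the rank-normal transform of a continuous outcome.  Returns the model
#' design matrix (samples x OTUs) plus a log of every stage's dimensions.
#'
#' @inheritParams flag_outlier_samples
#' @param outcome optional outcome vector aligned to the samples.
#' @param outcome_transform rank-normal transform the outcome
#'   (continuous outcomes only).
#' @param min_prevalence,winsor_quantile stage parameters.
#' @return list with \code{X} (samples x OTUs, transformed), \code{y},
#'   \code{removed_samples}, \code{removed_otus}, \code{size_factors},
#'   \code{log}.
#' @export
preprocess_pipeline <- function(counts, outcome = NULL, threshold_sd = 2.5,
                                min_prevalence = 0.10, winsor_quantile = 0.97,
                                outcome_transform = FALSE) {
  stages <- list()
  dims <- function(x) sprintf("%d OTUs x %d samples", nrow(x), ncol(x))
  flags <- flag_outlier_samples(counts, threshold_sd)
  removed_samples <- colnames(counts)[flags] %||% which(flags)
  counts2 <- counts[, !flags, drop = FALSE]
  if (!is.null(outcome)) outcome <- outcome[!flags]
  stages$outliers <- sprintf("outlier removal: %s -> %s", dims(counts), dims(counts2))
  counts3 <- prevalence_filter(counts2, min_prevalence)
  removed_otus <- setdiff(rownames(counts2) %||% seq_len(nrow(counts2)),
                          rownames(counts3) %||% integer(0))
  stages$prevalence <- sprintf("prevalence filter: %s -> %s", dims(counts2), dims(counts3))
  sf <- gmpr_size_factors(counts3)
  norm <- sweep(counts3, 2L, sf, "/")
  stages$gmpr <- "GMPR normalization"
  wz <- winsorize(norm, winsor_quantile)
  stages$winsorize <- sprintf("winsorization at %g quantile", winsor_quantile)
  tx <- sqrt_transform(wz)
  stages$sqrt <- "square-root transform"
  y <- outcome
  if (!is.null(y) && outcome_transform) {
    y <- quantile_normal_transform(y)
    stages$outcome <- "rank-normal outcome transform"
  }
  list(X = t(tx), y = y, removed_samples = removed_samples,
       removed_otus = removed_otus, size_factors = sf,
       log = unlist(stages))
}
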