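# Tab-delimited readers/writers and input alignment.  TSV (UTF-8, no
# quoting) is the canonical table dialect throughout.

#' Read an OTU count table
#'
#' Expects a TSV with OTU identifiers in the first column and sample
#' identifiers in the header (taxa x samples).  If \code{metadata} is given
#' and the sample identifiers only match after transposition, the table is
#' transposed with a warning.
#'
#' @param path TSV file path.
#' @param metadata optional data frame whose row names are sample IDs, used
#'   for the orientation check.
#' @return integer matrix, taxa x samples.
#' @export
read_count_table <- function(path, metadata = NULL) {
  df <- read.delim(path, check.names = FALSE, row.names = NULL)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 2L,
                        function(v) all(!is.na(suppressWarnings(as.numeric(v))))))
    stop("non-numeric cells in columns: ",
         paste(colnames(df)[-1L][bad], collapse = ", "))
  }
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(m < 0)) stop("negative counts in table")
  if (!is.null(metadata)) {
    samp <- rownames(metadata)
    if (!any(colnames(m) %in% samp) && any(rownames(m) %in% samp)) {
      warning("sample identifiers found in rows, not columns: transposing")
      m <- t(m)
    }
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a matrix as TSV with row identifiers
#'
#' @param m matrix with row names.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "OTU_ID") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix from TSV
#'
#' Header row and first column carry OTU identifiers; the matrix must be
#' symmetric with a zero diagonal.  Accepting precomputed distances lets the
#' correlation structure be built from pairwise sequence divergences without
#' an explicit tree.
#'
#' @param path TSV file path.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- as.character(df[[1L]])
  if (!identical(rownames(D), colnames(D)))
    stop("row and column identifiers of the distance matrix disagree")
  check_distance_matrix(D)
  D
}

#' Align counts, tree/distances and metadata
#'
#' Reorders the distance matrix to the OTU order of the count table and the
#' metadata to its sample order.  Any mismatch is a hard error naming the
#' offenders; no silent intersection is taken.
#'
#' @param counts count matrix, taxa x samples.
#' @param tree_or_D a \code{phylo} tree or a distance matrix.
#' @param metadata data frame with sample IDs as row names, or \code{NULL}.
#' @return list with \code{counts}, \code{D} (reordered) and
#'   \code{metadata} (reordered).
#' @export
align_inputs <- function(counts, tree_or_D, metadata = NULL) {
  otus <- rownames(counts)
  if (is.null(otus)) stop("count table has no OTU identifiers")
  D <- if (inherits(tree_or_D, "phylo")) patristic_distances(tree_or_D)
       else tree_or_D
  check_distance_matrix(D)
  miss_d <- setdiff(otus, rownames(D))
  extra_d <- setdiff(rownames(D), otus)
  if (length(miss_d) > 0)
    stop("OTUs in counts absent from tree/distances: ",
         paste(head(miss_d, 10L), collapse = ", "))
  if (length(extra_d) > 0)
    stop("OTUs in tree/distances absent from counts: ",
         paste(head(extra_d, 10L), collapse = ", "))
  D <- D[otus, otus]
  if (!is.null(metadata)) {
    samp <- colnames(counts)
    miss_m <- setdiff(samp, rownames(metadata))
    if (length(miss_m) > 0)
      stop("samples absent from metadata: ",
           paste(head(miss_m, 10L), collapse = ", "))
    metadata <- metadata[samp, , drop = FALSE]
  }
  list(counts = counts, D = D, metadata = metadata)
}

#' Serialize a fit as TSV plus a JSON sidecar
#'
#' Writes a per-OTU table (identifier, standardized and original-scale
#' coefficients) and a JSON manifest with the model configuration and
#' convergence diagnostics.
#'
#' @param fit a \code{sics_fit}.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the JSON manifest (e.g. alpha, seed,
#'   ridge used).
#' @export
write_fit <- function(fit, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(fit$beta_std) %||% paste0("OTU", seq_along(fit$beta_std))
  df <- data.frame(OTU_ID = nm, beta_std = fit$beta_std,
                   beta_orig = fit$beta_orig)
  write.table(df, file.path(dir, "coefficients.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- c(list(package_version = as.character(utils::packageVersion("sicsreg")),
                     family = fit$family, lambda1 = fit$lambda1,
                     lambda2 = fit$lambda2, gamma = fit$gamma,
                     intercept = fit$intercept, n_iter = fit$n_iter,
                     converged = fit$converged), extra)
  jsonlite::write_json(manifest, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
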