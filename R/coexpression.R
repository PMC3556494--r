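#' Connection matrices
#'
#' A `connection_matrix` holds the symmetric gene-by-gene matrix of
#' normalized, Fisher z-transformed correlations for one species — either a
#' single dataset's matrix or the average over a compendium. Off-diagonal
#' entries have empirical mean 0 and standard deviation 1 by construction;
#' the diagonal is `NA` and is excluded from all downstream vectors.
#'
#' @param z symmetric numeric matrix with gene ids as dimnames; diagonal
#'   entries are ignored and stored as `NA`.
#' @param provenance `"single-dataset"` or `"aggregated"`.
#' @param n_datasets number of datasets behind the matrix.
#' @param flagged_genes ids of genes whose correlations were zeroed for lack
#'   of variance.
#' @return an object of class `connection_matrix` with elements `z`,
#'   `gene_ids`, `provenance`, `n_datasets`, `flagged_genes`.
#' @export
connection_matrix <- function(z, provenance = "single-dataset",
                              n_datasets = 1L, flagged_genes = character()) {
  stopifnot(is.matrix(z), nrow(z) == ncol(z), !is.null(rownames(z)))
  diag(z) <- NA_real_
  attr(z, "flagged_genes") <- NULL
  structure(list(z = z, gene_ids = rownames(z), provenance = provenance,
                 n_datasets = n_datasets, flagged_genes = flagged_genes),
            class = "connection_matrix")
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("connection_matrix (%s, %d dataset%s): %d genes\n",
              x$provenance, x$n_datasets, if (x$n_datasets == 1L) "" else "s",
              length(x$gene_ids)))
  if (length(x$flagged_genes))
    cat(sprintf("  %d zero-variance genes flagged\n", length(x$flagged_genes)))
  invisible(x)
}

# Off-diagonal upper-triangle entries of a square matrix: each unordered
# gene pair counted once, diagonal excluded.
upper_offdiag <- function(m) m[upper.tri(m)]

#' All-pairs Pearson correlation of gene expression vectors
#'
#' Computes the gene-by-gene Pearson correlation matrix of a complete
#' dataset. Genes with zero variance get correlation 0 to every other gene
#' (flagged via an attribute) rather than being removed, so matrices stay
#' aligned across datasets.
#'
#' @param ds a complete [expression_dataset()] with at least 3 arrays.
#' @return a symmetric correlation matrix with unit diagonal and attribute
#'   `flagged_genes`.
#' @export
pearson_matrix <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (anyNA(v)) stop("dataset contains missing values; preprocess first")
  if (ncol(v) < 3L) stop("need at least 3 arrays to correlate")
  sds <- apply(v, 1L, stats::sd)
  flagged <- rownames(v)[sds == 0]
  rho <- suppressWarnings(stats::cor(t(v)))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  attr(rho, "flagged_genes") <- flagged
  rho
}

#' Fisher z-transform of a correlation matrix
#'
#' Elementwise `z = 0.5 * log((1 + rho) / (1 - rho))`, after clipping
#' `|rho|` at `clip` so correlations of exactly +/-1 (self pairs, duplicated
#' genes) do not map to infinity.
#'
#' @param rho numeric matrix (or vector) of correlations in \[-1, 1\].
#' @param clip clipping bound, default `1 - 1e-6`.
#' @return matrix of the same shape; attributes preserved.
#' @export
fisher_z <- function(rho, clip = 1 - 1e-6) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(rho, -clip), clip)
  z <- 0.5 * log((1 + r) / (1 - r))
  if (is.matrix(rho)) {
    dim(z) <- dim(rho)
    dimnames(z) <- dimnames(rho)
    attr(z, "flagged_genes") <- attr(rho, "flagged_genes")
  }
  z
}

#' Standardize a z-matrix to the standard normal scale
#'
#' Shifts and scales a symmetric matrix of Fisher z values so the
#' off-diagonal entries have empirical mean 0 and standard deviation 1. The
#' statistics are computed on the off-diagonal upper triangle (each unordered
#' pair counted once) and the diagonal is set to `NA`.
#'
#' @param zmat symmetric numeric matrix of z values.
#' @param provenance,n_datasets passed to [connection_matrix()].
#' @return a [connection_matrix()].
#' @export
standardize_connection <- function(zmat, provenance = "single-dataset",
                                   n_datasets = 1L) {
  stopifnot(is.matrix(zmat), nrow(zmat) == ncol(zmat))
  vals <- upper_offdiag(zmat)
  m <- mean(vals, na.rm = TRUE)
  s <- stats::sd(vals, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("degenerate correlation structure")
  z <- (zmat - m) / s
  connection_matrix(z, provenance = provenance, n_datasets = n_datasets,
                    flagged_genes = attr(zmat, "flagged_genes") %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-dataset connection matrix
#'
#' Convenience chain: Pearson correlation, Fisher z-transform, and
#' standardization to N(0,1) for one preprocessed dataset.
#'
#' @inheritParams pearson_matrix
#' @inheritParams fisher_z
#' @return a single-dataset [connection_matrix()].
#' @export
dataset_connection <- function(ds, clip = 1 - 1e-6) {
  standardize_connection(fisher_z(pearson_matrix(ds), clip = clip))
}

#' Average connection matrices over a compendium
#'
#' Aligns the matrices on the union of their gene ids, averages each gene
#' pair's normalized z values over the datasets where both genes are present,
#' and (by default) re-standardizes the result so the off-diagonal entries
#' again have mean 0 and standard deviation 1. The mean of D independent
#' standard-normal entries has standard deviation 1/sqrt(D), so without
#' re-standardization the aggregate is compressed towards 0.
#'
#' Pairs never observed together remain `NA` and are excluded downstream.
#'
#' @param mats list of [connection_matrix()] objects.
#' @param restandardize rescale the averaged matrix back to mean 0 / sd 1
#'   (default `TRUE`).
#' @return an aggregated [connection_matrix()].
#' @export
aggregate_connection <- function(mats, restandardize = TRUE) {
  if (!length(mats)) stop("no connection matrices to aggregate")
  stopifnot(all(vapply(mats, inherits, logical(1L), "connection_matrix")))
  if (length(mats) == 1L && !restandardize) return(mats[[1L]])
  genes <- unique(unlist(lapply(mats, `[[`, "gene_ids")))
  if (!length(genes)) stop("empty gene universe")
  n <- length(genes)
  acc <- matrix(0, n, n, dimnames = list(genes, genes))
  cnt <- matrix(0L, n, n)
  for (cm in mats) {
    idx <- match(cm$gene_ids, genes)
    z <- cm$z
    z[is.na(z)] <- 0                       # diagonal; counted out below
    acc[idx, idx] <- acc[idx, idx] + z
    obs <- !is.na(cm$z)
    cnt[idx, idx] <- cnt[idx, idx] + obs
  }
  avg <- acc / cnt                         # 0/0 -> NaN for never-seen pairs
  avg[cnt == 0L] <- NA_real_
  diag(avg) <- NA_real_
  if (restandardize) {
    standardize_connection(avg, provenance = "aggregated",
                           n_datasets = length(mats))
  } else {
    connection_matrix(avg, provenance = "aggregated",
                      n_datasets = length(mats))
  }
}

#' Build a species' aggregated connection matrix from its compendium
#'
#' @param datasets list of preprocessed [expression_dataset()] objects.
#' @param clip clipping bound for [fisher_z()].
#' @return an aggregated [connection_matrix()].
#' @export
compendium_connection <- function(datasets, clip = 1 - 1e-6) {
  mats <- lapply(datasets, dataset_connection, clip = clip)
  aggregate_connection(mats)
}

#' Write a connection matrix as TSV
#'
#' Gene-by-gene tab-delimited table preceded by a `#`-prefixed JSON header
#' line recording provenance.
#'
#' @param cm a [connection_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connection_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connection_matrix"))
  hdr <- jsonlite::toJSON(list(provenance = cm$provenance,
                               n_datasets = cm$n_datasets,
                               n_genes = length(cm$gene_ids)),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  df <- data.frame(gene = cm$gene_ids, cm$z, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connection matrix written by [write_connection_matrix()]
#'
#' @param path input path.
#' @return a [connection_matrix()].
#' @export
read_connection_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  meta <- list(provenance = "single-dataset", n_datasets = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    meta <- utils::modifyList(meta, jsonlite::fromJSON(sub("^#", "", first)))
    skip <- 1L
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  z <- as.matrix(df[, -1L, drop = FALSE])
  rownames(z) <- df[[1L]]
  connection_matrix(z, provenance = meta$provenance,
                    n_datasets = meta$n_datasets)
}
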