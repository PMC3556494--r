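#' Expression datasets
#'
#' An `expression_dataset` is one experiment's gene-by-array matrix of
#' log-ratio expression values, with gene identifiers as row names, array
#' identifiers as column names, and `NA` marking missing measurements.
#' An optional replicate grouping (named list of array-id character vectors)
#' records which arrays are biological replicates of one another.
#'
#' @param values numeric matrix, genes in rows, arrays in columns; both
#'   dimensions must carry unique names.
#' @param dataset_id single string identifying the experiment.
#' @param replicate_groups optional named list partitioning (a subset of) the
#'   array ids into replicate groups; arrays not listed are treated as
#'   singletons.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, dataset_id = "dataset",
                               replicate_groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  gid <- rownames(values)
  aid <- colnames(values)
  if (is.null(gid) || is.null(aid))
    stop("'values' must have row (gene) and column (array) names")
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(aid))
    stop("duplicate array id: ", aid[duplicated(aid)][1L])
  if (!is.null(replicate_groups)) {
    members <- unlist(replicate_groups, use.names = FALSE)
    unknown <- setdiff(members, aid)
    if (length(unknown))
      stop("replicate group references unknown array: ", unknown[1L])
    if (anyDuplicated(members))
      stop("array appears in more than one replicate group: ",
           members[duplicated(members)][1L])
  }
  structure(
    list(values = values, dataset_id = dataset_id,
         replicate_groups = replicate_groups),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  v <- x$values
  cat(sprintf("expression_dataset '%s': %d genes x %d arrays (%d missing)\n",
              x$dataset_id, nrow(v), ncol(v), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Reads a gene-by-array expression table. The `tsv` dialect has gene ids in
#' the first column followed by one numeric column per array. The `pcl`
#' dialect additionally carries `NAME` and `GWEIGHT` annotation columns
#' (parsed and dropped) and may contain an `EWEIGHT` row (ignored). Empty
#' fields, `NA`, `na`, `nan` and `NaN` are read as missing values.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"pcl"`.
#' @param dataset_id identifier stored on the returned dataset; defaults to
#'   the file name without extension.
#' @return an [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "pcl"),
                                   dataset_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  n_anno <- if (dialect == "pcl") 3L else 1L
  if (length(header) <= n_anno)
    stop("expression file has no array columns: ", path)
  array_ids <- header[-seq_len(n_anno)]
  # PCL files may carry an EWEIGHT row right after the header
  line_offset <- 1L
  if (dialect == "pcl" && length(body) &&
      toupper(body[[1L]][1L]) == "EWEIGHT") {
    body <- body[-1L]
    line_offset <- 2L
  }
  if (!length(body)) stop("expression file has no gene rows: ", path)
  n_col <- n_anno + length(array_ids)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != n_col)
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + line_offset, n_col, length(body[[i]])))
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  raw <- vapply(body, function(f) f[-seq_len(n_anno)],
                character(length(array_ids)))
  # vapply returns a vector when there is a single array column
  raw <- if (is.null(dim(raw))) matrix(raw, ncol = 1L) else t(raw)
  raw[raw %in% c("", "NA", "na", "nan", "NaN")] <- NA_character_
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value '%s' for gene %s",
                 raw[bad[1L, , drop = FALSE]], gene_ids[bad[1L, 1L]]))
  dimnames(values) <- list(gene_ids, array_ids)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  expression_dataset(values, dataset_id = dataset_id)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] for the `tsv` dialect; missing
#' values are written as `NA`.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes measured in too few arrays
#'
#' Drops genes present (non-missing) in less than `min_fraction` of the
#' arrays; a gene observed in exactly `min_fraction` of the arrays is kept.
#'
#' @param ds an [expression_dataset()].
#' @param min_fraction minimum fraction of arrays a gene must be observed in,
#'   in (0, 1]; default 0.5.
#' @return the filtered dataset, gene order preserved.
#' @export
filter_low_coverage_genes <- function(ds, min_fraction = 0.5) {
  stopifnot(inherits(ds, "expression_dataset"),
            min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(ds$values))
  keep <- frac >= min_fraction
  if (!any(keep)) stop("no genes survive filter")
  expression_dataset(ds$values[keep, , drop = FALSE], ds$dataset_id,
                     ds$replicate_groups)
}

# Pairwise Euclidean gene-gene distances on mutually observed arrays,
# rescaled by sqrt(n_arrays / n_shared) so sparsely shared genes are not
# spuriously near. Genes with no shared arrays get Inf.
gene_distances <- function(values) {
  obs <- !is.na(values)
  v0 <- values
  v0[!obs] <- 0
  sq <- v0^2
  shared <- tcrossprod(obs * 1)                     # counts of shared arrays
  ss <- tcrossprod(sq, obs) + tcrossprod(obs, sq) - 2 * tcrossprod(v0)
  ss[ss < 0] <- 0                                   # numerical noise
  d <- sqrt(ss * ncol(values) / pmax(shared, 1L))
  d[shared == 0L] <- Inf
  diag(d) <- Inf
  d
}

#' Impute missing values by k-nearest-neighbour averaging
#'
#' Each missing cell (gene g, array a) is replaced by the unweighted mean of
#' the values at array a of the `k` genes nearest to g by Euclidean distance,
#' where the distance is computed on the arrays where both genes are observed
#' and scaled by `sqrt(n_arrays / n_shared)`. Candidate neighbours must be
#' observed at array a; with fewer than `k` candidates all of them are used.
#' If no candidate exists the gene's own row mean is used, and failing that
#' the array's column mean, with a warning.
#'
#' @param ds an [expression_dataset()]; genes should already have passed the
#'   coverage filter.
#' @param k number of neighbours, default 10.
#' @return the dataset with no missing values; observed cells are unchanged.
#' @export
knn_impute <- function(ds, k = 10L) {
  stopifnot(inherits(ds, "expression_dataset"), k >= 1L)
  v <- ds$values
  if (!anyNA(v)) return(ds)
  d <- gene_distances(v)
  obs <- !is.na(v)
  miss <- which(!obs, arr.ind = TRUE)
  out <- v
  fallbacks <- 0L
  for (r in seq_len(nrow(miss))) {
    g <- miss[r, 1L]; a <- miss[r, 2L]
    cand <- which(obs[, a] & is.finite(d[, g]))
    if (length(cand)) {
      ord <- cand[order(d[cand, g], cand)]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[g, a] <- mean(v[nn, a])
    } else {
      fill <- mean(v[g, ], na.rm = TRUE)
      if (is.nan(fill)) fill <- mean(v[, a], na.rm = TRUE)
      out[g, a] <- fill
      fallbacks <- fallbacks + 1L
    }
  }
  if (fallbacks)
    warning(sprintf("%d missing cells had no eligible neighbour; %s",
                    fallbacks, "row/column means used"))
  if (anyNA(out)) stop("imputation failed to fill all missing values")
  expression_dataset(out, ds$dataset_id, ds$replicate_groups)
}

#' Average biological replicate arrays
#'
#' Collapses each replicate group to a single column holding the arithmetic
#' mean of the group's arrays; arrays not mentioned in any group are kept as
#' singletons. Output columns are named by group.
#'
#' @param ds an [expression_dataset()].
#' @param groups named list of array-id character vectors; defaults to the
#'   dataset's own `replicate_groups`.
#' @return the dataset with one column per group and `replicate_groups`
#'   cleared.
#' @export
average_replicates <- function(ds, groups = ds$replicate_groups) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (is.null(groups) || !length(groups))
    return(expression_dataset(v, ds$dataset_id))
  aid <- colnames(v)
  members <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(members, aid)
  if (length(unknown)) stop("unknown array in replicate group: ", unknown[1L])
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  singles <- setdiff(aid, members)
  groups <- c(groups, stats::setNames(as.list(singles), singles))
  # preserve array order: place each group at its first member's position
  first <- vapply(groups, function(g) match(g[1L], aid), integer(1L))
  groups <- groups[order(first)]
  out <- vapply(groups, function(g)
    rowMeans(v[, g, drop = FALSE], na.rm = FALSE), numeric(nrow(v)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(v),
                                       dimnames = list(rownames(v), names(groups)))
  expression_dataset(out, ds$dataset_id)
}

#' Read a replicate-group sidecar table
#'
#' Two-column TSV (`array_id`, `group_id`); arrays absent from the file are
#' singletons.
#'
#' @param path path to the TSV file.
#' @return named list of array-id vectors suitable for
#'   [average_replicates()].
#' @export
read_replicate_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, col.names = c("array_id", "group_id"))
  if (tolower(df$array_id[1L]) %in% c("array_id", "array")) df <- df[-1L, ]
  split(df$array_id, df$group_id)
}

#' Full preprocessing chain for one dataset
#'
#' Applies the coverage filter, KNN imputation (K = 10, Euclidean distance)
#' and replicate averaging in that order, yielding a complete matrix.
#'
#' @inheritParams filter_low_coverage_genes
#' @inheritParams knn_impute
#' @param groups replicate grouping for [average_replicates()].
#' @return a complete (no missing values) [expression_dataset()].
#' @export
preprocess_dataset <- function(ds, min_fraction = 0.5, k = 10L,
                               groups = ds$replicate_groups) {
  ds <- filter_low_coverage_genes(ds, min_fraction)
  ds <- knn_impute(ds, k)
  average_replicates(ds, groups)
}

#' Read and validate a one-to-one ortholog map
#'
#' Two-column TSV pairing species-A with species-B gene identifiers. The map
#' must be strictly one-to-one: a gene appearing twice on either side is an
#' error.
#'
#' @param path path to the TSV file; a header row is detected and skipped if
#'   its first field is non-unique-looking (`geneA`/`gene_a`/`a`, case
#'   insensitive).
#' @return an `ortholog_map`: data.frame with columns `gene_a`, `gene_b` and
#'   attribute `n_pairs`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog map must have two columns")
  df <- df[, 1:2]
  names(df) <- c("gene_a", "gene_b")
  if (nrow(df) && tolower(df$gene_a[1L]) %in% c("genea", "gene_a", "a"))
    df <- df[-1L, , drop = FALSE]
  ortholog_map(df$gene_a, df$gene_b)
}

#' Construct a one-to-one ortholog map
#'
#' @param gene_a,gene_b equal-length character vectors of matched gene ids.
#' @return an `ortholog_map` object.
#' @export
ortholog_map <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  stopifnot(length(gene_a) == length(gene_b))
  if (!length(gene_a)) stop("no ortholog pairs")
  if (anyDuplicated(gene_a))
    stop("gene mapped to multiple partners: ", gene_a[duplicated(gene_a)][1L])
  if (anyDuplicated(gene_b))
    stop("gene mapped to multiple partners: ", gene_b[duplicated(gene_b)][1L])
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       stringsAsFactors = FALSE),
            n_pairs = length(gene_a),
            class = c("ortholog_map", "data.frame"))
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d one-to-one pairs\n", attr(x, "n_pairs")))
  invisible(x)
}
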