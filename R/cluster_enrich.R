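#' Assemble a gene-by-condition matrix of condition-specific LNS
#'
#' Binds per-dataset-pair `lns` objects into one profile matrix: rows are
#' species-A gene ids, columns are dataset-pair contexts, entries the
#' condition-specific LNS (missing where a pair could not be scored).
#'
#' @param lns_list list of `lns` objects with distinct contexts.
#' @return numeric matrix with gene row names and context column names.
#' @export
lns_profile_matrix <- function(lns_list) {
  stopifnot(length(lns_list) >= 1L,
            all(vapply(lns_list, inherits, logical(1L), "lns")))
  ctx <- vapply(lns_list, `[[`, character(1L), "context")
  if (anyDuplicated(ctx)) stop("duplicate contexts in lns_list")
  genes <- sort(unique(unlist(lapply(lns_list, function(x) x$table$gene_a))))
  m <- matrix(NA_real_, length(genes), length(lns_list),
              dimnames = list(genes, ctx))
  for (j in seq_along(lns_list)) {
    tab <- lns_list[[j]]$table
    m[match(tab$gene_a, genes), j] <- tab$lns
  }
  m
}

#' Choose the number of clusters by the gap statistic
#'
#' Runs the gap statistic (uniform reference distribution, k-means clustering
#' with multiple restarts) over 1..`k_max` clusters and selects k by the
#' first-SE-max rule. Rows with any missing value are dropped with a message.
#'
#' @param m numeric profile matrix (genes x conditions).
#' @param k_max largest k considered, default 10.
#' @param seed integer seed, default 17.
#' @param n_boot reference sets for the gap statistic, default 50.
#' @return selected k (integer).
#' @export
choose_k <- function(m, k_max = 10L, seed = 17L, n_boot = 50L) {
  m <- drop_incomplete_rows(m)
  if (nrow(m) < k_max)
    stop("fewer complete rows than k_max")
  set.seed(seed)
  gap <- cluster::clusGap(m, FUNcluster = function(x, k)
    stats::kmeans(x, k, nstart = 10L, iter.max = 50L),
    K.max = k_max, B = n_boot, verbose = FALSE)
  tab <- gap$Tab
  as.integer(cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                            method = "firstSEmax"))
}

drop_incomplete_rows <- function(m) {
  stopifnot(is.matrix(m))
  ok <- stats::complete.cases(m)
  if (!all(ok))
    message(sprintf("dropping %d rows with missing condition-specific LNS",
                    sum(!ok)))
  m[ok, , drop = FALSE]
}

#' k-means clustering of condition-specific LNS profiles
#'
#' Clusters complete gene profiles with `stats::kmeans` using 10 random
#' restarts, keeping the solution with the lowest within-cluster sum of
#' squares. Every gene's assignment is its nearest center.
#'
#' @param m numeric profile matrix (genes x conditions); rows with missing
#'   values are dropped with a message.
#' @param k number of clusters.
#' @param seed integer seed, default 17.
#' @param nstart random restarts, default 10.
#' @return list with `assignment` (named integer vector), `centers`
#'   (k x conditions matrix), `withinss_total`.
#' @export
kmeans_profiles <- function(m, k, seed = 17L, nstart = 10L) {
  m <- drop_incomplete_rows(m)
  stopifnot(k >= 1L, k <= nrow(m))
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  list(assignment = stats::setNames(km$cluster, rownames(m)),
       centers = km$centers, withinss_total = km$tot.withinss)
}

#' Arrange cluster centers hierarchically
#'
#' Average-linkage hierarchical clustering of the Euclidean distances
#' between cluster centers; returns the dendrogram leaf order, used to
#' arrange clusters in heatmap displays.
#'
#' @param centers numeric matrix of cluster centers (k x conditions).
#' @return integer vector: cluster indices in leaf order.
#' @export
order_clusters <- function(centers) {
  stopifnot(is.matrix(centers) || is.data.frame(centers))
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k == 1L) return(1L)
  if (k == 2L) return(1:2)
  hc <- stats::hclust(stats::dist(centers), method = "average")
  # reorder leaves by center magnitude (heatmap convention) so collinear
  # centers come out monotone along the line
  dd <- stats::reorder(stats::as.dendrogram(hc), rowMeans(centers),
                       agglo.FUN = mean)
  stats::order.dendrogram(dd)
}

#' Read a flat annotation table
#'
#' Two-column TSV (`term_id`, `gene_id`) mapping annotation terms to genes;
#' terms are treated as flat sets (no ontology propagation).
#'
#' @param path path to the TSV file.
#' @return named list of gene-id character vectors, one per term.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("term_id", "gene_id"))
  if (tolower(df$term_id[1L]) %in% c("term_id", "term")) df <- df[-1L, ]
  if (!nrow(df)) stop("no annotations")
  lapply(split(df$gene_id, df$term_id), unique)
}

#' Hypergeometric enrichment of annotation terms per cluster
#'
#' For every (cluster, term) combination, tests over-representation of the
#' term's genes in the cluster with the hypergeometric upper tail, applies a
#' Bonferroni correction across all tested combinations jointly, and reports
#' those below `alpha`.
#'
#' @param assignment named integer vector of cluster memberships (names are
#'   gene ids), as from [kmeans_profiles()].
#' @param annotations named list of term gene sets, as from
#'   [read_annotation_table()].
#' @param universe gene universe for the test; defaults to the clustered
#'   genes. Cluster genes must be a subset.
#' @param alpha Bonferroni-corrected significance cutoff, default 0.01.
#' @return data.frame with columns `cluster`, `term`, `overlap`,
#'   `cluster_size`, `term_size`, `p`, `p_bonferroni`, sorted by corrected
#'   p; attribute `n_tests` records the correction factor. Only rows with
#'   `p_bonferroni < alpha` are returned.
#' @export
cluster_enrichment <- function(assignment, annotations, universe = NULL,
                               alpha = 0.01) {
  stopifnot(is.numeric(assignment), !is.null(names(assignment)))
  genes <- names(assignment)
  if (is.null(universe)) universe <- genes
  if (length(setdiff(genes, universe)))
    stop("clustered genes must be a subset of the universe")
  n_u <- length(universe)
  ann <- lapply(annotations, intersect, universe)
  empty <- vapply(ann, length, integer(1L)) == 0L
  if (any(empty)) {
    message(sprintf("skipping %d terms with no genes in the universe",
                    sum(empty)))
    ann <- ann[!empty]
  }
  clusters <- sort(unique(assignment))
  rows <- list()
  for (cl in clusters) {
    cg <- genes[assignment == cl]
    for (tm in names(ann)) {
      ts <- ann[[tm]]
      k <- length(intersect(cg, ts))
      p <- stats::phyper(k - 1L, length(ts), n_u - length(ts), length(cg),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term = tm, overlap = k, cluster_size = length(cg),
        term_size = length(ts), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable (cluster, term) combinations")
  rep_df <- do.call(rbind, rows)
  n_tests <- nrow(rep_df)
  rep_df$p_bonferroni <- pmin(1, rep_df$p * n_tests)
  rep_df <- rep_df[rep_df$p_bonferroni < alpha, , drop = FALSE]
  rep_df <- rep_df[order(rep_df$p_bonferroni), , drop = FALSE]
  rownames(rep_df) <- NULL
  attr(rep_df, "n_tests") <- n_tests
  rep_df
}

#' Write heatmap ordering for external plotting
#'
#' Emits a TSV of genes sorted by hierarchically arranged cluster, with the
#' cluster id and a boundary marker at each cluster's first gene.
#'
#' @param assignment named cluster assignment.
#' @param centers cluster centers used for [order_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_order <- function(assignment, centers, path) {
  ord <- order_clusters(as.matrix(centers))
  pieces <- lapply(ord, function(cl) {
    g <- sort(names(assignment)[assignment == cl])
    data.frame(gene = g, cluster = cl,
               boundary = seq_along(g) == 1L, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, pieces), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
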