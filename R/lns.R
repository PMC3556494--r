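#' Local Network Similarity between two species' co-expression networks
#'
#' For each one-to-one ortholog pair (j, j'), LNS is the Pearson correlation
#' between the two genes' connection-weight vectors over all other matched
#' orthologs: `W(j)` holds species A's normalized z-scored co-expression
#' weights from gene j to the other N-1 orthologs, `W(j')` the matching
#' vector in species B, and `LNS = cor(W(j), W(j'))`. LNS lies in \[-1, 1\];
#' 1 means the gene's first-degree co-expression neighbourhood is perfectly
#' conserved, 0 is the expectation under no conservation, negative values
#' indicate inverted neighbourhoods. The self-entries z(j,j)/z(j',j') are
#' excluded from both vectors.
#'
#' Entries missing from either matrix (gene pairs never co-measured) are
#' dropped pairwise; an LNS value is reported as `NA` with a reason flag when
#' fewer than 3 aligned weights remain or either vector is constant.
#'
#' @param conn_a,conn_b [connection_matrix()] objects for species A and B
#'   (typically aggregated over each compendium).
#' @param orthologs an [ortholog_map()]; pairs absent from either matrix are
#'   reported with missing LNS and a reason.
#' @param context label stored on the result, default `"global"`.
#' @return an object of class `lns`: list with `table` (data.frame
#'   `gene_a`, `gene_b`, `lns`, `n_used`, `flag`), `context`, `n_pairs`.
#' @seealso [condition_lns()], [lns_null()], [count_diverged()]
#' @export
lns <- function(conn_a, conn_b, orthologs, context = "global") {
  stopifnot(inherits(conn_a, "connection_matrix"),
            inherits(conn_b, "connection_matrix"),
            inherits(orthologs, "ortholog_map"))
  in_a <- orthologs$gene_a %in% conn_a$gene_ids
  in_b <- orthologs$gene_b %in% conn_b$gene_ids
  present <- in_a & in_b
  if (sum(present) < 3L)
    stop("fewer than 3 ortholog pairs present in both connection matrices")
  ga <- orthologs$gene_a[present]
  gb <- orthologs$gene_b[present]
  A <- conn_a$z[ga, ga, drop = FALSE]
  B <- conn_b$z[gb, gb, drop = FALSE]
  r <- rowwise_pearson(A, B)
  flag <- rep("ok", length(ga))
  flag[is.na(r$r) & r$n >= 3L] <- "constant-vector"
  flag[r$n < 3L] <- "insufficient-overlap"
  tab <- data.frame(gene_a = ga, gene_b = gb, lns = r$r, n_used = r$n,
                    flag = flag, stringsAsFactors = FALSE)
  if (any(!present)) {
    absent <- data.frame(gene_a = orthologs$gene_a[!present],
                         gene_b = orthologs$gene_b[!present],
                         lns = NA_real_, n_used = 0L,
                         flag = ifelse(!in_a[!present], "absent-from-A",
                                       "absent-from-B"),
                         stringsAsFactors = FALSE)
    tab <- rbind(tab, absent)
    tab <- tab[match(orthologs$gene_a, tab$gene_a), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, context = context,
                 n_pairs = attr(orthologs, "n_pairs")),
            class = "lns")
}

# Row-wise Pearson correlation between two aligned square matrices, skipping
# the diagonal and any position that is NA in either matrix. Row i yields
# cor(A[i, -i], B[i, -i]) over jointly observed positions. Vectorized over
# rows; the per-pair loop equivalent serves as the test oracle.
rowwise_pearson <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  M <- !is.na(A) & !is.na(B)
  diag(M) <- FALSE
  A0 <- ifelse(M, A, 0)
  B0 <- ifelse(M, B, 0)
  n <- rowSums(M)
  sx <- rowSums(A0); sy <- rowSums(B0)
  sxx <- rowSums(A0 * A0); syy <- rowSums(B0 * B0)
  sxy <- rowSums(A0 * B0)
  num <- n * sxy - sx * sy
  den2 <- (n * sxx - sx^2) * (n * syy - sy^2)
  r <- rep(NA_real_, nrow(A))
  ok <- n >= 3L & den2 > 0
  r[ok] <- num[ok] / sqrt(den2[ok])
  r <- pmin(pmax(r, -1), 1)
  list(r = r, n = as.integer(n))
}

#' LNS of a single ortholog pair from explicit connection vectors
#'
#' @param w_a,w_b aligned numeric vectors of connection weights (length at
#'   least 3, ordered identically by orthology).
#' @return Pearson correlation, or `NA` if either vector is constant over
#'   the jointly observed positions.
#' @export
lns_pair <- function(w_a, w_b) {
  stopifnot(length(w_a) == length(w_b), length(w_a) >= 3L)
  ok <- !is.na(w_a) & !is.na(w_b)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(w_a[ok]) == 0 || stats::sd(w_b[ok]) == 0) return(NA_real_)
  min(max(stats::cor(w_a[ok], w_b[ok]), -1), 1)
}

#' Condition-specific LNS from one matched dataset pair
#'
#' Computes single-dataset connection matrices for one perturbation in each
#' species and scores every ortholog pair. Because the connection weights are
#' correlations between genes over arrays, the result does not require the
#' two time courses to be aligned or sampled identically.
#'
#' @param ds_a,ds_b preprocessed [expression_dataset()] objects, one per
#'   species, covering the same perturbation.
#' @param orthologs an [ortholog_map()].
#' @param context label for the dataset pair; defaults to
#'   `"<idA>|<idB>"`.
#' @return an `lns` object.
#' @export
condition_lns <- function(ds_a, ds_b, orthologs, context = NULL) {
  if (is.null(context))
    context <- paste(ds_a$dataset_id, ds_b$dataset_id, sep = "|")
  lns(dataset_connection(ds_a), dataset_connection(ds_b), orthologs,
      context = context)
}

#' Randomized-ortholog null distribution of LNS
#'
#' Simulates zero conservation: the ortholog assignment is shuffled along the
#' species-B axis by a uniform random permutation (pairs mapped back to
#' themselves by chance are kept), leaving both co-expression networks
#' intact, and LNS is recomputed for every pair. Samples from all
#' permutations are pooled.
#'
#' @inheritParams lns
#' @param n_permutations number of independent shuffles, default 50.
#' @param seed integer seed, default 17.
#' @return an object of class `lns_null`: list with `samples`, `n_permutations`,
#'   `seed`, `mean`, `sd`.
#' @export
lns_null <- function(conn_a, conn_b, orthologs, n_permutations = 50L,
                     seed = 17L) {
  stopifnot(n_permutations >= 1L)
  present <- orthologs$gene_a %in% conn_a$gene_ids &
    orthologs$gene_b %in% conn_b$gene_ids
  ga <- orthologs$gene_a[present]
  gb <- orthologs$gene_b[present]
  if (length(ga) < 3L) stop("fewer than 3 usable ortholog pairs")
  A <- conn_a$z[ga, ga, drop = FALSE]
  B <- conn_b$z[gb, gb, drop = FALSE]
  n <- length(ga)
  set.seed(seed)
  samples <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    perm <- sample.int(n)
    r <- rowwise_pearson(A, B[perm, perm, drop = FALSE])$r
    samples[[p]] <- r[!is.na(r)]
  }
  s <- unlist(samples, use.names = FALSE)
  structure(list(samples = s, n_permutations = n_permutations, seed = seed,
                 mean = mean(s), sd = stats::sd(s)),
            class = "lns_null")
}

#' @export
print.lns_null <- function(x, ...) {
  cat(sprintf(
    "lns_null: %d pooled LNS samples from %d permutations (seed %d)\n",
    length(x$samples), x$n_permutations, x$seed))
  cat(sprintf("  mean %.4f, sd %.4f\n", x$mean, x$sd))
  invisible(x)
}

#' Count orthologs diverged relative to the randomized null
#'
#' A pair is counted as diverged when its LNS falls below the mean of the
#' pooled null samples. Significance of the overall shift between the real
#' and null LNS distributions is assessed by a two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test. Pairs with missing LNS are excluded and
#' reported.
#'
#' @param x an `lns` object.
#' @param null an `lns_null` for the same context.
#' @return list with `count`, `p`, `cutoff` (the null mean), `n_scored`,
#'   `n_missing`.
#' @export
count_diverged <- function(x, null) {
  stopifnot(inherits(x, "lns"), inherits(null, "lns_null"))
  v <- x$table$lns
  miss <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (!length(v)) stop("no scored ortholog pairs")
  cutoff <- null$mean
  p <- stats::wilcox.test(v, null$samples, alternative = "two.sided",
                          exact = FALSE)$p.value
  list(count = sum(v < cutoff), p = p, cutoff = cutoff,
       n_scored = length(v), n_missing = miss)
}

#' Within-species LNS by compendium subsampling
#'
#' Splits one species' datasets into two disjoint random halves, builds an
#' aggregated connection matrix per half, and scores every gene against
#' itself across the halves under the identity orthology. The resulting
#' distribution bounds what full conservation looks like given the noise and
#' condition coverage of the compendium.
#'
#' @param datasets list of at least 2 preprocessed [expression_dataset()]
#'   objects.
#' @param split_seed seed for the random half split, default 17.
#' @return an `lns` object with `gene_a == gene_b` and context
#'   `"within-species"`.
#' @export
within_species_lns <- function(datasets, split_seed = 17L) {
  if (length(datasets) < 2L) stop("need at least 2 datasets to split")
  set.seed(split_seed)
  idx <- sample(rep_len(c(TRUE, FALSE), length(datasets)))
  half1 <- compendium_connection(datasets[idx])
  half2 <- compendium_connection(datasets[!idx])
  genes <- intersect(half1$gene_ids, half2$gene_ids)
  lns(half1, half2, ortholog_map(genes, genes), context = "within-species")
}

#' @export
print.lns <- function(x, ...) {
  tab <- x$table
  scored <- tab$lns[!is.na(tab$lns)]
  cat(sprintf("lns [%s]: %d ortholog pairs (%d scored, %d missing)\n",
              x$context, nrow(tab), length(scored),
              sum(is.na(tab$lns))))
  if (length(scored))
    cat(sprintf("  median %.3f, range [%.3f, %.3f]\n",
                stats::median(scored), min(scored), max(scored)))
  invisible(x)
}

#' @export
summary.lns <- function(object, null = NULL, ...) {
  tab <- object$table
  scored <- tab$lns[!is.na(tab$lns)]
  out <- list(context = object$context,
              n_pairs = nrow(tab),
              n_scored = length(scored),
              n_missing = sum(is.na(tab$lns)),
              median = stats::median(scored),
              mean = mean(scored),
              quartiles = stats::quantile(scored, c(0.25, 0.5, 0.75)),
              n_negative = sum(scored < 0))
  if (!is.null(null)) out$diverged <- count_diverged(object, null)
  class(out) <- "summary.lns"
  out
}

#' @export
print.summary.lns <- function(x, ...) {
  cat(sprintf("LNS summary [%s]\n", x$context))
  cat(sprintf("  pairs: %d scored / %d total (%d missing)\n",
              x$n_scored, x$n_pairs, x$n_missing))
  cat(sprintf("  median %.4f, mean %.4f, %d pairs with LNS < 0\n",
              x$median, x$mean, x$n_negative))
  if (!is.null(x$diverged))
    cat(sprintf("  diverged below null mean (%.4f): %d  (Mann-Whitney p = %.3g)\n",
                x$diverged$cutoff, x$diverged$count, x$diverged$p))
  invisible(x)
}

#' @export
as.data.frame.lns <- function(x, ...) x$table

#' Histogram of an LNS distribution, optionally against its null
#'
#' @param x an `lns` object.
#' @param null optional `lns_null` overlaid as a density line.
#' @param breaks histogram breaks, default 40.
#' @param ... passed to [graphics::hist()].
#' @export
plot.lns <- function(x, null = NULL, breaks = 40, ...) {
  v <- x$table$lns[!is.na(x$table$lns)]
  graphics::hist(v, breaks = breaks, freq = FALSE,
                 main = sprintf("LNS distribution [%s]", x$context),
                 xlab = "LNS", col = "grey85", border = "grey40",
                 xlim = c(-1, 1), ...)
  if (!is.null(null)) {
    d <- stats::density(null$samples)
    graphics::lines(d, col = "firebrick", lwd = 2)
    graphics::legend("topleft", legend = c("observed", "randomized null"),
                     fill = c("grey85", NA), border = c("grey40", NA),
                     lty = c(NA, 1), col = c(NA, "firebrick"), bty = "n")
  }
  invisible(x)
}

#' Write an LNS table as TSV
#'
#' Columns: gene_a, gene_b, context, lns, n_used, flag.
#'
#' @param x an `lns` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lns_table <- function(x, path) {
  stopifnot(inherits(x, "lns"))
  df <- data.frame(gene_a = x$table$gene_a, gene_b = x$table$gene_b,
                   context = x$context, lns = x$table$lns,
                   n_used = x$table$n_used, flag = x$table$flag,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write null-distribution summaries as TSV
#'
#' @param null an `lns_null`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_summary <- function(null, path) {
  stopifnot(inherits(null, "lns_null"))
  q <- stats::quantile(null$samples, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99))
  df <- data.frame(n = length(null$samples),
                   n_permutations = null$n_permutations,
                   seed = null$seed, mean = null$mean, sd = null$sd,
                   t(q), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
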