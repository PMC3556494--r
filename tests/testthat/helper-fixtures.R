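# Shared fixture builders and independent oracles.

# small expression_dataset from a matrix literal
make_ds <- function(values, genes = NULL, arrays = NULL, id = "toy",
                    groups = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(arrays)) arrays <- sprintf("a%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, arrays)
  expression_dataset(values, dataset_id = id, replicate_groups = groups)
}

# a seeded random complete dataset
random_ds <- function(n_genes, n_arrays, seed, id = "rnd") {
  set.seed(seed)
  make_ds(matrix(rnorm(n_genes * n_arrays), n_genes, n_arrays), id = id)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# naive two-loop Pearson matrix oracle
pearson_oracle <- function(values) {
  n <- nrow(values)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(values),
                                                rownames(values)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- values[i, ]; y <- values[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# brute-force per-pair LNS oracle: loops over pairs, builds both connection
# vectors explicitly, drops the self entry and unmatched positions, and
# correlates with stats::cor
lns_oracle <- function(conn_a, conn_b, orthologs) {
  ga <- orthologs$gene_a
  gb <- orthologs$gene_b
  A <- conn_a$z[ga, ga, drop = FALSE]
  B <- conn_b$z[gb, gb, drop = FALSE]
  vapply(seq_along(ga), function(i) {
    wa <- A[i, -i]; wb <- B[i, -i]
    ok <- !is.na(wa) & !is.na(wb)
    if (sum(ok) < 3L || sd(wa[ok]) == 0 || sd(wb[ok]) == 0) return(NA_real_)
    cor(wa[ok], wb[ok])
  }, numeric(1L))
}

# default two-species fixture, preprocessed and aggregated; cached per run
planted_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comp <- generate_compendium(synthetic_spec())
      pa <- lapply(comp$datasets_a, preprocess_dataset)
      pb <- lapply(comp$datasets_b, preprocess_dataset)
      cache <<- list(comp = comp,
                     conn_a = compendium_connection(pa),
                     conn_b = compendium_connection(pb))
    }
    cache
  }
})

# rank-based AUC for "ascending LNS flags planted divergent pairs"
auc_ascending <- function(lns_values, is_divergent) {
  ok <- !is.na(lns_values)
  v <- lns_values[ok]; d <- is_divergent[ok]
  cmp <- outer(v[d], v[!d], "<") + 0.5 * outer(v[d], v[!d], "==")
  mean(cmp)
}
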