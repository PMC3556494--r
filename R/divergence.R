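#' Normalize a sequence-divergence feature
#'
#' Applies the transformation used for divergence measures such as dN, dN/dS,
#' Ka and Ka/Ks: log2 transform, mean subtraction, and division by the
#' standard deviation (population form, i.e. denominator n). Nonpositive
#' values cannot be log-transformed and are dropped (returned as `NA`) with
#' a warning reporting the count.
#'
#' @param values numeric vector of positive feature values.
#' @return numeric vector of the same length; usable entries have mean 0 and
#'   sd 1, dropped entries are `NA`.
#' @export
normalize_feature <- function(values) {
  stopifnot(is.numeric(values))
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  usable <- !is.na(values) & values > 0
  n_dropped <- sum(!is.na(values) & values <= 0)
  if (n_dropped)
    warning(sprintf("%d nonpositive values dropped before log2 transform",
                    n_dropped))
  x <- log2(values[usable])
  if (length(x) < 3L) stop("fewer than 3 usable values")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("feature has zero variance after log2 transform")
  out[usable] <- (x - mean(x)) / s
  out
}

# Align an LNS table with a per-gene feature vector (named by species-A
# gene id); returns the paired complete cases.
align_lns_feature <- function(x, feature) {
  stopifnot(inherits(x, "lns"))
  if (is.null(names(feature)))
    stop("'feature' must be named by species-A gene id")
  v <- x$table$lns[match(names(feature), x$table$gene_a)]
  ok <- !is.na(v) & !is.na(feature)
  list(lns = v[ok], feature = unname(feature[ok]))
}

#' Correlate LNS with a continuous sequence feature
#'
#' Pearson correlation between per-ortholog LNS and a gene-level feature
#' (e.g. normalized dN/dS), with a permutation p-value obtained by randomly
#' re-matching the feature to the LNS values: `p = (1 + #{|r_perm| >= |r|})
#' / (n_perm + 1)`.
#'
#' @param x an `lns` object.
#' @param feature numeric vector named by species-A gene id (typically from
#'   [normalize_feature()]).
#' @param n_perm number of permutations, at least 100; default 1000.
#' @param seed integer seed, default 17.
#' @return list with `r`, `p_perm`, `n`.
#' @export
correlate_with_lns <- function(x, feature, n_perm = 1000L, seed = 17L) {
  stopifnot(n_perm >= 100L)
  al <- align_lns_feature(x, feature)
  if (length(al$lns) < 10L) stop("fewer than 10 aligned genes")
  r <- stats::cor(al$lns, al$feature)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(stats::cor(al$lns, sample(al$feature))) >= abs(r))
      exceed <- exceed + 1L
  }
  list(r = r, p_perm = (exceed + 1L) / (n_perm + 1L), n = length(al$lns))
}

#' Point-biserial correlation of LNS with a binary promoter feature
#'
#' Correlates LNS with a two-level categorical feature (e.g. TATA-containing
#' in both species vs not) using the point-biserial formula
#' `r = (m1 - m0) / s * sqrt(n1 * n0 / n^2)`, where `s` is the population
#' standard deviation of all LNS values; this is algebraically the Pearson
#' correlation with 0/1 coding. Significance is a permutation p-value as in
#' [correlate_with_lns()].
#'
#' @param x an `lns` object.
#' @param binary logical (or 0/1) vector named by species-A gene id.
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed, default 17.
#' @return list with `r`, `p_perm`, `n`, `n1`, `n0`.
#' @export
point_biserial <- function(x, binary, n_perm = 1000L, seed = 17L) {
  b <- as.logical(binary)
  names(b) <- names(binary)
  al <- align_lns_feature(x, ifelse(b, 1, 0))
  g <- al$feature > 0.5
  if (!any(g) || all(g)) stop("both classes must be non-empty")
  v <- al$lns
  n <- length(v); n1 <- sum(g); n0 <- n - n1
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("LNS values are constant")
  r <- (mean(v[g]) - mean(v[!g])) / s * sqrt(n1 * n0 / n^2)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    gp <- sample(g)
    rp <- (mean(v[gp]) - mean(v[!gp])) / s * sqrt(n1 * n0 / n^2)
    if (abs(rp) >= abs(r)) exceed <- exceed + 1L
  }
  list(r = r, p_perm = (exceed + 1L) / (n_perm + 1L), n = n, n1 = n1, n0 = n0)
}

#' Encode a three-level TATA status as a binary contrast
#'
#' TATA-box status per ortholog pair is one of `"both"`, `"one"`,
#' `"neither"`. The default contrast compares pairs TATA-containing in both
#' species against the rest; `"one_vs_neither"` restricts to pairs with a
#' TATA box in exactly one species versus none (pairs with `"both"` become
#' `NA`).
#'
#' @param status character vector with levels both/one/neither, named by
#'   species-A gene id.
#' @param contrast `"both_vs_rest"` (default) or `"one_vs_neither"`.
#' @return named logical vector suitable for [point_biserial()].
#' @export
tata_contrast <- function(status, contrast = c("both_vs_rest",
                                               "one_vs_neither")) {
  contrast <- match.arg(contrast)
  lv <- c("both", "one", "neither")
  if (length(setdiff(unique(status[!is.na(status)]), lv)))
    stop("TATA status levels must be 'both', 'one', 'neither'")
  out <- switch(contrast,
                both_vs_rest = status == "both",
                one_vs_neither = ifelse(status == "both", NA,
                                        status == "one"))
  names(out) <- names(status)
  out
}

#' Read a per-gene feature table
#'
#' TSV keyed by species-A gene id in the first column; remaining columns are
#' features (continuous or categorical).
#'
#' @param path path to the TSV file.
#' @return data.frame with gene ids as row names.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate gene id in feature table: ",
         df[[1L]][duplicated(df[[1L]])][1L])
  rownames(df) <- df[[1L]]
  df[, -1L, drop = FALSE]
}
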