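#' Mean-center a time-course dataset
#'
#' Subtracts each gene's mean over the time course so the average expression
#' of every row is 0 before Fourier analysis.
#'
#' @param ds a complete [expression_dataset()].
#' @return the centered dataset.
#' @export
mean_center <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (anyNA(v)) stop("dataset contains missing values; preprocess first")
  expression_dataset(v - rowMeans(v), ds$dataset_id, ds$replicate_groups)
}

# Per-gene DFT coefficients at the non-zero frequencies up to Nyquist.
# Rows of the returned complex matrix are genes, columns frequency indices
# 1..floor(T/2). Time points are assumed evenly spaced.
gene_dft <- function(values) {
  tp <- ncol(values)
  co <- t(stats::mvfft(t(values)))           # genes x frequencies 0..T-1
  co[, seq(2L, floor(tp / 2) + 1L), drop = FALSE]
}

#' Identify the dominant (cell-cycle) frequency of a time course
#'
#' Sums spectral power over all genes at each non-zero frequency up to the
#' Nyquist limit and returns the frequency index (cycles per time course)
#' with maximal total power. When no frequency dominates — its share of the
#' total non-zero-frequency power falls below `conf_threshold` times the
#' uniform share — the result is flagged low-confidence.
#'
#' @param ds a mean-centered, complete [expression_dataset()] with at least
#'   8 evenly spaced time points.
#' @param conf_threshold multiple of the uniform power share below which the
#'   call is flagged, default 2.
#' @return list with `frequency` (integer cycles per course), `power_share`,
#'   and `low_confidence` (logical).
#' @export
identify_period <- function(ds, conf_threshold = 2) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  if (ncol(v) < 8L) stop("need at least 8 time points")
  if (anyNA(v)) stop("dataset contains missing values; preprocess first")
  co <- gene_dft(v - rowMeans(v))
  power <- colSums(Mod(co)^2)
  f <- which.max(power)
  share <- power[f] / sum(power)
  list(frequency = as.integer(f), power_share = unname(share),
       low_confidence = share < conf_threshold / length(power))
}

#' Per-gene periodicity scores and peak phases at a given frequency
#'
#' Scores each gene by the fraction of its non-zero-frequency spectral power
#' carried by the target frequency, `|X_f|^2 / sum_{f'>0} |X_{f'}|^2`, so a
#' pure sinusoid at `freq` scores 1 regardless of amplitude. The phase is the
#' peak-time convention: a gene following `cos(2*pi*freq*t/T - phi)` over
#' time points `t = 0..T-1` is assigned phase `phi` in \[0, 2*pi).
#'
#' @param ds a complete [expression_dataset()] time course (centered
#'   internally).
#' @param freq frequency index in cycles per time course, as returned by
#'   [identify_period()].
#' @return data.frame with columns `gene_id`, `score`, `phase`.
#' @export
fourier_score <- function(ds, freq) {
  stopifnot(inherits(ds, "expression_dataset"), freq >= 1L)
  v <- ds$values
  if (anyNA(v)) stop("dataset contains missing values; preprocess first")
  co <- gene_dft(v - rowMeans(v))
  if (freq > ncol(co)) stop("frequency index beyond Nyquist limit")
  total <- rowSums(Mod(co)^2)
  target <- co[, freq]
  score <- ifelse(total > 0, Mod(target)^2 / total, 0)
  phase <- ifelse(Mod(target) > 0, (-Arg(target)) %% (2 * pi), 0)
  data.frame(gene_id = rownames(v), score = unname(score),
             phase = unname(phase), stringsAsFactors = FALSE)
}

#' Flag the top-scoring genes as periodic
#'
#' Orders genes by descending periodicity score (ties broken by gene id,
#' lexically) and flags the top `n_top` as cell-cycle regulated.
#'
#' @param results data.frame from [fourier_score()].
#' @param n_top number of genes to call periodic; must not exceed the gene
#'   count. The counts used on real compendia are dataset-specific choices.
#' @return `results` with an added logical column `periodic`; row order
#'   unchanged.
#' @export
select_periodic <- function(results, n_top) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "score") %in% names(results)),
            n_top >= 0L, n_top <= nrow(results))
  ord <- order(-results$score, results$gene_id)
  periodic <- logical(nrow(results))
  periodic[ord[seq_len(n_top)]] <- TRUE
  results$periodic <- periodic
  results
}

#' Suggest the number of periodic calls via a time-permutation null
#'
#' Permutes each gene's time series independently `n_perm` times, recomputes
#' periodicity scores, and suggests flagging the genes whose observed score
#' exceeds the null score quantile corresponding to `fdr` (a conservative
#' per-gene threshold against the pooled permuted scores).
#'
#' @inheritParams fourier_score
#' @param fdr target false-call rate against the permuted null, default 0.01.
#' @param n_perm number of permutations, default 20.
#' @param seed integer seed, default 17.
#' @return suggested `n_top` (integer).
#' @export
suggest_n_top <- function(ds, freq, fdr = 0.01, n_perm = 20L, seed = 17L) {
  obs <- fourier_score(ds, freq)$score
  v <- ds$values
  set.seed(seed)
  null_scores <- numeric(0)
  for (p in seq_len(n_perm)) {
    vp <- t(apply(v, 1L, sample))
    dimnames(vp) <- dimnames(v)
    dsp <- expression_dataset(vp, ds$dataset_id)
    null_scores <- c(null_scores, fourier_score(dsp, freq)$score)
  }
  thr <- stats::quantile(null_scores, 1 - fdr, names = FALSE)
  as.integer(sum(obs > thr))
}

#' Cross-species overlap of periodic gene calls
#'
#' Counts ortholog pairs called periodic in both species and tests
#' over-representation of the overlap with the exact hypergeometric upper
#' tail; a permutation p-value (random re-draws of set B within the ortholog
#' universe) is reported as a cross-check.
#'
#' @param set_a,set_b character vectors of species-A / species-B gene ids
#'   called periodic; must be subsets of the ortholog universe.
#' @param orthologs an [ortholog_map()] defining the universe.
#' @param n_perm permutations for the cross-check, default 2000.
#' @param seed integer seed, default 17.
#' @return list with `overlap`, `p_hyper`, `p_perm`, `n_universe`,
#'   `n_a`, `n_b`, and `degenerate` (TRUE when the overlap is forced).
#' @export
overlap_test <- function(set_a, set_b, orthologs, n_perm = 2000L,
                         seed = 17L) {
  stopifnot(inherits(orthologs, "ortholog_map"))
  n <- attr(orthologs, "n_pairs")
  if (!n) stop("empty ortholog universe")
  if (length(setdiff(set_a, orthologs$gene_a)))
    stop("set_a contains genes outside the ortholog universe")
  if (length(setdiff(set_b, orthologs$gene_b)))
    stop("set_b contains genes outside the ortholog universe")
  a <- orthologs$gene_a %in% set_a
  b <- orthologs$gene_b %in% set_b
  k <- sum(a & b)
  na <- sum(a); nb <- sum(b)
  degenerate <- na == n || nb == n || na == 0L || nb == 0L
  if (degenerate)
    warning("overlap is forced by set sizes; p-value degenerate")
  p_hyper <- stats::phyper(k - 1L, na, n - na, nb, lower.tail = FALSE)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    kp <- sum(a & sample(b))
    if (kp >= k) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1L) / (n_perm + 1L)
  list(overlap = k, p_hyper = p_hyper, p_perm = p_perm, n_universe = n,
       n_a = na, n_b = nb, degenerate = degenerate)
}
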