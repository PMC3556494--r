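#' Specification of a synthetic two-species compendium
#'
#' Describes the generative model behind [generate_compendium()]: genes
#' belong to co-expression modules; within each dataset every module has a
#' latent log-ratio factor per array drawn from N(0, module_signal_sd^2),
#' and a gene's value is its module's factor plus N(0, noise_sd^2) noise.
#' Species B shares species A's module structure except for a planted
#' fraction of orthologs reassigned to a different module — a neighbourhood
#' swap, which is exactly the kind of divergence LNS detects. Missing values
#' and replicate arrays are injected to exercise the preprocessing chain.
#'
#' The defaults emulate a multi-dataset microarray compendium at desk scale:
#' 300 genes in 10 modules, 6 datasets of 12 arrays per species, signal sd 1
#' against noise sd 0.7 (within-module correlation about 0.67), 5% missing
#' cells, 10% diverged orthologs.
#'
#' @param n_genes number of ortholog pairs, default 300.
#' @param n_modules number of co-expression modules, default 10.
#' @param n_datasets datasets per species, default 6.
#' @param arrays_per_dataset arrays per dataset (before replication),
#'   default 12.
#' @param module_signal_sd sd of the latent module factors, default 1.
#' @param noise_sd sd of gene-level noise, default 0.7.
#' @param divergent_fraction fraction of orthologs with swapped module
#'   membership in species B, default 0.1.
#' @param missing_rate fraction of cells set missing, default 0.05.
#' @param replicate_count noisy replicate arrays per base array, default 1
#'   (no replication).
#' @param seed integer seed, default 17.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 300L, n_modules = 10L, n_datasets = 6L,
                           arrays_per_dataset = 12L, module_signal_sd = 1,
                           noise_sd = 0.7, divergent_fraction = 0.1,
                           missing_rate = 0.05, replicate_count = 1L,
                           seed = 17L) {
  stopifnot(n_genes >= 1L, n_modules >= 1L, n_datasets >= 1L,
            arrays_per_dataset >= 1L, module_signal_sd > 0, noise_sd > 0,
            divergent_fraction >= 0, divergent_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, replicate_count >= 1L)
  if (n_modules > n_genes) stop("n_modules exceeds n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 n_datasets = as.integer(n_datasets),
                 arrays_per_dataset = as.integer(arrays_per_dataset),
                 module_signal_sd = module_signal_sd, noise_sd = noise_sd,
                 divergent_fraction = divergent_fraction,
                 missing_rate = missing_rate,
                 replicate_count = as.integer(replicate_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# One species' dataset: module factors + gene noise (+ replicates, missing).
simulate_species_dataset <- function(spec, modules, gene_ids, dataset_id) {
  n_arr <- spec$arrays_per_dataset
  factors <- matrix(stats::rnorm(spec$n_modules * n_arr,
                                 sd = spec$module_signal_sd),
                    spec$n_modules, n_arr)
  rep_groups <- NULL
  if (spec$replicate_count > 1L) {
    base_ids <- sprintf("%s_a%02d", dataset_id, seq_len(n_arr))
    array_ids <- as.vector(vapply(base_ids, function(b)
      paste0(b, "_r", seq_len(spec$replicate_count)),
      character(spec$replicate_count)))
    col_factor <- rep(seq_len(n_arr), each = spec$replicate_count)
    rep_groups <- split(array_ids, base_ids[col_factor])
  } else {
    array_ids <- sprintf("%s_a%02d", dataset_id, seq_len(n_arr))
    col_factor <- seq_len(n_arr)
  }
  n_col <- length(array_ids)
  v <- factors[modules, col_factor, drop = FALSE] +
    matrix(stats::rnorm(spec$n_genes * n_col, sd = spec$noise_sd),
           spec$n_genes, n_col)
  dimnames(v) <- list(gene_ids, array_ids)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(v)) < spec$missing_rate,
                   nrow(v), ncol(v))
    v[mask] <- NA_real_
  }
  expression_dataset(v, dataset_id = dataset_id,
                     replicate_groups = rep_groups)
}

#' Generate a synthetic two-species expression compendium
#'
#' Draws a pair of multi-dataset compendia with identical block co-expression
#' structure except for a planted set of diverged orthologs whose module
#' membership is reassigned in species B (see [synthetic_spec()]). Datasets
#' of the two species are statistically independent given the module
#' structure, as different experiments in different species would be.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `datasets_a`, `datasets_b` (lists of
#'   [expression_dataset()]), `orthologs` (an [ortholog_map()]), and `truth`
#'   — a list with `modules_a`, `modules_b` (named integer vectors) and
#'   `divergent` (species-A ids of the planted diverged orthologs; length
#'   `round(divergent_fraction * n_genes)`).
#' @export
generate_compendium <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  width <- max(4L, nchar(as.character(spec$n_genes)))
  ga <- sprintf("ga%0*d", width, seq_len(spec$n_genes))
  gb <- sprintf("gb%0*d", width, seq_len(spec$n_genes))
  modules_a <- rep_len(seq_len(spec$n_modules), spec$n_genes)
  n_div <- round(spec$divergent_fraction * spec$n_genes)
  divergent_idx <- if (n_div) sort(sample.int(spec$n_genes, n_div)) else integer()
  modules_b <- modules_a
  if (spec$n_modules > 1L) {
    for (i in divergent_idx)
      modules_b[i] <- sample(setdiff(seq_len(spec$n_modules), modules_a[i]), 1L)
  }
  datasets_a <- lapply(seq_len(spec$n_datasets), function(d)
    simulate_species_dataset(spec, modules_a, ga, sprintf("A%02d", d)))
  datasets_b <- lapply(seq_len(spec$n_datasets), function(d)
    simulate_species_dataset(spec, modules_b, gb, sprintf("B%02d", d)))
  list(datasets_a = datasets_a, datasets_b = datasets_b,
       orthologs = ortholog_map(ga, gb),
       truth = list(modules_a = stats::setNames(modules_a, ga),
                    modules_b = stats::setNames(modules_b, gb),
                    divergent = ga[divergent_idx]))
}

#' Generate a synthetic synchrony time course
#'
#' Periodic genes follow a cosine with the given number of cycles over the
#' course and uniform random peak phases; the remaining genes are pure
#' Gaussian noise. Planted phases follow the peak-time convention of
#' [fourier_score()].
#'
#' @param n_genes total genes, default 100.
#' @param n_periodic number of periodic genes, default 20.
#' @param n_timepoints evenly spaced time points; must exceed `2 * cycles + 1`
#'   to avoid aliasing. Default 16.
#' @param cycles complete expression cycles over the course, default 2.
#' @param noise_sd sd of additive noise, default 0.2.
#' @param amplitude cosine amplitude, default 1.
#' @param seed integer seed, default 17.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (data.frame `gene_id`, `periodic`, `phase`).
#' @export
generate_timecourse <- function(n_genes = 100L, n_periodic = 20L,
                                n_timepoints = 16L, cycles = 2L,
                                noise_sd = 0.2, amplitude = 1, seed = 17L) {
  stopifnot(n_periodic <= n_genes, cycles >= 1L, noise_sd >= 0)
  if (n_timepoints < 2L * cycles + 2L)
    stop("n_timepoints must be at least 2 * cycles + 2 (aliasing)")
  set.seed(seed)
  width <- max(3L, nchar(as.character(n_genes)))
  gid <- sprintf("tg%0*d", width, seq_len(n_genes))
  tt <- seq_len(n_timepoints) - 1L
  phases <- stats::runif(n_periodic, 0, 2 * pi)
  v <- matrix(stats::rnorm(n_genes * n_timepoints, sd = noise_sd),
              n_genes, n_timepoints)
  for (i in seq_len(n_periodic))
    v[i, ] <- v[i, ] +
      amplitude * cos(2 * pi * cycles * tt / n_timepoints - phases[i])
  dimnames(v) <- list(gid, sprintf("t%02d", tt))
  truth <- data.frame(gene_id = gid,
                      periodic = seq_len(n_genes) <= n_periodic,
                      phase = c(phases, rep(NA_real_, n_genes - n_periodic)),
                      stringsAsFactors = FALSE)
  list(dataset = expression_dataset(v, dataset_id = "timecourse"),
       truth = truth)
}

#' Write a synthetic compendium to disk
#'
#' Emits every dataset of both species in the TSV dialect accepted by
#' [read_expression_matrix()], the ortholog map, replicate sidecars (when
#' replication is on), the planted truth, and the generating parameters as a
#' flat key-value config file.
#'
#' @param comp result of [generate_compendium()].
#' @param dir output directory, created if needed.
#' @param spec the [synthetic_spec()] used (recorded in `spec.cfg`).
#' @return `dir`, invisibly.
#' @export
write_compendium <- function(comp, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in c(comp$datasets_a, comp$datasets_b)) {
    write_expression_matrix(ds, file.path(dir, paste0(ds$dataset_id, ".tsv")))
    if (!is.null(ds$replicate_groups)) {
      rg <- ds$replicate_groups
      df <- data.frame(array_id = unlist(rg, use.names = FALSE),
                       group_id = rep(names(rg), lengths(rg)))
      utils::write.table(df, file.path(dir, paste0(ds$dataset_id,
                                                   "_replicates.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  utils::write.table(data.frame(comp$orthologs),
                     file.path(dir, "orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- data.frame(gene_a = names(comp$truth$modules_a),
                      module_a = comp$truth$modules_a,
                      module_b = comp$truth$modules_b,
                      divergent = names(comp$truth$modules_a) %in%
                        comp$truth$divergent)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    writeLines(paste(names(unclass(spec)), unlist(spec), sep = "="),
               file.path(dir, "spec.cfg"))
  }
  invisible(dir)
}
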