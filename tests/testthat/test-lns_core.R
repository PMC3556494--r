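test_that("lns_pair matches the hand Pearson formula and handles degenerate vectors", {
  wa <- c(0.1, -0.2, 0.3, 0.0)
  wb <- c(0.2, -0.1, 0.2, 0.1)
  # hand Pearson: cov / (sd * sd) computed explicitly
  hand <- sum((wa - mean(wa)) * (wb - mean(wb))) /
    sqrt(sum((wa - mean(wa))^2) * sum((wb - mean(wb))^2))
  expect_equal(lns_pair(wa, wb), hand, tolerance = 1e-12)
  expect_equal(lns_pair(wa, wa), 1)
  expect_equal(lns_pair(wa, -wa), -1)
  expect_true(is.na(lns_pair(c(1, 1, 1, 1), wb)))
})

test_that("matrix-based global LNS equals the brute-force per-pair oracle to 1e-10", {
  set.seed(40)
  fix <- planted_fixture()
  om20 <- ortholog_map(fix$comp$orthologs$gene_a[1:20],
                       fix$comp$orthologs$gene_b[1:20])
  res <- lns(fix$conn_a, fix$conn_b, om20)
  expect_equal(res$table$lns, lns_oracle(fix$conn_a, fix$conn_b, om20),
               tolerance = 1e-10)
})

test_that("self-comparison under the identity map yields LNS 1; permuted matching centers the distribution at 0", {
  fix <- planted_fixture()
  ga <- fix$comp$orthologs$gene_a
  self <- lns(fix$conn_a, fix$conn_a, ortholog_map(ga, ga))
  v <- self$table$lns
  expect_true(all(!is.na(v)))
  expect_equal(v, rep(1, length(v)), tolerance = 1e-12)
  # permute species-B rows relative to orthology: distribution centered at 0
  set.seed(41)
  perm <- sample(length(ga))
  shuffled <- ortholog_map(ga, fix$comp$orthologs$gene_b[perm])
  vp <- lns(fix$conn_a, fix$conn_b, shuffled)$table$lns
  expect_lt(abs(mean(vp, na.rm = TRUE)), 0.05)
})

test_that("LNS is symmetric in the species arguments and bounded in [-1, 1]", {
  fix <- planted_fixture()
  om <- fix$comp$orthologs
  ab <- lns(fix$conn_a, fix$conn_b, om)$table$lns
  ba <- lns(fix$conn_b, fix$conn_a, ortholog_map(om$gene_b, om$gene_a))$table$lns
  expect_equal(ab, ba, tolerance = 1e-12)
  expect_true(all(abs(ab) <= 1, na.rm = TRUE))
})

test_that("pairs absent from a matrix are reported with missing LNS and a reason", {
  fix <- planted_fixture()
  om <- fix$comp$orthologs
  extra <- ortholog_map(c(om$gene_a[1:10], "ghostA"),
                        c(om$gene_b[1:10], "ghostB"))
  res <- lns(fix$conn_a, fix$conn_b, extra)
  tab <- res$table
  expect_equal(nrow(tab), 11L)
  ghost <- tab[tab$gene_a == "ghostA", ]
  expect_true(is.na(ghost$lns))
  expect_match(ghost$flag, "absent")
  expect_true(all(tab$flag[tab$gene_a != "ghostA"] == "ok"))
})

test_that("condition-specific LNS is invariant to a common array permutation and detects planted swaps", {
  spec <- synthetic_spec(n_genes = 120, n_datasets = 1, arrays_per_dataset = 14,
                         divergent_fraction = 0.25, missing_rate = 0, seed = 5)
  comp <- generate_compendium(spec)
  ds_a <- comp$datasets_a[[1]]
  ds_b <- comp$datasets_b[[1]]
  res <- condition_lns(ds_a, ds_b, comp$orthologs)
  expect_gt(median(res$table$lns, na.rm = TRUE), 0)
  # reordering species-B arrays in time leaves every LNS unchanged
  set.seed(6)
  vb <- ds_b$values[, sample(ncol(ds_b$values))]
  res2 <- condition_lns(ds_a, expression_dataset(vb, "B01p"), comp$orthologs,
                        context = res$context)
  expect_equal(res2$table$lns, res$table$lns, tolerance = 1e-10)
  # planted module swaps score below the conserved pairs
  div <- res$table$gene_a %in% comp$truth$divergent
  expect_lt(mean(res$table$lns[div], na.rm = TRUE),
            mean(res$table$lns[!div], na.rm = TRUE))
})

test_that("randomized null is seed-deterministic, centered at 0, near normal, and matches a single-shuffle oracle", {
  fix <- planted_fixture()
  om <- fix$comp$orthologs
  n1 <- lns_null(fix$conn_a, fix$conn_b, om, n_permutations = 5, seed = 23)
  n2 <- lns_null(fix$conn_a, fix$conn_b, om, n_permutations = 5, seed = 23)
  expect_identical(n1$samples, n2$samples)
  expect_true(all(abs(n1$samples) <= 1))
  # single permutation on 10 genes equals direct recomputation of the shuffle
  om10 <- ortholog_map(om$gene_a[1:10], om$gene_b[1:10])
  none <- lns_null(fix$conn_a, fix$conn_b, om10, n_permutations = 1, seed = 7)
  set.seed(7)
  perm <- sample.int(10)
  oracle <- lns_oracle(fix$conn_a, fix$conn_b,
                       ortholog_map(om$gene_a[1:10], om$gene_b[1:10][perm]))
  expect_equal(none$samples, oracle[!is.na(oracle)], tolerance = 1e-10)
})

test_that("count_diverged counts below the null mean and is calibrated on null self-comparison", {
  fix <- planted_fixture()
  om <- fix$comp$orthologs
  null <- lns_null(fix$conn_a, fix$conn_b, om, n_permutations = 20, seed = 3)
  real <- lns(fix$conn_a, fix$conn_b, om)
  d <- count_diverged(real, null)
  expect_equal(d$cutoff, mean(null$samples))
  expect_equal(d$count, sum(real$table$lns < d$cutoff, na.rm = TRUE))
  expect_lt(d$p, 1e-10)        # planted conservation shifts the distribution
  # a "table" drawn from the null itself: about half below the mean, p large
  fake <- real
  set.seed(4)
  fake$table$lns <- sample(null$samples, nrow(real$table))
  dn <- count_diverged(fake, null)
  expect_gt(dn$p, 0.01)
  expect_gt(dn$count / dn$n_scored, 0.3)
  expect_lt(dn$count / dn$n_scored, 0.7)
  # all-conserved table: nothing below the cutoff
  fake$table$lns <- rep(1, nrow(fake$table))
  expect_equal(count_diverged(fake, null)$count, 0L)
})

test_that("within-species LNS is 1 for duplicated compendia, ~0 for independent noise, and exceeds between-species LNS on planted data", {
  ds <- lapply(1:4, function(i) random_ds(40, 10, seed = 100 + 0, id = paste0("d", i)))
  dup <- within_species_lns(ds, split_seed = 1)     # identical halves
  expect_equal(dup$table$lns, rep(1, nrow(dup$table)), tolerance = 1e-10)
  indep <- lapply(1:4, function(i) random_ds(40, 10, seed = 200 + i,
                                             id = paste0("e", i)))
  noise <- within_species_lns(indep, split_seed = 2)
  expect_lt(abs(median(noise$table$lns, na.rm = TRUE)), 0.15)
  # modular compendium at matched aggregation depth: within-species halves
  # (no divergence possible) beat the between-species divergence fixture
  spec <- synthetic_spec(n_datasets = 12, divergent_fraction = 0.25,
                         missing_rate = 0, seed = 9)
  comp <- generate_compendium(spec)
  within <- within_species_lns(comp$datasets_a, split_seed = 3)
  between <- lns(compendium_connection(comp$datasets_a[1:6]),
                 compendium_connection(comp$datasets_b[1:6]),
                 comp$orthologs)
  expect_gt(median(within$table$lns, na.rm = TRUE),
            median(between$table$lns, na.rm = TRUE))
  expect_error(within_species_lns(ds[1]), "at least 2")
})

test_that("LNS tables round-trip through TSV", {
  fix <- planted_fixture()
  om <- ortholog_map(fix$comp$orthologs$gene_a[1:15],
                     fix$comp$orthologs$gene_b[1:15])
  res <- lns(fix$conn_a, fix$conn_b, om)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lns_table(res, path)
  back <- read_lns_table(path)
  expect_equal(back$table$lns, res$table$lns, tolerance = 1e-10)
  expect_identical(back$context, "global")
})
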