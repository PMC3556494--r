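test_that("mean centering zeroes every row mean and is idempotent", {
  ds <- make_ds(rbind(c(1, 2, 3), c(5, 5, 5), c(-1, 0, 1)))
  out <- mean_center(ds)
  expect_equal(unname(out$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(out$values[2, ]), c(0, 0, 0))
  expect_identical(mean_center(out)$values, out$values)
})

test_that("dominant frequency is recovered from planted sinusoids and white noise is flagged", {
  tc <- generate_timecourse(n_genes = 100, n_periodic = 100,
                            n_timepoints = 16, cycles = 2, noise_sd = 0.3,
                            seed = 9)
  p <- identify_period(mean_center(tc$dataset))
  expect_equal(p$frequency, 2L)
  expect_false(p$low_confidence)
  # single shared sinusoid at 3 cycles
  t3 <- generate_timecourse(n_genes = 40, n_periodic = 40, n_timepoints = 20,
                            cycles = 3, noise_sd = 0.1, seed = 10)
  expect_equal(identify_period(mean_center(t3$dataset))$frequency, 3L)
  # pure noise: no dominant frequency
  noise <- generate_timecourse(n_genes = 80, n_periodic = 0,
                               n_timepoints = 16, cycles = 2, noise_sd = 1,
                               seed = 11)
  expect_true(identify_period(mean_center(noise$dataset))$low_confidence)
  short <- make_ds(matrix(rnorm(4 * 20), 20, 4))
  expect_error(identify_period(short), "at least 8")
})

test_that("fourier scores are 1 for pure cosines at the target frequency, 0 at others, with analytic phases", {
  tt <- 0:15
  v <- rbind(cos(2 * pi * 2 * tt / 16),
             cos(2 * pi * 3 * tt / 16),
             cos(2 * pi * 2 * tt / 16 - pi / 2),
             rep(0, 16))
  ds <- make_ds(v)
  fs <- fourier_score(ds, 2L)
  expect_equal(fs$score[1], 1, tolerance = 1e-12)
  expect_equal(fs$score[2], 0, tolerance = 1e-12)   # orthogonal frequency
  expect_equal(fs$score[4], 0)                      # all-zero gene
  expect_equal(fs$phase[4], 0)
  # quarter-period shift appears as a pi/2 phase offset
  expect_equal((fs$phase[3] - fs$phase[1]) %% (2 * pi), pi / 2,
               tolerance = 1e-10)
  # scores ignore additive constants (mean centering absorbs them)
  fs_shift <- fourier_score(make_ds(v + 7), 2L)
  expect_equal(fs_shift$score, fs$score, tolerance = 1e-12)
})

test_that("planted phases are recovered within one time-step's angular resolution", {
  tc <- generate_timecourse(n_genes = 60, n_periodic = 30, n_timepoints = 16,
                            cycles = 2, noise_sd = 0, seed = 12)
  fs <- fourier_score(tc$dataset, 2L)
  truth <- tc$truth$phase[tc$truth$periodic]
  est <- fs$phase[match(tc$truth$gene_id[tc$truth$periodic], fs$gene_id)]
  err <- abs((est - truth + pi) %% (2 * pi) - pi)
  expect_true(all(err <= 2 * pi / 16))
})

test_that("top-N selection flags planted sinusoids first with lexical tie-breaking", {
  tc <- generate_timecourse(n_genes = 100, n_periodic = 10, n_timepoints = 16,
                            cycles = 2, noise_sd = 0.2, seed = 13)
  fs <- fourier_score(mean_center(tc$dataset), 2L)
  sel <- select_periodic(fs, 10L)
  expect_identical(sort(sel$gene_id[sel$periodic]),
                   sort(tc$truth$gene_id[tc$truth$periodic]))
  expect_equal(sum(select_periodic(fs, 0L)$periodic), 0L)
  all_sel <- select_periodic(fs, nrow(fs))
  expect_true(all(all_sel$periodic))
  # deterministic lexical tie-break on equal scores
  tied <- data.frame(gene_id = c("b", "a", "c"), score = c(0.5, 0.5, 0.1))
  expect_identical(tied$gene_id[select_periodic(tied, 1L)$periodic], "a")
})

test_that("overlap test reports the exact hypergeometric tail and agrees with permutation", {
  om <- ortholog_map(sprintf("a%04d", 1:4701), sprintf("b%04d", 1:4701))
  set_a <- sprintf("a%04d", 1:591)
  # choose species-B calls so the pair overlap is exactly 111
  set_b <- sprintf("b%04d", c(1:111, 700:1214))      # 111 + 515 = 626
  res <- overlap_test(set_a, set_b, om, n_perm = 200, seed = 1)
  expect_equal(res$overlap, 111L)
  expect_equal(res$n_a, 591L)
  expect_equal(res$n_b, 626L)
  expect_equal(res$p_hyper,
               phyper(110, 591, 4701 - 591, 626, lower.tail = FALSE),
               tolerance = 1e-12)
  # disjoint and degenerate cases
  d <- overlap_test(sprintf("a%04d", 1:5), sprintf("b%04d", 6:10), om,
                    n_perm = 50, seed = 2)
  expect_equal(d$overlap, 0L)
  expect_warning(
    full <- overlap_test(om$gene_a, om$gene_b, om, n_perm = 10, seed = 3),
    "degenerate")
  expect_equal(full$overlap, 4701L)
})

test_that("hypergeometric and permutation p-values agree within Monte-Carlo error on small fixtures", {
  om <- ortholog_map(sprintf("a%02d", 1:60), sprintf("b%02d", 1:60))
  set_a <- sprintf("a%02d", 1:20)
  set_b <- sprintf("b%02d", 10:34)
  res <- overlap_test(set_a, set_b, om, n_perm = 4000, seed = 5)
  se <- sqrt(res$p_hyper * (1 - res$p_hyper) / 4000)
  expect_lt(abs(res$p_perm - res$p_hyper), 4 * se + 1e-3)
})

test_that("suggest_n_top calls most planted sinusoids and few noise genes at moderate noise", {
  tc <- generate_timecourse(n_genes = 120, n_periodic = 25, n_timepoints = 16,
                            cycles = 2, noise_sd = 0.25, seed = 14)
  n <- suggest_n_top(mean_center(tc$dataset), 2L, seed = 15)
  expect_gte(n, 20L)
  expect_lte(n, 40L)
})
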