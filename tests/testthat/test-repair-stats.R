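make_norm <- function(c0, c4, rna_count = NULL, keep = NULL) {
  nb <- length(c0)
  if (is.null(rna_count)) rna_count <- rep(0, nb)
  if (is.null(keep)) keep <- rep(TRUE, nb)
  rna <- expression_track(rna_count, ifelse(rna_count > 0, rna_count, 0))
  structure(
    list(scale_ratio = 1, n_reference_bins = sum(rna_count == 0),
         reference = rna_count == 0,
         table_0h = bin_counts(c0), table_4h = bin_counts(c4)),
    class = "dpc_normalization"
  )
}

test_that("repair percent is the signed normalized difference, invalid at c0 = 0", {
  norm <- make_norm(c(100, 80, 100, 0), c(50, 80, 120, 10))
  track <- repair_percent(norm, bin_mask(rep(TRUE, 4)))
  expect_equal(track$repair_percent[1:3], c(50, 0, -20))
  expect_true(is.na(track$repair_percent[4]))
  expect_false(track$valid[4])
})

test_that("repair summaries are quartiles over valid kept bins", {
  norm <- make_norm(rep(100, 5), c(100, 75, 50, 25, 0))
  track <- repair_percent(norm, bin_mask(rep(TRUE, 5)))
  s <- summarize_repair(track)
  expect_equal(c(s$q1, s$median, s$q3), c(25, 50, 75))
  expect_equal(s$n_bins, 5L)

  one <- repair_percent(make_norm(100, 58), bin_mask(TRUE))
  s1 <- summarize_repair(one)
  expect_equal(c(s1$q1, s1$median, s1$q3), rep(42, 3))

  flat <- repair_percent(make_norm(rep(100, 8), rep(50, 8)), bin_mask(rep(TRUE, 8)))
  sf <- summarize_repair(flat)
  expect_equal(c(sf$q1, sf$median, sf$q3), rep(50, 3))

  none <- repair_percent(make_norm(c(0, 0, 0, 0), rep(1, 4)), bin_mask(rep(TRUE, 4)))
  expect_error(summarize_repair(none), "no valid kept bins")

  # quartiles agree with the independent type-7 oracle on random tracks
  set.seed(5)
  for (i in 1:30) {
    vals <- runif(sample(2:80, 1), -40, 95)
    tr <- repair_percent(make_norm(rep(100, length(vals)), 100 - vals),
                         bin_mask(rep(TRUE, length(vals))))
    s <- summarize_repair(tr)
    expect_equal(unlist(s[c("q1", "median", "q3")], use.names = FALSE),
                 oracle_quantile7(vals, c(0.25, 0.5, 0.75)), tolerance = 1e-9)
  }
})

test_that("expression stratification uses half-open TPM intervals and reports empty strata", {
  norm <- make_norm(rep(100, 6), c(90, 80, 70, 60, 50, 40))
  track <- repair_percent(norm, bin_mask(rep(TRUE, 6)))
  rna <- expression_track(c(1, 1, 1, 1, 1, 1), c(0.5, 1, 2, 4, 9, 20))

  # all bins in the first stratum; the second empty
  low <- expression_track(rep(1, 6), rep(1, 6))
  st <- stratify_by_expression(track, low, c(0, 3, Inf))
  expect_equal(st$n_bins, c(6L, 0L))
  expect_true(is.na(st$median[2]))

  # one bin per stratum reproduces the bin values
  st1 <- stratify_by_expression(track, rna, c(0.4, 0.9, 1.5, 3, 8, 15, Inf))
  expect_equal(st1$median, c(10, 20, 30, 40, 50, 60))
  expect_equal(st1$n_bins, rep(1L, 6))

  expect_error(stratify_by_expression(track, rna, c(3, 1)), "strictly increasing")
})

test_that("stratum medians are non-decreasing under a monotone repair curve", {
  # half-saturation chosen on this small genome's TPM scale so the repair
  # fraction genuinely varies across strata
  cfg <- small_config(seed = 21, gene_number = 140,
                      repair_curve = list(max_repair = 0.8, half_saturation = 1000))
  exp1 <- simulate_dpc_experiment(cfg, "WT")
  res <- run_repair_pipeline(exp1$t0, exp1$t4, exp1$expression, exp1$bins)
  tpm <- exp1$expression$tpm
  edges <- c(3, unname(quantile(tpm[tpm > 3], c(0.25, 0.5, 0.75))), Inf)
  st <- stratify_by_expression(res$track, exp1$expression, edges)
  med <- st$median[st$n_bins > 20]
  expect_gte(length(med), 4)
  expect_true(all(diff(med) > -1))  # small sampling inversions tolerated
})

test_that("gene repair profiles follow 5'->3' order and the difference rule", {
  bins <- make_bins(data.frame(chrom = "chrA", length = 5000), 1000)
  norm <- make_norm(c(10, 10, 10, 10, 10), c(9, 2, 5, 8, 9))
  plus <- list(chrom = "chrA", start = 1100, end = 3900, strand = "+", gene_id = "g1")
  prof <- gene_repair_profile(norm, plus, bins)
  expect_equal(prof$diff, c(8, 5, 2))
  expect_equal(prof$position, 1:3)

  minus <- modifyList(plus, list(strand = "-"))
  expect_equal(gene_repair_profile(norm, minus, bins)$diff, c(2, 5, 8))

  zero <- make_norm(rep(10, 5), rep(10, 5))
  expect_true(all(gene_repair_profile(zero, plus, bins)$diff == 0))

  expect_error(gene_repair_profile(norm, modifyList(plus, list(chrom = "chrQ")), bins),
               "absent")
  expect_error(gene_repair_profile(norm, modifyList(plus, list(start = 9000, end = 9500)),
                                   bins), "no bins")
})

test_that("two-group comparison matches the pooled-variance closed form", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- compare_groups(a, b)
  # independent closed-form evaluation
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_exp <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_exp <- 2 * pt(-abs(t_exp), length(a) + length(b) - 2)
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$p, p_exp, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # symmetry under swapping
  swapped <- compare_groups(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
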