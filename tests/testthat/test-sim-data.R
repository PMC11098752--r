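test_that("simulated genomes are deterministic with non-overlapping genes", {
  cfg <- small_config(seed = 101)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  # pairwise brute-force overlap check within each chromosome
  genes <- g1$genes
  for (chr in unique(genes$chrom)) {
    gc <- genes[genes$chrom == chr, ]
    if (nrow(gc) < 2) next
    for (i in seq_len(nrow(gc) - 1)) {
      overlaps <- gc$start[-seq_len(i)] < gc$end[i] & gc$end[-seq_len(i)] > gc$start[i]
      expect_false(any(overlaps))
    }
  }

  # fully silent expression model
  silent_cfg <- small_config(seed = 5,
                             expression = list(fraction_silent = 1, log_mean = 0, log_sd = 1))
  expect_true(all(simulate_genome(silent_cfg)$genes$tpm == 0))

  # infeasible packing is an explicit error
  expect_error(
    simulation_config(n_chromosomes = 1, chromosome_length = 1e5,
                      gene_number = 50, gene_length_range = c(4000, 4000)) |>
      simulate_genome(),
    "infeasible"
  )
})

test_that("expression tracks put gene TPM on overlapped bins and zeros elsewhere", {
  cfg <- small_config(seed = 31)
  chrom <- data.frame(chrom = "chr1", length = 10000)
  bins <- make_bins(chrom, 1000)

  none <- simulate_expression_track(
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), tpm = numeric()),
    bins, cfg)
  expect_true(all(none$count == 0) && all(none$tpm == 0))

  one <- data.frame(gene_id = "g", chrom = "chr1", start = 2100, end = 4900,
                    strand = "+", tpm = 40)
  tr <- simulate_expression_track(one, bins, cfg)
  expect_equal(which(tr$true_tpm > 0), 3:5)  # gene spans exactly 3 bins
  expect_true(all(tr$count[tr$true_tpm == 0] == 0))
  expect_true(all(tr$tpm[tr$count == 0] == 0))
})

test_that("expressed-bin RNA counts have the stated Poisson mean", {
  cfg <- small_config(seed = 77, rna_depth = 1e7)
  chrom <- data.frame(chrom = "chr1", length = 1.2e7)
  bins <- make_bins(chrom, 1000)
  tpm <- 30
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 1.0e7,
                     strand = "+", tpm = tpm)
  tr <- simulate_expression_track(gene, bins, cfg)
  lambda <- tpm * cfg$rna_depth / 1e6
  n_exp <- sum(tr$true_tpm > 0)
  expect_gte(n_exp, 10000)
  se <- sqrt(lambda / n_exp)
  expect_lt(abs(mean(tr$count[tr$true_tpm > 0]) - lambda), 3 * se)
})

test_that("DPC count simulation encodes uniform load, repair and exact ground truth", {
  cfg <- small_config(seed = 13)
  ex <- simulate_dpc_experiment(cfg, "WT")

  # ground truth consistency: repair fraction = curve(TPM) x genotype factor, exactly
  expect_identical(ex$truth$true_repair,
                   repair_fraction(ex$expression$true_tpm, cfg$repair_curve) *
                     cfg$genotype_factor[["WT"]])
  expect_true(all(ex$truth$true_repair[ex$expression$true_tpm == 0] == 0))
  expect_true(all(ex$truth$true_repair >= 0 & ex$truth$true_repair <= 1))

  # determinism across the whole generator
  ex2 <- simulate_dpc_experiment(cfg, "WT")
  expect_identical(ex$t0[[1]]$counts, ex2$t0[[1]]$counts)
  expect_identical(ex$t4[[2]]$counts, ex2$t4[[2]]$counts)

  # genotype factor 0: 0 h and 4 h share their expectation; empirical means
  # of silent and expressed bins at 4 h agree within Monte-Carlo error
  null_ex <- simulate_dpc_experiment(cfg, "THZ1")
  expect_true(all(null_ex$truth$true_repair == 0))
  t4 <- null_ex$t4[[1]]$counts
  s4 <- null_ex$truth$library_factors$factor[3]
  mu <- cfg$initial_dpc_density * s4
  expressed <- null_ex$expression$true_tpm > 0
  expect_lt(abs(mean(t4[expressed]) - mu), 4 * sqrt(mu / sum(expressed)))
  expect_lt(abs(mean(t4[!expressed]) - mu), 4 * sqrt(mu / sum(!expressed)))

  expect_error(simulate_dpc_counts(cfg, ex$expression, "nonsense"), "unknown condition")
})

test_that("negative-binomial noise is overdispersed relative to Poisson", {
  cfg_nb <- small_config(seed = 55, noise_model = "negative_binomial",
                         nb_dispersion = 0.2)
  ex <- simulate_dpc_experiment(cfg_nb, "WT")
  t0 <- ex$t0[[1]]$counts
  s0 <- ex$truth$library_factors$factor[1]
  mu <- cfg_nb$initial_dpc_density * s0
  # variance should approach mu + dispersion * mu^2, far above Poisson's mu
  expect_gt(var(t0), 2 * mu)
})

test_that("FRAP trace simulation matches its closed form and endpoints", {
  # zero noise: recovery at frame k equals the stated exponential exactly
  f <- 0.35; k <- 0.3; b <- 0.25
  traces <- simulate_frap_traces(f, k, n_cells = 1, n_frames = 20,
                                 bleach_depth = b, noise_sd = 0, seed = 3)
  rfi <- normalize_trace(traces[[1]])$rfi
  j <- 0:19
  expected <- b + ((1 - f * (1 - b)) - b) * (1 - exp(-k * j))
  expect_equal(rfi[6:25], expected, tolerance = 1e-9)
  expect_equal(rfi[1:5], rep(1, 5), tolerance = 1e-9)

  # immobile fraction 0: asymptote returns to the pre-bleach level
  free <- simulate_frap_traces(0, 1, 1, 60, bleach_depth = b, noise_sd = 0, seed = 4)
  rfi0 <- normalize_trace(free[[1]])$rfi
  expect_equal(rfi0[length(rfi0)], 1, tolerance = 1e-9)

  # immobile fraction 1: no recovery above the bleach level
  stuck <- simulate_frap_traces(1, 1, 1, 60, bleach_depth = b, noise_sd = 0, seed = 4)
  rfi1 <- normalize_trace(stuck[[1]])$rfi
  expect_equal(max(rfi1[6:65]), b, tolerance = 1e-9)
})

test_that("repair curve saturates, is monotone and vanishes at zero TPM", {
  curve <- list(max_repair = 0.8, half_saturation = 50)
  tpm <- c(0, 1, 10, 50, 500, 1e6)
  r <- repair_fraction(tpm, curve)
  expect_equal(r[1], 0)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= curve$max_repair))
  expect_equal(repair_fraction(50, curve), 0.4)  # half-saturation point

  step <- list(max_repair = 0.5, half_saturation = 0)
  expect_equal(repair_fraction(c(0, 0.001, 100), step), c(0, 0.5, 0.5))
})
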