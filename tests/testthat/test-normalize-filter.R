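test_that("IQR outlier mask flags the right bins and reports quartiles", {
  res <- iqr_outlier_mask(bin_counts(c(1, 2, 3, 4, 100)))
  expect_equal(res$mask$keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$report$q1, 2)
  expect_equal(res$report$q3, 4)
  expect_equal(res$report$n_removed_high, 1L)
  expect_equal(res$report$n_removed_low, 0L)  # lower bound 2 - 3 < 0
  expect_match(res$mask$provenance[5], "iqr_high")

  # all equal: IQR = 0, bounds collapse to the value, nothing flagged
  allsame <- iqr_outlier_mask(bin_counts(rep(5, 10)))
  expect_true(all(allsame$mask$keep))

  expect_error(iqr_outlier_mask(bin_counts(c(1, 2, 3))), "at least 4")
})

test_that("IQR mask agrees with the sort-based oracle on random vectors", {
  set.seed(42)
  for (i in 1:120) {
    n <- sample(4:200, 1)
    x <- switch(sample(3, 1),
      rpois(n, sample(c(2, 20, 200), 1)),
      rlnorm(n, 3, 1),
      rep(runif(1, 0, 10), n)  # degenerate all-equal case
    )
    got <- iqr_outlier_mask(bin_counts(x))$mask$keep
    expect_equal(got, oracle_iqr_keep(x))
  }
})

test_that("TPM floor is a strict less-than rule", {
  bins <- make_bins(data.frame(chrom = "c", length = 3000), 1000)
  tr <- expression_track(c(1, 2, 3), c(0.05, 0.08, 0.10))
  m <- tpm_floor_mask(tr, floor = 0.08)
  expect_equal(m$keep, c(FALSE, TRUE, TRUE))
  expect_match(m$provenance[1], "tpm_floor")
})

test_that("mask propagation takes the union of removals and is idempotent", {
  m1 <- bin_mask(c(TRUE, FALSE, TRUE, TRUE), c(NA, "iqr_high:dna_4h", NA, NA))
  m2 <- bin_mask(c(TRUE, TRUE, FALSE, TRUE), c(NA, NA, "tpm_floor:dna_0h", NA))
  comb <- propagate_mask(list(m1, m2))
  expect_equal(comb$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(!comb$keep), 2L)  # disjoint flag sets add up
  expect_equal(comb$provenance[2], "iqr_high:dna_4h")

  again <- propagate_mask(list(comb, comb))
  expect_equal(again$keep, comb$keep)

  ident <- propagate_mask(list(bin_mask(rep(TRUE, 4)), bin_mask(rep(TRUE, 4))))
  expect_true(all(ident$keep))

  expect_error(propagate_mask(list(m1, bin_mask(TRUE))), "different bin sets")
})

test_that("zero-transcription normalization scales 0 h onto the 4 h level", {
  # 5-bin worked case, bins 4 and 5 are the zero-RNA reference
  t0 <- bin_counts(c(100, 80, 60, 120, 80))   # ref sum 200
  t4 <- bin_counts(c(50, 40, 30, 55, 45))     # ref sum 100
  rna <- expression_track(c(10, 5, 3, 0, 0), c(40, 20, 12, 0, 0))
  mask <- bin_mask(rep(TRUE, 5))
  norm <- normalize_to_nonexpressed(t0, t4, rna, mask)
  expect_equal(norm$scale_ratio, 0.5)
  expect_equal(norm$n_reference_bins, 2L)
  expect_equal(norm$table_0h$counts, c(50, 40, 30, 60, 40))
  expect_equal(sum(norm$table_0h$counts[norm$reference]),
               sum(t4$counts[norm$reference]), tolerance = 1e-12)

  # equal reference sums -> identity
  same <- normalize_to_nonexpressed(t4, t4, rna, mask)
  expect_equal(same$scale_ratio, 1)
  expect_equal(same$table_0h$counts, t4$counts)

  expect_error(
    normalize_to_nonexpressed(t0, t4, expression_track(rep(1, 5), rep(1, 5)), mask),
    "reference bins"
  )
})

test_that("normalization conserves reference sums and is scale-equivariant on random inputs", {
  set.seed(7)
  for (i in 1:60) {
    nb <- sample(10:200, 1)
    rna_count <- rpois(nb, 0.7)
    rna <- expression_track(rna_count, ifelse(rna_count > 0, rna_count * 10, 0))
    t0 <- bin_counts(rpois(nb, 60) + runif(nb))
    t4 <- bin_counts(rpois(nb, 40) + runif(nb))
    mask <- bin_mask(runif(nb) > 0.2)
    if (!any(mask$keep & rna$count == 0)) next
    norm <- normalize_to_nonexpressed(t0, t4, rna, mask)
    ref <- norm$reference
    expect_equal(sum(norm$table_0h$counts[ref]), sum(t4$counts[ref]),
                 tolerance = 1e-9)
    # common rescaling of both samples leaves the ratio unchanged
    k <- runif(1, 0.1, 10)
    norm_k <- normalize_to_nonexpressed(bin_counts(t0$counts * k),
                                        bin_counts(t4$counts * k), rna, mask)
    expect_equal(norm_k$scale_ratio, norm$scale_ratio, tolerance = 1e-12)
  }
})

test_that("expression threshold mask follows the quoted boundary semantics", {
  rna <- expression_track(c(0, 1, 2, 3, 4), c(0, 0.5, 3, 3.5, 8))
  # threshold 3: TPM == 3 removed ("less than or equal"), > 3 kept
  m3 <- expression_threshold_mask(rna, 3)
  expect_equal(m3$keep, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # no threshold: zero-TPM bins removed
  m0 <- expression_threshold_mask(rna, NULL)
  expect_equal(m0$keep, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  # threshold 0 keeps any positive TPM
  expect_true(expression_threshold_mask(rna, 0)$keep[2])
  expect_error(expression_threshold_mask(rna, -1), "non-negative")
})
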