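# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# type-7 quantile from first principles: sort, h = (n-1)p + 1, linear
# interpolation between adjacent order statistics
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- min(lo + 1, n)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# IQR outlier keep-flags, independently of the package's code path
oracle_iqr_keep <- function(x) {
  q <- oracle_quantile7(x, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  flag_low <- if (lo < 0) rep(FALSE, length(x)) else x < lo
  !(flag_low | x > hi)
}

# per-(fragment, bin) overlap enumeration with the 1/n fractional rule;
# fragments assumed already filter-passing
oracle_fractional_counts <- function(fragments, bins) {
  counts <- numeric(nrow(bins))
  for (i in seq_len(nrow(fragments))) {
    ov <- which(bins$chrom == fragments$chrom[i] &
                  bins$start < fragments$end[i] &
                  bins$end > fragments$start[i])
    if (length(ov) > 0) counts[ov] <- counts[ov] + 1 / length(ov)
  }
  counts
}

# random small counting instance: one chromosome, random bins/fragments
random_count_instance <- function(seed) {
  set.seed(seed)
  n_bins <- sample(3:100, 1)
  bin_size <- sample(c(50, 100, 250), 1)
  chrom_len <- n_bins * bin_size - sample(0:(bin_size - 1), 1)
  bins <- make_bins(data.frame(chrom = "chrT", length = chrom_len), bin_size)
  n_frag <- sample(1:1000, 1)
  start <- floor(runif(n_frag, 0, chrom_len - 1))
  len <- sample(1:(3 * bin_size), n_frag, replace = TRUE)
  fragments <- data.frame(
    chrom = "chrT", start = start, end = pmin(start + len, chrom_len),
    mapq = sample(c(0, 20, 30, 60), n_frag, replace = TRUE),
    is_primary = runif(n_frag) > 0.1,
    is_duplicate = runif(n_frag) < 0.1
  )
  list(bins = bins, fragments = fragments)
}

# small ready-made simulation config for pipeline-level tests
small_config <- function(seed = 11, gene_number = 100, ...) {
  simulation_config(
    seed = seed, n_chromosomes = 1, chromosome_length = 4e6,
    gene_number = gene_number, gene_length_range = c(6000, 15000), ...
  )
}
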