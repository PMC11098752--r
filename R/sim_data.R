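#' Configuration for the synthetic DPC-seq experiment generator
#'
#' The generator emulates the statistical structure of a formaldehyde-pulse
#' DPC-seq experiment in a human fibroblast-like genome: DPCs land
#' uniformly across genic and intergenic 1-kb bins at 0 h, and by 4 h a
#' fraction of them has been removed from transcribed bins in proportion to
#' nascent-RNA expression, modulated by genotype (WT repairs; CSA/CSB KO
#' and THZ1-treated cells do not).
#'
#' @param seed integer RNG seed; all `simulate_*` operations derive their
#'   streams from it.
#' @param n_chromosomes,chromosome_length genome shape (lengths in bases;
#'   a scalar length is recycled).
#' @param bin_size bin width in bases (default 1000).
#' @param gene_number,gene_length_range number of genes and the min/max
#'   gene length in bases.
#' @param expression zero-inflated log-normal expression model:
#'   `fraction_silent` genes with TPM 0, the rest log-normal
#'   (`log_mean`, `log_sd`); expressed-gene TPMs are rescaled so the
#'   per-bin true TPM track sums to 1e6.
#' @param initial_dpc_density expected DPC fragments per bin at 0 h
#'   (before library scaling).
#' @param repair_curve saturating map from TPM to repair fraction:
#'   `max_repair * tpm / (tpm + half_saturation)`, with
#'   `half_saturation = 0` meaning a step to `max_repair` on any expressed
#'   bin. Always 0 at TPM 0.
#' @param genotype_factor named multipliers in \[0,1\] on the repair
#'   fraction per condition label.
#' @param noise_model `"poisson"` (default) or `"negative_binomial"`.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); ignored under Poisson.
#' @param rna_depth expected total nascent-RNA fragments over the genome;
#'   per-bin RNA counts are Poisson with mean `tpm * rna_depth / 1e6`.
#' @param n_replicates DPC-seq replicates per timepoint.
#' @param library_size_range per-sample library scale factors are drawn
#'   log-uniformly from this interval, forcing the normalization stage to
#'   do real work.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 25e6,
                              bin_size = 1000L,
                              gene_number = 1200L,
                              gene_length_range = c(8000L, 20000L),
                              expression = list(fraction_silent = 0.2, log_mean = 0, log_sd = 1),
                              initial_dpc_density = 50,
                              repair_curve = list(max_repair = 0.5, half_saturation = 0),
                              genotype_factor = c(WT = 1, CSA_KO = 0, CSB_KO = 0, THZ1 = 0),
                              noise_model = c("poisson", "negative_binomial"),
                              nb_dispersion = 0.05,
                              rna_depth = 2e7,
                              n_replicates = 2L,
                              library_size_range = c(0.5, 2)) {
  noise_model <- match.arg(noise_model)
  chromosome_length <- rep_len(chromosome_length, n_chromosomes)
  stopifnot(
    n_chromosomes >= 1L, all(chromosome_length > 0), bin_size > 0,
    gene_number >= 0, length(gene_length_range) == 2L,
    gene_length_range[1] > 0, gene_length_range[1] <= gene_length_range[2],
    expression$fraction_silent >= 0, expression$fraction_silent <= 1,
    expression$log_sd >= 0,
    initial_dpc_density > 0,
    repair_curve$max_repair >= 0, repair_curve$max_repair <= 1,
    repair_curve$half_saturation >= 0,
    all(genotype_factor >= 0), all(genotype_factor <= 1),
    !is.null(names(genotype_factor)),
    nb_dispersion > 0, rna_depth > 0, n_replicates >= 1L,
    library_size_range[1] > 0, library_size_range[1] <= library_size_range[2]
  )
  structure(
    list(
      seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = chromosome_length, bin_size = as.integer(bin_size),
      gene_number = as.integer(gene_number), gene_length_range = gene_length_range,
      expression = expression, initial_dpc_density = initial_dpc_density,
      repair_curve = repair_curve, genotype_factor = genotype_factor,
      noise_model = noise_model, nb_dispersion = nb_dispersion,
      rna_depth = rna_depth, n_replicates = as.integer(n_replicates),
      library_size_range = library_size_range
    ),
    class = "sim_config"
  )
}

#' True repair fraction as a function of expression
#'
#' Saturating (Michaelis-Menten-shaped) in TPM with
#' `repair_fraction(0) == 0` always; `half_saturation = 0` degenerates to a
#' step of height `max_repair` on expressed bins.
#'
#' @param tpm numeric TPM values.
#' @param curve list with `max_repair` and `half_saturation`.
#' @return repair fractions in \[0,1\].
#' @export
repair_fraction <- function(tpm, curve) {
  r <- if (curve$half_saturation <= 0) {
    ifelse(tpm > 0, curve$max_repair, 0)
  } else {
    curve$max_repair * tpm / (tpm + curve$half_saturation)
  }
  r[tpm == 0] <- 0
  r
}

#' Simulate a genome: chromosome sizes and non-overlapping genes
#'
#' Genes are placed uniformly at random without overlap by rejection
#' sampling (strand assigned at random; strand is otherwise ignored, as
#' counting is unstranded). Each gene is silent (TPM 0) with probability
#' `fraction_silent`, otherwise its TPM is log-normal; expressed-gene TPMs
#' are rescaled so that the per-bin true TPM track sums to 1e6.
#'
#' @param config a [simulation_config()].
#' @return list with `chrom_sizes` (data.frame `chrom`, `length`) and
#'   `genes` (data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tpm`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_sizes <- data.frame(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    length = config$chromosome_length,
    stringsAsFactors = FALSE
  )
  total_len <- sum(chrom_sizes$length)
  if (config$gene_number * config$gene_length_range[2] > total_len) {
    stop("infeasible gene packing: gene_number x max gene length exceeds genome length")
  }
  placed <- vector("list", config$gene_number)
  starts_by_chr <- ends_by_chr <- stats::setNames(
    rep(list(numeric(0)), config$n_chromosomes), chrom_sizes$chrom
  )
  max_tries <- 200L * max(1L, config$gene_number)
  tries <- 0L
  i <- 1L
  while (i <= config$gene_number) {
    tries <- tries + 1L
    if (tries > max_tries) stop("infeasible gene packing: rejection sampling did not converge")
    len <- round(stats::runif(1, config$gene_length_range[1], config$gene_length_range[2]))
    chr_i <- sample.int(config$n_chromosomes, 1, prob = chrom_sizes$length)
    chr <- chrom_sizes$chrom[chr_i]
    if (chrom_sizes$length[chr_i] < len) next
    start <- floor(stats::runif(1, 0, chrom_sizes$length[chr_i] - len + 1))
    end <- start + len
    if (any(start < ends_by_chr[[chr]] & end > starts_by_chr[[chr]])) next
    starts_by_chr[[chr]] <- c(starts_by_chr[[chr]], start)
    ends_by_chr[[chr]] <- c(ends_by_chr[[chr]], end)
    placed[[i]] <- data.frame(chrom = chr, start = start, end = end,
                              stringsAsFactors = FALSE)
    i <- i + 1L
  }
  genes <- if (config$gene_number > 0) do.call(rbind, placed) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  if (nrow(genes) > 0) {
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    silent <- stats::runif(nrow(genes)) < config$expression$fraction_silent
    tpm <- ifelse(silent, 0,
                  stats::rlnorm(nrow(genes), config$expression$log_mean,
                                config$expression$log_sd))
    # rescale so per-bin true TPM sums to 1e6 (TPM semantics); weight each
    # gene by the number of bins it touches
    bs <- config$bin_size
    nb_gene <- floor((genes$end - 1) / bs) - floor(genes$start / bs) + 1
    wsum <- sum(tpm * nb_gene)
    if (wsum > 0) tpm <- tpm * 1e6 / wsum
    genes$tpm <- tpm
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tpm")]
    rownames(genes) <- NULL
  }
  list(chrom_sizes = chrom_sizes, genes = genes)
}

#' Simulate a nascent-RNA expression track over genome bins
#'
#' Bins overlapping an expressed gene carry that gene's TPM as ground
#' truth (where two genes touch one bin, the larger TPM); bins outside
#' genes carry TPM 0 and raw count 0 exactly. Raw RNA counts are Poisson
#' with mean `true_tpm * rna_depth / 1e6`; the measured `tpm` column is
#' recomputed from the sampled counts via [compute_tpm()].
#'
#' @param genes gene table from [simulate_genome()].
#' @param bins a `genome_bins` partition of the same genome.
#' @param config the [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return an [expression_track()] with columns `count`, `tpm` (measured)
#'   and `true_tpm` (ground truth).
#' @export
simulate_expression_track <- function(genes, bins, config, seed = config$seed + 1L) {
  stopifnot(inherits(bins, "genome_bins"), inherits(config, "sim_config"))
  set.seed(seed)
  true_tpm <- numeric(nrow(bins))
  if (nrow(genes) > 0) {
    for (g in seq_len(nrow(genes))) {
      hit <- bins$chrom == genes$chrom[g] & bins$start < genes$end[g] &
        bins$end > genes$start[g]
      true_tpm[hit] <- pmax(true_tpm[hit], genes$tpm[g])
    }
  }
  lambda <- true_tpm * config$rna_depth / 1e6
  count <- stats::rpois(length(lambda), lambda)
  if (sum(count) > 0) {
    measured <- compute_tpm(bin_counts(count, timepoint = "rna"), bins)$tpm
  } else {
    measured <- numeric(length(count))
  }
  expression_track(count, measured, true_tpm = true_tpm)
}

draw_counts <- function(mu, config) {
  if (config$noise_model == "poisson") {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
}

#' Simulate DPC-seq bin counts at 0 h and 4 h with ground truth
#'
#' At 0 h the expected DPC load is uniform across all bins
#' (`initial_dpc_density`), matching the equal distribution of crosslinks
#' over genic and intergenic regions after a formaldehyde pulse. At 4 h the
#' expectation is reduced to `1 - r(TPM) * genotype_factor` of the 0 h
#' level, where `r` is the configured repair curve. Each replicate of each
#' timepoint receives its own log-uniform library-size factor; counts are
#' drawn under the configured noise model.
#'
#' @param config the [simulation_config()].
#' @param expression the simulated [expression_track()] (must carry
#'   `true_tpm`).
#' @param condition a label present in `config$genotype_factor`.
#' @param seed RNG seed (defaults to a condition-specific offset of
#'   `config$seed`).
#' @return list with `t0` and `t4` (lists of `n_replicates`
#'   [bin_counts()] tables) and `truth` (list: per-bin `true_tpm`,
#'   `true_repair`, `genotype_factor`, `library_factors`).
#' @export
simulate_dpc_counts <- function(config, expression, condition,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(expression, "expression_track"))
  if (!condition %in% names(config$genotype_factor)) {
    stop("unknown condition label '", condition, "'")
  }
  if (!"true_tpm" %in% names(expression)) stop("expression track lacks ground-truth TPM")
  if (is.null(seed)) {
    seed <- config$seed + 1000L * match(condition, names(config$genotype_factor))
  }
  set.seed(seed)
  g <- config$genotype_factor[[condition]]
  r <- repair_fraction(expression$true_tpm, config$repair_curve) * g
  n_samples <- 2L * config$n_replicates
  lf <- exp(stats::runif(n_samples, log(config$library_size_range[1]),
                         log(config$library_size_range[2])))
  nb <- length(r)
  t0 <- t4 <- vector("list", config$n_replicates)
  for (k in seq_len(config$n_replicates)) {
    s0 <- lf[k]
    s4 <- lf[config$n_replicates + k]
    mu0 <- rep(config$initial_dpc_density * s0, nb)
    mu4 <- config$initial_dpc_density * (1 - r) * s4
    t0[[k]] <- bin_counts(draw_counts(mu0, config),
                          timepoint = "0h", condition = condition, replicate = k)
    t4[[k]] <- bin_counts(draw_counts(mu4, config),
                          timepoint = "4h", condition = condition, replicate = k)
  }
  list(
    t0 = t0, t4 = t4,
    truth = list(
      true_tpm = expression$true_tpm, true_repair = r,
      genotype_factor = g,
      library_factors = data.frame(
        timepoint = rep(c("0h", "4h"), each = config$n_replicates),
        replicate = rep(seq_len(config$n_replicates), 2),
        factor = c(lf[seq_len(config$n_replicates)],
                   lf[config$n_replicates + seq_len(config$n_replicates)])
      )
    )
  )
}

#' Simulate single-cell FRAP traces with known immobile fraction
#'
#' Each cell's true relative fluorescence is 1 during the pre-bleach
#' frames, drops to `bleach_depth` at the first post-bleach frame, and
#' recovers mono-exponentially toward the asymptote
#' `1 - immobile_fraction * (1 - bleach_depth)`:
#' `RFI_j = b + (A - b) * (1 - exp(-recovery_rate * j))` for post-bleach
#' frame `j = 0, 1, ...`. Gaussian noise of sd `noise_sd` is added on the
#' RFI scale, after which each trace is mapped back to raw fluorescence
#' with a per-cell intensity scale and frame-constant background, so that
#' [normalize_trace()] has real work to undo.
#'
#' @param immobile_fraction true immobile fraction in \[0,1\].
#' @param recovery_rate exponential recovery rate per frame.
#' @param n_cells number of cells.
#' @param n_frames number of post-bleach recovery frames.
#' @param bleach_depth RFI immediately after bleaching (default 0.25).
#' @param noise_sd additive Gaussian noise sd on the RFI scale.
#' @param seed RNG seed.
#' @param n_prebleach pre-bleach frames (default 5, the short-assay
#'   profile).
#' @param frame_interval seconds per frame.
#' @return list of [frap_trace()] objects.
#' @export
simulate_frap_traces <- function(immobile_fraction, recovery_rate, n_cells,
                                 n_frames, bleach_depth = 0.25, noise_sd = 0,
                                 seed = 1L, n_prebleach = 5L, frame_interval = 0.4) {
  stopifnot(immobile_fraction >= 0, immobile_fraction <= 1,
            bleach_depth >= 0, bleach_depth < 1, recovery_rate >= 0,
            n_cells >= 1, n_frames >= 1, noise_sd >= 0)
  set.seed(seed)
  asymptote <- 1 - immobile_fraction * (1 - bleach_depth)
  j <- seq(0, n_frames - 1)
  true_rfi <- c(rep(1, n_prebleach),
                bleach_depth + (asymptote - bleach_depth) * (1 - exp(-recovery_rate * j)))
  lapply(seq_len(n_cells), function(cell) {
    scale <- stats::rlnorm(1, log(1000), 0.2)
    bg <- stats::runif(1, 30, 80)
    rfi <- true_rfi + stats::rnorm(length(true_rfi), 0, noise_sd)
    frap_trace(
      signal = bg + scale * rfi, background = bg,
      n_prebleach = n_prebleach, frame_interval = frame_interval,
      cell_id = sprintf("cell%03d", cell)
    )
  })
}

#' Simulate a long-format Ct table for the DPC-qPCR chain
#'
#' Builds a table with DPC and free-DNA fractions for an untreated sample
#' and FA timepoints, from known true relative DPC levels. Free-DNA Cts
#' are drawn around a base value; the DPC-fraction Ct of sample s is
#' `Ct_free,s + dct_nt - log2(true level of s relative to NT)`, plus
#' replicate noise, so [ddct_dpc_levels()] should recover the encoded
#' levels.
#'
#' @param true_levels named numeric vector of true DPC levels relative to
#'   the untreated sample; must include entries for `untreated` (typically
#'   1) and `fa_zero`.
#' @param amplicons character vector of amplicon names.
#' @param untreated,fa_zero sample labels.
#' @param n_replicates technical replicates per well.
#' @param base_ct free-DNA base Ct.
#' @param dct_nt DPC-minus-free Ct offset of the untreated sample.
#' @param noise_sd replicate Ct noise (0 for exact recovery).
#' @param seed RNG seed.
#' @return long-format Ct data.frame.
#' @export
simulate_ct_table <- function(true_levels, amplicons = "ampA",
                              untreated = "NT", fa_zero = "FA_0h",
                              n_replicates = 3L, base_ct = 22, dct_nt = 6,
                              noise_sd = 0, seed = 1L) {
  stopifnot(!is.null(names(true_levels)), untreated %in% names(true_levels),
            fa_zero %in% names(true_levels), all(true_levels > 0))
  set.seed(seed)
  rows <- list()
  for (amp in amplicons) {
    for (s in names(true_levels)) {
      ct_free <- base_ct + stats::runif(1, -1, 1)
      ct_dpc <- ct_free + dct_nt - log2(true_levels[[s]] / true_levels[[untreated]])
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          amplicon = amp, sample = s,
          fraction = c("DPC", "free"),
          replicate = rep_i,
          ct = c(ct_dpc, ct_free) + stats::rnorm(2, 0, noise_sd)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate BED-dialect fragments realizing integer bin counts
#'
#' For fixture writing: draws, for each bin, the requested integer number
#' of fragments with starts uniform in the bin (fragments may straddle the
#' next bin), high MAPQ, primary and non-duplicate. Intended for
#' small-scale I/O round-trips, not for genome-scale simulation.
#'
#' @param bins `genome_bins`.
#' @param counts integer per-bin fragment counts.
#' @param frag_len fragment (template) length in bases.
#' @param seed RNG seed.
#' @return a fragment data.frame compatible with [count_fragments()].
#' @export
generate_fragments <- function(bins, counts, frag_len = 300L, seed = 1L) {
  stopifnot(length(counts) == nrow(bins), all(counts == round(counts)), all(counts >= 0))
  set.seed(seed)
  idx <- rep(seq_len(nrow(bins)), counts)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mapq = integer(), is_primary = logical(), is_duplicate = logical()))
  }
  start <- floor(stats::runif(length(idx), bins$start[idx], bins$end[idx]))
  chrom_len <- stats::ave(bins$end, bins$chrom, FUN = max)[idx]
  end <- pmin(start + frag_len, chrom_len)
  data.frame(
    chrom = bins$chrom[idx], start = start, end = end,
    mapq = 60L, is_primary = TRUE, is_duplicate = FALSE
  )
}

#' Simulate a full DPC-seq experiment for one condition
#'
#' Convenience wrapper: genome -> bins -> expression track -> DPC counts.
#'
#' @param config a [simulation_config()].
#' @param condition condition label.
#' @return list with `config`, `chrom_sizes`, `genes`, `bins`,
#'   `expression` and the [simulate_dpc_counts()] output (`t0`, `t4`,
#'   `truth`).
#' @export
simulate_dpc_experiment <- function(config, condition = "WT") {
  genome <- simulate_genome(config)
  bins <- make_bins(genome$chrom_sizes, config$bin_size)
  expr <- simulate_expression_track(genome$genes, bins, config)
  counts <- simulate_dpc_counts(config, expr, condition)
  c(list(config = config, chrom_sizes = genome$chrom_sizes, genes = genome$genes,
         bins = bins, expression = expr), counts)
}
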