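#' Partition a genome into fixed-width bins
#'
#' Splits every chromosome into adjacent, non-overlapping bins of
#' `bin_size` bases. Coordinates are 0-based, half-open (BED convention)
#' throughout the package. The last bin of a chromosome is truncated at the
#' chromosome end, so each chromosome contributes `ceiling(length/bin_size)`
#' bins.
#'
#' @param chrom_sizes data.frame with columns `chrom` and `length` (bases),
#'   as read by [read_chrom_sizes()].
#' @param bin_size bin width in bases (default 1000, the 1-kb partition used
#'   for DPC-seq and nascent RNA-seq tracks).
#' @return A `genome_bins` data.frame with columns `chrom`, `start`, `end`
#'   and attribute `bin_size`.
#' @export
make_bins <- function(chrom_sizes, bin_size = 1000L) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(chrom_sizes$length <= 0)) stop("chromosome lengths must be positive")
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size <= 0) {
    stop("bin_size must be a single positive number")
  }
  bin_size <- as.integer(bin_size)
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- as.numeric(chrom_sizes$length[i])
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(
      chrom = chrom_sizes$chrom[i],
      start = starts,
      end = pmin(starts + bin_size, len),
      stringsAsFactors = FALSE
    )
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size
  class(bins) <- c("genome_bins", "data.frame")
  bins
}

#' Number of bins
#' @param bins a `genome_bins` object
#' @return integer bin count
#' @export
n_bins <- function(bins) nrow(bins)

#' Per-bin count table for one sample
#'
#' Container for per-bin fragment counts of a single sample
#' (timepoint x condition x replicate). Counts may be fractional (the 1/n
#' overlap rule) and the stored total always equals their sum.
#'
#' @param counts non-negative numeric vector, one value per bin
#' @param timepoint,condition,replicate sample labels
#' @return a `bin_counts` object
#' @export
bin_counts <- function(counts, timepoint = NA_character_, condition = NA_character_,
                       replicate = NA_character_) {
  stopifnot(is.numeric(counts), all(is.finite(counts)), all(counts >= 0))
  structure(
    list(
      counts = as.numeric(counts),
      total = sum(counts),
      timepoint = as.character(timepoint),
      condition = as.character(condition),
      replicate = as.character(replicate)
    ),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf(
    "<bin_counts> %d bins, total %.2f [%s / %s / rep %s]\n",
    length(x$counts), x$total, x$timepoint, x$condition, x$replicate
  ))
  invisible(x)
}

frag_cols <- c("chrom", "start", "end", "mapq", "is_primary", "is_duplicate")

#' Count aligned fragments into genome bins
#'
#' Aggregates fragment (template-span) intervals into per-bin counts under
#' featureCounts-style rules: unstranded; fragments failing the MAPQ,
#' primary-alignment or duplicate filters contribute nothing; a passing
#' fragment overlapping `n >= 1` bins contributes `1/n` to each overlapped
#' bin in fractional mode (the `--fraction` rule), or 1 to each otherwise.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `mapq`, `is_primary`, `is_duplicate`.
#' @param bins a `genome_bins` object.
#' @param mapq_min minimum mapping quality (default 30).
#' @param require_primary drop non-primary alignments (default TRUE).
#' @param ignore_duplicates drop duplicate-flagged fragments (default TRUE).
#' @param fractional use the 1/n rule (default TRUE).
#' @param on_unknown_chrom `"skip"` (default, with a warning) or `"error"`
#'   for fragments on chromosomes absent from `bins`.
#' @param timepoint,condition,replicate sample labels stored on the result.
#' @return a [bin_counts()] table. In fractional mode the total equals the
#'   number of filter-passing fragments that overlap at least one bin.
#' @export
count_fragments <- function(fragments, bins, mapq_min = 30, require_primary = TRUE,
                            ignore_duplicates = TRUE, fractional = TRUE,
                            on_unknown_chrom = c("skip", "error"),
                            timepoint = NA_character_, condition = NA_character_,
                            replicate = NA_character_) {
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  stopifnot(is.data.frame(fragments), all(frag_cols %in% names(fragments)))
  if (nrow(fragments) > 0 && any(fragments$start >= fragments$end)) {
    stop("fragment intervals must satisfy start < end")
  }
  keep <- fragments$mapq >= mapq_min
  if (require_primary) keep <- keep & fragments$is_primary
  if (ignore_duplicates) keep <- keep & !fragments$is_duplicate
  fr <- fragments[keep, , drop = FALSE]

  unknown <- !(fr$chrom %in% unique(bins$chrom))
  if (any(unknown)) {
    if (on_unknown_chrom == "error") {
      stop("fragments on chromosomes absent from the bin set: ",
           paste(unique(fr$chrom[unknown]), collapse = ", "))
    }
    warning(sprintf("skipping %d fragment(s) on unknown chromosomes", sum(unknown)))
    fr <- fr[!unknown, , drop = FALSE]
  }

  counts <- numeric(nrow(bins))
  if (nrow(fr) > 0) {
    bins_gr <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
    frag_gr <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(fr$start + 1L, fr$end))
    hits <- GenomicRanges::findOverlaps(frag_gr, bins_gr)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    n_per_frag <- tabulate(q, nbins = nrow(fr))
    w <- if (fractional) 1 / n_per_frag[q] else rep(1, length(q))
    acc <- tapply(w, s, sum)
    counts[as.integer(names(acc))] <- as.numeric(acc)
  }
  bin_counts(counts, timepoint = timepoint, condition = condition, replicate = replicate)
}

#' Combine replicate count tables on a common library scale
#'
#' Computes the average of the replicate totals, rescales each replicate so
#' its total equals that average, then averages the corresponding bins
#' across replicates. The combined total equals the average of the input
#' totals.
#'
#' @param tables list of [bin_counts()] tables over the same bin set.
#' @return a combined `bin_counts` table (replicate label `"combined"`).
#' @export
combine_replicates <- function(tables) {
  if (inherits(tables, "bin_counts")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, logical(1), "bin_counts")))
  nb <- vapply(tables, function(t) length(t$counts), integer(1))
  if (length(unique(nb)) != 1L) stop("replicate tables cover different bin sets")
  totals <- vapply(tables, function(t) t$total, numeric(1))
  if (any(totals <= 0)) stop("cannot combine a replicate with total count 0")
  t_bar <- mean(totals)
  scaled <- mapply(function(t, tot) t$counts * (t_bar / tot), tables, totals, SIMPLIFY = FALSE)
  combined <- Reduce(`+`, scaled) / length(scaled)
  bin_counts(combined,
    timepoint = tables[[1]]$timepoint,
    condition = tables[[1]]$condition,
    replicate = "combined"
  )
}

#' Per-bin expression track (raw counts and TPM)
#'
#' @param count non-negative per-bin raw fragment counts
#' @param tpm per-bin TPM values (0 wherever `count` is 0)
#' @param true_tpm optional ground-truth TPM column (synthetic data only)
#' @return an `expression_track` data.frame
#' @export
expression_track <- function(count, tpm, true_tpm = NULL) {
  stopifnot(length(count) == length(tpm), all(count >= 0), all(tpm >= 0))
  if (any(count == 0 & tpm != 0)) stop("tpm must be 0 wherever raw count is 0")
  out <- data.frame(count = as.numeric(count), tpm = as.numeric(tpm))
  if (!is.null(true_tpm)) out$true_tpm <- as.numeric(true_tpm)
  class(out) <- c("expression_track", "data.frame")
  out
}

#' Compute per-bin TPM from a count table
#'
#' `tpm_i = (count_i / length_kb_i) / sum_j(count_j / length_kb_j) * 1e6`.
#' With uniform bin lengths this reduces to counts per million; terminal
#' short bins are length-corrected.
#'
#' @param table a [bin_counts()] table.
#' @param bins the matching `genome_bins` object.
#' @return an [expression_track()] whose `tpm` column sums to 1e6.
#' @export
compute_tpm <- function(table, bins) {
  stopifnot(inherits(table, "bin_counts"), length(table$counts) == nrow(bins))
  if (table$total <= 0) stop("cannot compute TPM for a table with total count 0")
  len_kb <- (bins$end - bins$start) / 1000
  rate <- table$counts / len_kb
  expression_track(table$counts, rate / sum(rate) * 1e6)
}
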