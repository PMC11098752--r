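#' Per-bin repair percentage
#'
#' `100 * (c0 - c4) / c0` on the normalized 0 h counts. Bins whose
#' normalized 0 h count is zero are marked invalid rather than infinite and
#' are excluded from every summary; negative values (net DPC gain) are kept
#' unclipped.
#'
#' @param norm a `dpc_normalization` from [normalize_to_nonexpressed()].
#' @param mask the propagated [bin_mask()]; the track records it so
#'   summaries only ever see kept bins.
#' @return a `repair_track` list: `repair_percent` (NA where invalid),
#'   `valid` and `keep` logical vectors.
#' @export
repair_percent <- function(norm, mask) {
  stopifnot(inherits(norm, "dpc_normalization"), inherits(mask, "bin_mask"))
  c0 <- norm$table_0h$counts
  c4 <- norm$table_4h$counts
  stopifnot(length(mask$keep) == length(c0))
  valid <- c0 > 0
  rp <- rep(NA_real_, length(c0))
  rp[valid] <- 100 * (c0[valid] - c4[valid]) / c0[valid]
  structure(list(repair_percent = rp, valid = valid, keep = mask$keep),
            class = "repair_track")
}

#' Quartile summary of a repair track
#'
#' Median, Q1 and Q3 of the repair percentage over valid, kept bins,
#' optionally restricted by an extra selector (e.g. an expression
#' threshold mask).
#'
#' @param track a `repair_track`.
#' @param select optional additional logical selector or [bin_mask()].
#' @param label stratum/condition label carried into the output.
#' @param quartile_type passed to [stats::quantile()] (default 7).
#' @return one-row data.frame: `label`, `n_bins`, `q1`, `median`, `q3`.
#' @export
summarize_repair <- function(track, select = NULL, label = NA_character_,
                             quartile_type = 7) {
  stopifnot(inherits(track, "repair_track"))
  sel <- track$valid & track$keep
  if (!is.null(select)) {
    if (inherits(select, "bin_mask")) select <- select$keep
    stopifnot(is.logical(select), length(select) == length(sel))
    sel <- sel & select
  }
  if (!any(sel)) stop("no valid kept bins selected for summary")
  qs <- stats::quantile(track$repair_percent[sel], c(0.25, 0.5, 0.75),
                        type = quartile_type, names = FALSE)
  data.frame(label = label, n_bins = sum(sel), q1 = qs[1], median = qs[2], q3 = qs[3])
}

#' Expression-stratified repair summaries
#'
#' Bins are stratified on RNA TPM into half-open intervals
#' `[e_k, e_{k+1})` defined by strictly increasing edges; one quartile
#' summary per stratum. Empty strata are reported with `n_bins = 0` and NA
#' quartiles.
#'
#' @param track a `repair_track`.
#' @param rna the RNA [expression_track()].
#' @param stratum_edges strictly increasing TPM edges (append `Inf` for an
#'   open last stratum).
#' @param quartile_type passed to [stats::quantile()].
#' @return data.frame of per-stratum summaries, lowest stratum first.
#' @export
stratify_by_expression <- function(track, rna, stratum_edges, quartile_type = 7) {
  stopifnot(inherits(track, "repair_track"), inherits(rna, "expression_track"))
  if (length(stratum_edges) < 2L || any(diff(stratum_edges) <= 0)) {
    stop("stratum edges must be strictly increasing with at least two values")
  }
  idx <- findInterval(rna$tpm, stratum_edges)
  out <- vector("list", length(stratum_edges) - 1L)
  for (k in seq_along(out)) {
    label <- sprintf("[%g,%g)", stratum_edges[k], stratum_edges[k + 1])
    sel <- idx == k
    if (any(sel & track$valid & track$keep)) {
      out[[k]] <- summarize_repair(track, select = sel, label = label,
                                   quartile_type = quartile_type)
    } else {
      out[[k]] <- data.frame(label = label, n_bins = 0L,
                             q1 = NA_real_, median = NA_real_, q3 = NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-level repair profile
#'
#' Per-bin repair along a gene, computed as the difference between the
#' normalized 0 h counts and the 4 h counts (`c0 - c4`) for every bin the
#' gene overlaps, ordered 5'->3' along the gene's strand (minus-strand
#' genes reverse genomic order). The repair percentage is also emitted for
#' convenience.
#'
#' @param norm a `dpc_normalization`.
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` and optionally `gene_id`.
#' @param bins the `genome_bins` partition.
#' @return a data.frame with `gene_id`, `position` (1 = 5' end), `bin`,
#'   `diff` and `repair_percent`.
#' @export
gene_repair_profile <- function(norm, gene, bins) {
  stopifnot(inherits(norm, "dpc_normalization"), inherits(bins, "genome_bins"))
  gene <- as.list(gene)
  if (!gene$chrom %in% bins$chrom) stop("gene chromosome absent from the binned genome")
  hit <- which(bins$chrom == gene$chrom & bins$start < gene$end & bins$end > gene$start)
  if (length(hit) == 0L) stop("gene overlaps no bins")
  if (identical(gene$strand, "-")) hit <- rev(hit)
  c0 <- norm$table_0h$counts[hit]
  c4 <- norm$table_4h$counts[hit]
  data.frame(
    gene_id = if (is.null(gene$gene_id)) NA_character_ else gene$gene_id,
    position = seq_along(hit),
    bin = hit,
    diff = c0 - c4,
    repair_percent = ifelse(c0 > 0, 100 * (c0 - c4) / c0, NA_real_)
  )
}

#' Two-group comparison of repair values
#'
#' Unpaired two-tailed t-test between two collections of per-bin repair
#' percentages (Student's equal-variance by default, Welch optional).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `p`, `df` and `method`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 finite values")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       method = ht$method)
}
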