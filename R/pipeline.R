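#' Run the full binned DPC repair pipeline
#'
#' Applies the complete analysis chain to replicate DPC-seq bin count
#' tables and a nascent-RNA track:
#' \enumerate{
#'   \item combine replicates of the 0 h and 4 h samples on a common
#'     library scale;
#'   \item flag DNA outlier bins by the IQR rule in each combined DNA
#'     table, and low-coverage DNA bins by the TPM floor;
#'   \item propagate every mask across all datasets (a bin removed
#'     anywhere is removed everywhere);
#'   \item rescale the 0 h sample to the 4 h level on the
#'     zero-transcription (zero RNA read) reference bins;
#'   \item compute per-bin repair percentages and summarize over expressed
#'     bins (RNA TPM above `expr_threshold`).
#' }
#'
#' @param t0_reps,t4_reps lists of [bin_counts()] replicate tables.
#' @param rna the RNA [expression_track()].
#' @param bins the `genome_bins` partition.
#' @param tpm_floor DNA TPM floor (default 0.08).
#' @param expr_threshold final RNA TPM threshold for the headline summary
#'   (default 3; `NULL` excludes only zero-TPM bins).
#' @param quartile_type quantile interpolation rule (default 7).
#' @return list with the combined tables (`t0`, `t4`), `mask`
#'   (propagated), `filter_report`, `norm` (the normalization result),
#'   `track` (the repair track), `expressed` (the threshold mask) and
#'   `summary` (quartile summary over expressed bins).
#' @export
run_repair_pipeline <- function(t0_reps, t4_reps, rna, bins,
                                tpm_floor = 0.08, expr_threshold = 3,
                                quartile_type = 7) {
  t0 <- combine_replicates(t0_reps)
  t4 <- combine_replicates(t4_reps)

  iqr0 <- iqr_outlier_mask(t0, quartile_type = quartile_type, dataset = "dna_0h")
  iqr4 <- iqr_outlier_mask(t4, quartile_type = quartile_type, dataset = "dna_4h")
  floor0 <- tpm_floor_mask(compute_tpm(t0, bins), floor = tpm_floor, dataset = "dna_0h")
  floor4 <- tpm_floor_mask(compute_tpm(t4, bins), floor = tpm_floor, dataset = "dna_4h")
  mask <- propagate_mask(list(iqr0$mask, iqr4$mask, floor0, floor4))
  report <- rbind(iqr0$report, iqr4$report)
  report$fraction_bins_remaining_all <- mean(mask$keep)

  norm <- normalize_to_nonexpressed(t0, t4, rna, mask)
  track <- repair_percent(norm, mask)
  expressed <- expression_threshold_mask(rna, expr_threshold)
  summary <- summarize_repair(track, select = expressed,
                              label = if (is.null(expr_threshold)) "tpm>0"
                                      else sprintf("tpm>%g", expr_threshold),
                              quartile_type = quartile_type)

  list(t0 = t0, t4 = t4, mask = mask, filter_report = report, norm = norm,
       track = track, expressed = expressed, summary = summary)
}
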