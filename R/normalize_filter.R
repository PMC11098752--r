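#' Bin keep/drop mask with provenance
#'
#' @param keep logical vector, TRUE for bins retained
#' @param provenance character vector naming the rule that removed each
#'   dropped bin (`NA` for kept bins)
#' @return a `bin_mask` object
#' @export
bin_mask <- function(keep, provenance = NULL) {
  stopifnot(is.logical(keep), !anyNA(keep))
  if (is.null(provenance)) provenance <- rep(NA_character_, length(keep))
  stopifnot(length(provenance) == length(keep))
  structure(list(keep = keep, provenance = as.character(provenance)), class = "bin_mask")
}

#' @export
print.bin_mask <- function(x, ...) {
  cat(sprintf("<bin_mask> %d/%d bins kept\n", sum(x$keep), length(x$keep)))
  invisible(x)
}

#' Flag outlier bins by the IQR rule
#'
#' Computes Q1 and Q3 of the per-bin counts and flags bins below
#' `Q1 - 1.5 * IQR` or above `Q3 + 1.5 * IQR`. When the lower bound falls
#' below zero no low-end bins are flagged (count data cannot fall under a
#' negative bound, and the rule is applied literally).
#'
#' @param table a [bin_counts()] table (>= 4 bins).
#' @param quartile_type quantile interpolation rule passed to
#'   [stats::quantile()] (default 7, linear interpolation between order
#'   statistics).
#' @param dataset label recorded in the report and provenance strings.
#' @return list with elements `mask` (a [bin_mask()]) and `report`
#'   (a one-row data.frame with Q1, Q3, IQR, removal counts and the
#'   fraction of bins remaining).
#' @export
iqr_outlier_mask <- function(table, quartile_type = 7, dataset = "dna") {
  stopifnot(inherits(table, "bin_counts"))
  x <- table$counts
  if (length(x) < 4L) stop("IQR filtering requires at least 4 bins")
  qs <- stats::quantile(x, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- qs[2] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[2] + 1.5 * iqr
  flag_low <- if (lo < 0) rep(FALSE, length(x)) else x < lo
  flag_high <- x > hi
  keep <- !(flag_low | flag_high)
  prov <- rep(NA_character_, length(x))
  prov[flag_low] <- paste0("iqr_low:", dataset)
  prov[flag_high] <- paste0("iqr_high:", dataset)
  report <- data.frame(
    dataset = dataset, q1 = qs[1], q3 = qs[2], iqr = iqr,
    lower_bound = lo, upper_bound = hi,
    n_removed_low = sum(flag_low), n_removed_high = sum(flag_high),
    fraction_bins_remaining = mean(keep)
  )
  list(mask = bin_mask(keep, prov), report = report)
}

#' Flag low-coverage DNA bins by a TPM floor
#'
#' Bins whose DNA TPM is strictly below `floor` are flagged (they provide
#' limited opportunity for repair and add noise); a TPM exactly equal to the
#' floor is kept.
#'
#' @param dna_tpm an [expression_track()] of DNA bin TPMs.
#' @param floor TPM floor (default 0.08).
#' @param dataset label used in provenance strings.
#' @return a [bin_mask()].
#' @export
tpm_floor_mask <- function(dna_tpm, floor = 0.08, dataset = "dna") {
  stopifnot(inherits(dna_tpm, "expression_track"))
  flag <- dna_tpm$tpm < floor
  prov <- rep(NA_character_, length(flag))
  prov[flag] <- paste0("tpm_floor:", dataset)
  bin_mask(!flag, prov)
}

#' Propagate masks across all datasets
#'
#' A bin removed by any rule in any dataset is removed from all datasets:
#' the combined keep flag is the logical AND of the input keep flags, with
#' provenance merged (first applicable rule wins; ties joined with `;`).
#'
#' @param masks list of [bin_mask()] objects over the same bin set.
#' @return the combined [bin_mask()].
#' @export
propagate_mask <- function(masks) {
  if (inherits(masks, "bin_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L, all(vapply(masks, inherits, logical(1), "bin_mask")))
  nb <- vapply(masks, function(m) length(m$keep), integer(1))
  if (length(unique(nb)) != 1L) stop("masks cover different bin sets")
  keep <- Reduce(`&`, lapply(masks, `[[`, "keep"))
  prov <- rep(NA_character_, nb[1])
  for (m in masks) {
    add <- !is.na(m$provenance)
    prov[add] <- ifelse(is.na(prov[add]), m$provenance[add],
                        paste(prov[add], m$provenance[add], sep = ";"))
  }
  bin_mask(keep, prov)
}

#' Scale the 0 h sample to the 4 h level using zero-transcription bins
#'
#' RNA bins with zero raw reads indicate no transcription, hence no
#' transcription-coupled repair; the DPC signal there should be unchanged
#' between 0 h and 4 h. Kept bins with zero RNA reads are summed in both
#' DNA samples and the ratio `sum_ref(4h) / sum_ref(0h)` rescales every
#' 0 h bin onto the 4 h sample's library scale.
#'
#' @param table_0h,table_4h [bin_counts()] tables (replicate-combined).
#' @param rna the RNA [expression_track()].
#' @param mask the propagated [bin_mask()].
#' @return a `dpc_normalization` list: `scale_ratio`, `n_reference_bins`,
#'   `reference` (logical selector), the scaled 0 h table (`table_0h`) and
#'   the untouched 4 h table (`table_4h`).
#' @export
normalize_to_nonexpressed <- function(table_0h, table_4h, rna, mask) {
  stopifnot(
    inherits(table_0h, "bin_counts"), inherits(table_4h, "bin_counts"),
    inherits(rna, "expression_track"), inherits(mask, "bin_mask")
  )
  nb <- length(table_0h$counts)
  if (length(table_4h$counts) != nb || nrow(rna) != nb || length(mask$keep) != nb) {
    stop("tables, RNA track and mask cover different bin sets")
  }
  ref <- mask$keep & rna$count == 0
  if (!any(ref)) stop("no surviving zero-transcription reference bins")
  s0 <- sum(table_0h$counts[ref])
  s4 <- sum(table_4h$counts[ref])
  if (s0 <= 0) stop("reference bins carry no 0 h signal; cannot compute scale ratio")
  ratio <- s4 / s0
  scaled <- bin_counts(table_0h$counts * ratio,
    timepoint = table_0h$timepoint, condition = table_0h$condition,
    replicate = table_0h$replicate
  )
  structure(
    list(
      scale_ratio = ratio, n_reference_bins = sum(ref), reference = ref,
      table_0h = scaled, table_4h = table_4h
    ),
    class = "dpc_normalization"
  )
}

#' @export
print.dpc_normalization <- function(x, ...) {
  cat(sprintf(
    "<dpc_normalization> scale ratio %.4f over %d zero-transcription reference bins\n",
    x$scale_ratio, x$n_reference_bins
  ))
  invisible(x)
}

#' Final expression-threshold filter
#'
#' With a threshold `t`, bins whose RNA TPM is less than or equal to `t`
#' are removed (kept bins satisfy `TPM > t`); with no threshold, all bins
#' with RNA TPM equal to zero are removed.
#'
#' @param rna the RNA [expression_track()].
#' @param tpm_threshold TPM threshold, or `NULL` for the zero-TPM default.
#' @return a [bin_mask()].
#' @export
expression_threshold_mask <- function(rna, tpm_threshold = NULL) {
  stopifnot(inherits(rna, "expression_track"))
  if (is.null(tpm_threshold)) {
    keep <- rna$tpm > 0
    rule <- "rna_tpm_zero"
  } else {
    if (tpm_threshold < 0) stop("TPM threshold must be non-negative")
    keep <- rna$tpm > tpm_threshold
    rule <- sprintf("rna_tpm_le_%g", tpm_threshold)
  }
  prov <- rep(NA_character_, length(keep))
  prov[!keep] <- rule
  bin_mask(keep, prov)
}

#' Write a filter report as JSON
#'
#' @param report data.frame of per-dataset IQR filter reports
#'   (rbind of [iqr_outlier_mask()] reports).
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}
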