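#' Validate a long-format Ct table
#'
#' Expected columns: `amplicon`, `sample`, `fraction` (e.g. `"DPC"` /
#' `"free"`; a transcription table may use a single fraction), `replicate`,
#' `ct`. Ct values must be finite and positive. Replicates are averaged on
#' the Ct scale before any normalization.
#'
#' @param ct data.frame in long format.
#' @return the averaged table (one row per amplicon x sample x fraction,
#'   column `ct`).
#' @export
average_ct_replicates <- function(ct) {
  need <- c("amplicon", "sample", "fraction", "ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) stop("Ct values must be finite and positive")
  out <- stats::aggregate(ct ~ amplicon + sample + fraction, data = ct, FUN = mean)
  out
}

#' Relative DPC levels by the 2^-ddCt chain
#'
#' Three-step normalization of DPC-qPCR data: (1) DPC-associated DNA is
#' normalized to free DNA within each sample,
#' `2^-[(Ct_DPC,s - Ct_free,s) - (Ct_DPC,NT - Ct_free,NT)]`, which also
#' places the untreated sample at 1; (2) that step's output is already
#' relative to the untreated (non-treated) sample; (3) all samples are then
#' divided by the FA 0 h value so the FA 0 h sample is exactly 1.
#'
#' @param ct long-format Ct table (see [average_ct_replicates()]).
#' @param untreated sample label of the non-treated reference.
#' @param fa_zero sample label of the FA 0 h reference.
#' @param dpc_fraction,free_fraction fraction labels.
#' @return data.frame with `amplicon`, `sample`, `level_vs_nt` (after steps
#'   1-2) and `level` (after step 3; `level == 1` at FA 0 h).
#' @export
ddct_dpc_levels <- function(ct, untreated = "NT", fa_zero = "FA_0h",
                            dpc_fraction = "DPC", free_fraction = "free") {
  avg <- average_ct_replicates(ct)
  out <- lapply(split(avg, avg$amplicon), function(a) {
    dpc <- a[a$fraction == dpc_fraction, ]
    fre <- a[a$fraction == free_fraction, ]
    samples <- sort(unique(a$sample))
    ct_dpc <- dpc$ct[match(samples, dpc$sample)]
    ct_free <- fre$ct[match(samples, fre$sample)]
    if (anyNA(ct_dpc) || anyNA(ct_free)) {
      stop("missing DPC or free-DNA measurement for amplicon ", a$amplicon[1])
    }
    dct <- ct_dpc - ct_free
    if (!untreated %in% samples) stop("missing untreated reference sample '", untreated, "'")
    ddct <- dct - dct[samples == untreated]
    level_vs_nt <- 2^(-ddct)
    if (!fa_zero %in% samples) stop("missing FA 0 h reference sample '", fa_zero, "'")
    level <- level_vs_nt / level_vs_nt[samples == fa_zero]
    data.frame(amplicon = a$amplicon[1], sample = samples,
               level_vs_nt = level_vs_nt, level = level)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative transcription by the 2^-dCt chain
#'
#' Within each treatment arm, every timepoint is normalized to that arm's
#' 0 min sample: `level = 2^-(Ct_s - Ct_0min)`, so the 0 min sample is
#' exactly 1.
#'
#' @param ct long-format Ct table; the `sample` column holds the timepoint
#'   label and an additional `treatment` column identifies the arm (a
#'   missing `treatment` column means a single arm).
#' @param reference sample label of the time-zero reference
#'   (default `"0min"`).
#' @return data.frame with `amplicon`, `treatment`, `sample`, `level`.
#' @export
dct_transcription <- function(ct, reference = "0min") {
  if (!"treatment" %in% names(ct)) ct$treatment <- "all"
  need <- c("amplicon", "treatment", "sample", "ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) stop("Ct values must be finite and positive")
  avg <- stats::aggregate(ct ~ amplicon + treatment + sample, data = ct, FUN = mean)
  out <- lapply(split(avg, list(avg$amplicon, avg$treatment), drop = TRUE), function(a) {
    if (!reference %in% a$sample) {
      stop("missing '", reference, "' sample for treatment ", a$treatment[1])
    }
    ct0 <- a$ct[a$sample == reference]
    data.frame(amplicon = a$amplicon[1], treatment = a$treatment[1],
               sample = a$sample, level = 2^(-(a$ct - ct0)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
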