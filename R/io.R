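#' Read and write chrom.sizes tables
#'
#' Tab-separated, two columns: chromosome name and length in bases.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(out$length <= 0)) stop("chromosome lengths must be positive")
  out
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes data.frame with columns `chrom`, `length`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(chrom_sizes[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write the fragment BED dialect
#'
#' BED6 with the fragment's MAPQ in the score column, strand `"."`
#' (counting is unstranded) and the alignment flags encoded in the name
#' field as `id;primary=0/1;dup=0/1`.
#'
#' @param path file path.
#' @return fragment data.frame (`chrom`, `start`, `end`, `mapq`,
#'   `is_primary`, `is_duplicate`) compatible with [count_fragments()].
#' @export
read_fragments_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name", "score", "strand"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "integer", "character"))
  parse_flag <- function(key) {
    m <- regmatches(raw$name, regexpr(paste0(key, "=[01]"), raw$name))
    if (length(m) != nrow(raw)) stop("malformed fragment name field (missing ", key, "=)")
    substring(m, nchar(key) + 2L) == "1"
  }
  data.frame(
    chrom = raw$chrom, start = raw$start, end = raw$end, mapq = raw$score,
    is_primary = parse_flag("primary"), is_duplicate = parse_flag("dup")
  )
}

#' @rdname read_fragments_bed
#' @param fragments fragment data.frame.
#' @export
write_fragments_bed <- function(fragments, path) {
  name <- sprintf("frag%06d;primary=%d;dup=%d", seq_len(nrow(fragments)),
                  as.integer(fragments$is_primary), as.integer(fragments$is_duplicate))
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    name, fragments$mapq, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write per-bin values as bedGraph
#'
#' Four tab-separated columns: chrom, start, end, value (0-based
#' half-open intervals).
#'
#' @param path file path.
#' @param bins optional `genome_bins`; when given, the records are checked
#'   to match the partition bin-for-bin and the value vector is returned in
#'   bin order.
#' @return with `bins`: numeric vector of per-bin values; otherwise a
#'   data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, bins = NULL) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric", "numeric"))
  if (is.null(bins)) return(out)
  if (nrow(out) != nrow(bins) ||
      !all(out$chrom == bins$chrom & out$start == bins$start & out$end == bins$end)) {
    stop("bedGraph records do not match the bin partition")
  }
  out$value
}

#' @rdname read_bedgraph
#' @param values numeric per-bin values (one per bin).
#' @export
write_bedgraph <- function(values, bins, path) {
  stopifnot(length(values) == nrow(bins))
  utils::write.table(data.frame(bins$chrom, bins$start, bins$end, values),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write FRAP trace CSV files
#'
#' Long format, one row per frame: `cell_id`, `frame` (1-based),
#' `signal`, `background`.
#'
#' @param path file path.
#' @param n_prebleach pre-bleach frame count used to rebuild
#'   [frap_trace()] objects.
#' @param frame_interval seconds per frame.
#' @return list of `frap_trace` objects, one per cell.
#' @export
read_frap_csv <- function(path, n_prebleach, frame_interval = 0.4) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "frame", "signal", "background") %in% names(raw)))
  lapply(split(raw, raw$cell_id), function(d) {
    d <- d[order(d$frame), ]
    frap_trace(d$signal, d$background, n_prebleach = n_prebleach,
               frame_interval = frame_interval, cell_id = d$cell_id[1])
  })
}

#' @rdname read_frap_csv
#' @param traces list of [frap_trace()] objects.
#' @export
write_frap_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, frame = seq_along(tr$signal),
               signal = tr$signal, background = tr$background)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write long-format Ct tables as CSV
#'
#' @param path file path.
#' @return Ct data.frame.
#' @export
read_ct_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname read_ct_csv
#' @param ct Ct data.frame.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete set of synthetic fixtures to a directory
#'
#' Emits chrom.sizes, a fragment BED realizing the first 0 h replicate's
#' counts (rounded to integers), bedGraphs of the DPC bin counts and the
#' RNA count/TPM track, a FRAP CSV and a Ct CSV. Everything round-trips
#' through the corresponding readers.
#'
#' @param experiment output of [simulate_dpc_experiment()].
#' @param frap_traces list of [frap_trace()] objects.
#' @param ct Ct data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(experiment, frap_traces, ct, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bins <- experiment$bins
  paths <- c(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    fragments = file.path(dir, "dpc_0h_rep1.fragments.bed"),
    dpc_0h = file.path(dir, "dpc_0h_rep1.counts.bedGraph"),
    dpc_4h = file.path(dir, "dpc_4h_rep1.counts.bedGraph"),
    rna_counts = file.path(dir, "rna.counts.bedGraph"),
    rna_tpm = file.path(dir, "rna.tpm.bedGraph"),
    frap = file.path(dir, "frap_traces.csv"),
    ct = file.path(dir, "ct_table.csv")
  )
  write_chrom_sizes(experiment$chrom_sizes, paths["chrom_sizes"])
  frags <- generate_fragments(bins, round(experiment$t0[[1]]$counts),
                              seed = experiment$config$seed)
  write_fragments_bed(frags, paths["fragments"])
  write_bedgraph(experiment$t0[[1]]$counts, bins, paths["dpc_0h"])
  write_bedgraph(experiment$t4[[1]]$counts, bins, paths["dpc_4h"])
  write_bedgraph(experiment$expression$count, bins, paths["rna_counts"])
  write_bedgraph(experiment$expression$tpm, bins, paths["rna_tpm"])
  write_frap_csv(frap_traces, paths["frap"])
  write_ct_csv(ct, paths["ct"])
  invisible(paths)
}
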