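#' Caller parameters for run-length CNV detection
#'
#' @description
#' Aberrations are detected as maximal runs of consecutive probes whose
#' log2 ratios all clear a threshold, with a minimum run length. The
#' classic reporting rule for such arrays assigns a CNV to any segment of
#' at least three consecutive probes, gains above zero and losses below
#' zero; on noisy data a zero cutoff calls an aberration at almost every
#' probe, so the default thresholds are the conventional +/-0.25 on the
#' log2 scale. Setting `gain_threshold = 0` and `loss_threshold = 0`
#' ("sign mode") recovers the literal sign rule for noiseless input.
#'
#' @param min_probes minimum consecutive probes per call (default 3).
#' @param gain_threshold log2 ratio at or above which a probe supports a
#'   gain (default 0.25; must be >= 0).
#' @param loss_threshold log2 ratio at or below which a probe supports a
#'   loss (default -0.25; must be <= 0).
#' @param max_probe_gap optional maximum distance in bp between adjacent
#'   probes within a run; `NULL` (default) never breaks runs on distance.
#' @return A `caller_params` list.
#' @export
caller_params <- function(min_probes = 3, gain_threshold = 0.25,
                          loss_threshold = -0.25, max_probe_gap = NULL) {
  if (min_probes < 1) abort("'min_probes' must be >= 1")
  if (gain_threshold < 0) abort("'gain_threshold' must be >= 0")
  if (loss_threshold > 0) abort("'loss_threshold' must be <= 0")
  if (!is.null(max_probe_gap) && max_probe_gap <= 0) {
    abort("'max_probe_gap' must be positive or NULL")
  }
  structure(list(min_probes = as.integer(min_probes),
                 gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold,
                 max_probe_gap = max_probe_gap),
            class = "caller_params")
}

#' Read a probe-level log2-ratio table
#'
#' Expects a tab-delimited file with header columns `sample_id`, `chrom`,
#' `position`, `log2_ratio` (as written by [write_sample_array()]).
#' Probes are sorted by chromosome and position; non-finite ratios and
#' duplicate positions are rejected.
#'
#' @param path path to the TSV file.
#' @return A `SampleArray` data.frame.
#' @export
read_sample_array <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "chrom", "position", "log2_ratio")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  ratio <- suppressWarnings(as.numeric(raw$log2_ratio))
  bad <- which(is.na(pos) | !is.finite(ratio))
  if (length(bad)) {
    abort("non-numeric or non-finite value at line %d of %s",
          bad[1] + 1L, path)  # +1 for the header line
  }
  out <- data.frame(sample_id = raw$sample_id, chrom = raw$chrom,
                    position = pos, log2_ratio = ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$chrom, out$position), , drop = FALSE]
  dup <- duplicated(out[, c("sample_id", "chrom", "position")])
  if (any(dup)) {
    abort("duplicate probe position on chromosome %s", out$chrom[dup][1])
  }
  rownames(out) <- NULL
  out
}

#' Call per-sample CNVs by thresholded run-length scanning
#'
#' Scans each chromosome of each sample for maximal runs of consecutive
#' probes that all sit at or above `gain_threshold` (gain) or at or below
#' `loss_threshold` (loss). A run becomes a call when it spans at least
#' `min_probes` probes; its `start`/`end` are the first and last probe
#' positions of the run. Runs are maximal: the adjacent probe on either
#' side (if any) does not satisfy the run's threshold.
#'
#' @param array a `SampleArray` data.frame (one or more samples).
#' @param params a [caller_params()] object.
#' @return Data.frame of calls with columns `sample_id`, `chrom`, `start`,
#'   `end`, `direction`, `n_probes`, `mean_log2`, sorted by sample,
#'   chromosome and start. Zero rows when nothing qualifies.
#' @examples
#' pm <- make_probe_map(c(chr1 = 2e6), mean_spacing = 1e5, seed = 1)
#' ev <- data.frame(chrom = "chr1", start = 1, end = 8e5,
#'                  direction = "loss", shift = -1)
#' arr <- simulate_sample_array(pm, ev, noise_sd = 0, seed = 1)
#' call_cnvs(arr)
#' @export
call_cnvs <- function(array, params = caller_params()) {
  if (NROW(array) == 0L) abort("'array' has no probes")
  stopifnot(inherits(params, "caller_params"))

  out <- list()
  for (sid in unique(array$sample_id)) {
    sarr <- array[array$sample_id == sid, , drop = FALSE]
    for (chrom in unique(sarr$chrom)) {
      sub <- sarr[sarr$chrom == chrom, , drop = FALSE]
      sub <- sub[order(sub$position), , drop = FALSE]
      if (any(!is.finite(sub$log2_ratio))) {
        abort("non-finite log2 ratio in sample %s", sid)
      }
      out[[length(out) + 1L]] <- scan_chromosome(
        sid, chrom, sub$position, sub$log2_ratio, params)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(empty_calls())
  }
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = integer(), end = integer(), direction = character(),
             n_probes = integer(), mean_log2 = numeric(),
             stringsAsFactors = FALSE)
}

# Internal: run-length scan of one chromosome of one sample.
# state: +1 where the probe supports a gain, -1 a loss, 0 neither;
# a probe exactly at a threshold qualifies (closed boundaries).
scan_chromosome <- function(sample_id, chrom, pos, ratio, params) {
  state <- integer(length(ratio))
  state[ratio >= params$gain_threshold] <- 1L
  state[ratio <= params$loss_threshold] <- -1L
  # thresholds (0, 0) would mark a zero ratio as both; treat as neither
  if (params$gain_threshold == 0 && params$loss_threshold == 0) {
    state[ratio == 0] <- 0L
    state[ratio > 0] <- 1L
    state[ratio < 0] <- -1L
  }
  # break runs across probe deserts when a gap limit is set
  run_id <- cumsum(c(1L, as.integer(
    diff(state) != 0L |
      (if (is.null(params$max_probe_gap)) FALSE
       else diff(pos) > params$max_probe_gap))))
  calls <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (state[idx[1]] == 0L || length(idx) < params$min_probes) next
    calls[[length(calls) + 1L]] <- data.frame(
      sample_id = sample_id, chrom = chrom,
      start = pos[idx[1]], end = pos[idx[length(idx)]],
      direction = if (state[idx[1]] > 0L) "gain" else "loss",
      n_probes = length(idx), mean_log2 = mean(ratio[idx]),
      stringsAsFactors = FALSE)
  }
  if (length(calls)) do.call(rbind, calls) else empty_calls()
}

#' Write CNV calls to TSV (and optionally BED)
#'
#' @param calls call table from [call_cnvs()].
#' @param path output TSV path.
#' @param bed_path optional BED path (0-based half-open,
#'   name = `sample_id:direction`).
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path, bed_path = NULL) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                      end = calls$end,
                      name = paste0(calls$sample_id, ":", calls$direction))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a CNV call table written by [write_cnv_calls()]
#'
#' @param path TSV path with the seven call columns.
#' @return Call data.frame.
#' @export
read_cnv_calls <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "direction")
  missing <- setdiff(need, names(calls))
  if (length(missing)) {
    abort("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  }
  calls
}
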