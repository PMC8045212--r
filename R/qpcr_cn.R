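#' Read a qPCR plate from TSV
#'
#' Expects columns `sample_id`, `well`, `target_ct`, `reference_ct` (as
#' written by [write_qpcr_plate()]). Ct values must be finite and
#' positive.
#'
#' @param path TSV path.
#' @return A `QpcrPlate` data.frame.
#' @export
read_qpcr_plate <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  plate <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "well", "target_ct", "reference_ct")
  missing <- setdiff(need, names(plate))
  if (length(missing)) {
    abort("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  }
  ct <- c(plate$target_ct, plate$reference_ct)
  if (any(!is.finite(ct) | ct <= 0)) abort("Ct values must be finite and > 0")
  plate
}

#' Aggregate replicate wells into per-sample delta-Ct
#'
#' Computes delta-Ct (target Ct minus reference Ct) per well, drops wells
#' farther than `outlier_ct` cycles from the sample's median delta-Ct,
#' and returns the mean and sd over the surviving wells. A sample whose
#' wells are all dropped is kept with `n_used = 0` and a flag rather
#' than silently removed.
#'
#' @param plate a `QpcrPlate` data.frame.
#' @param outlier_ct rejection radius around the per-sample median
#'   delta-Ct, in cycles (default 0.5).
#' @return Data.frame with columns `sample_id`, `mean_dct`, `sd_dct`,
#'   `n_used`, `all_dropped`.
#' @examples
#' plate <- data.frame(sample_id = "S1", well = 1:4,
#'                     target_ct = c(26, 26, 26, 28), reference_ct = 25)
#' aggregate_replicates(plate)  # outlier well 4 dropped, n_used 3
#' @export
aggregate_replicates <- function(plate, outlier_ct = 0.5) {
  if (NROW(plate) == 0L) abort("plate has no wells")
  if (outlier_ct < 0) abort("'outlier_ct' must be >= 0")
  dct <- plate$target_ct - plate$reference_ct
  rows <- lapply(unique(plate$sample_id), function(sid) {
    d <- dct[plate$sample_id == sid]
    if (length(d) == 0L) abort("sample %s has zero wells", sid)
    keep <- abs(d - stats::median(d)) <= outlier_ct
    used <- d[keep]
    data.frame(sample_id = sid,
               mean_dct = if (length(used)) mean(used) else NA_real_,
               sd_dct = if (length(used) > 1L) stats::sd(used)
                        else if (length(used) == 1L) 0 else NA_real_,
               n_used = length(used),
               all_dropped = length(used) == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy number from the comparative delta-delta-Ct closed form
#'
#' `ddCt = sample dCt - calibrator dCt`;
#' `cn = calibrator_cn * 2^(-ddCt)`. One missing target copy raises the
#' sample's delta-Ct by one cycle, halving the estimate.
#'
#' @param sample_dct per-sample mean delta-Ct (vector ok).
#' @param calibrator_dct mean delta-Ct of the calibrator sample.
#' @param calibrator_cn known calibrator copy number (default 2).
#' @return Numeric copy-number estimate(s).
#' @examples
#' estimate_copy_number(2.0, 1.0)  # ddCt +1 -> 1 copy
#' @export
estimate_copy_number <- function(sample_dct, calibrator_dct,
                                 calibrator_cn = 2) {
  if (calibrator_cn < 1) abort("'calibrator_cn' must be >= 1")
  calibrator_cn * 2^(-(sample_dct - calibrator_dct))
}

#' Categorize a copy-number estimate as loss / normal / gain
#'
#' The estimate is integerized by rounding half away from zero, then
#' classified against the diploid state: below two copies is a loss,
#' exactly two is normal, above two is a gain. Estimates sitting far from
#' any integer (more than `confidence_margin` away) are flagged low
#' confidence.
#'
#' @param cn_estimate non-negative copy-number estimate (vector ok).
#' @param confidence_margin distance from the nearest integer beyond
#'   which the call is flagged (default 0.35).
#' @return Data.frame with columns `cn_estimate`, `cn_integer`,
#'   `category`, `low_confidence`.
#' @examples
#' categorize_copy_number(c(1.04, 2.0, 2.5))$category
#' @export
categorize_copy_number <- function(cn_estimate, confidence_margin = 0.35) {
  if (any(cn_estimate < 0)) abort("negative copy-number estimate")
  cn_int <- as.integer(round_half_up(cn_estimate))
  category <- ifelse(cn_int < 2L, "loss", ifelse(cn_int == 2L,
                                                 "normal", "gain"))
  data.frame(cn_estimate = cn_estimate, cn_integer = cn_int,
             category = category,
             low_confidence = abs(cn_estimate - cn_int) > confidence_margin,
             stringsAsFactors = FALSE)
}

#' Full plate-to-copy-number workflow
#'
#' Aggregates replicates, calibrates delta-delta-Ct against the named
#' calibrator sample, and categorizes every sample. The calibrator
#' always self-calls at exactly `calibrator_cn`.
#'
#' @param plate a `QpcrPlate` data.frame.
#' @param calibrator_id sample id of the calibrator; defaults to the
#'   plate's `calibrator_id` attribute when present.
#' @param calibrator_cn calibrator copy number; defaults to the plate's
#'   `calibrator_cn` attribute, else 2.
#' @param outlier_ct replicate rejection radius in cycles (default 0.5).
#' @return Data.frame with columns `sample_id`, `mean_dct`, `sd_dct`,
#'   `n_used`, `cn_estimate`, `cn_integer`, `category`, `low_confidence`.
#' @export
call_copy_numbers <- function(plate,
                              calibrator_id = attr(plate, "calibrator_id"),
                              calibrator_cn = attr(plate, "calibrator_cn"),
                              outlier_ct = 0.5) {
  if (is.null(calibrator_id)) abort("no calibrator sample specified")
  if (is.null(calibrator_cn)) calibrator_cn <- 2L
  agg <- aggregate_replicates(plate, outlier_ct)
  cal <- agg[agg$sample_id == calibrator_id, , drop = FALSE]
  if (nrow(cal) == 0L) abort("calibrator '%s' not on plate", calibrator_id)
  if (cal$all_dropped) abort("calibrator '%s' has no usable wells",
                             calibrator_id)
  est <- estimate_copy_number(agg$mean_dct, cal$mean_dct, calibrator_cn)
  cat <- categorize_copy_number(ifelse(is.na(est), 0, est))
  out <- cbind(agg[, c("sample_id", "mean_dct", "sd_dct", "n_used")],
               cat)
  out$cn_estimate[agg$all_dropped] <- NA_real_
  out$cn_integer[agg$all_dropped] <- NA_integer_
  out$category[agg$all_dropped] <- NA_character_
  out$low_confidence[agg$all_dropped] <- TRUE
  rownames(out) <- NULL
  out
}
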