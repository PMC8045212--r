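#' Merge per-sample CNV calls into copy-number-variable regions
#'
#' CNVRs are the connected components of the interval-overlap graph over
#' all calls on a chromosome (transitive union; two closed 1-based
#' intervals overlap iff they share at least one bp). A region supported
#' by two or more distinct samples is `shared`; its `trend` is `gain` or
#' `loss` when all contributing calls agree in direction, `inconsistent`
#' otherwise. Singleton calls are retained as unshared regions.
#'
#' With `split_mode = TRUE` each merged component is further partitioned
#' at every distinct contributing call boundary, and each sub-region
#' inherits only the calls covering it; the sub-regions tile the
#' component exactly. This mirrors map constructions in which long merged
#' fragments are split at internal breakpoints.
#'
#' @param calls call data.frame (columns `sample_id`, `chrom`, `start`,
#'   `end`, `direction`; as from [call_cnvs()]).
#' @param split_mode partition merged regions at call boundaries
#'   (default `FALSE`: plain union merge).
#' @param include_sex keep sex-chromosome calls (default `FALSE`:
#'   autosomes only, the usual convention for small cohorts where sex
#'   chromosome dosage differences dominate).
#' @return Data.frame of CNVRs with columns `cnvr_id`, `chrom`, `start`,
#'   `end`, `length`, `n_calls`, `sample_count`, `n_gain_calls`,
#'   `n_loss_calls`, `shared`, `trend`, plus a list-column `members`
#'   holding the row indices of the contributing calls in `calls`.
#'   Sorted by chromosome then start; regions on one chromosome are
#'   pairwise non-overlapping.
#' @export
build_cnvrs <- function(calls, split_mode = FALSE, include_sex = FALSE) {
  if (NROW(calls) > 0 && any(calls$end < calls$start)) {
    abort("call with end < start")
  }
  calls$.row <- seq_len(NROW(calls))
  if (!include_sex && NROW(calls) > 0) {
    calls <- calls[is_autosome(calls$chrom), , drop = FALSE]
  }
  if (NROW(calls) == 0L) return(empty_cnvrs())

  regions <- list()
  for (chrom in unique(calls$chrom)) {
    sub <- calls[calls$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    # sweep: a new component starts when the next interval begins after
    # the furthest end seen so far
    comp <- integer(nrow(sub))
    comp[1] <- 1L
    hi <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      comp[i] <- comp[i - 1] + (sub$start[i] > hi)
      hi <- max(hi, sub$end[i])
    }
    for (k in unique(comp)) {
      block <- sub[comp == k, , drop = FALSE]
      if (!split_mode) {
        regions[[length(regions) + 1L]] <-
          cnvr_row(chrom, min(block$start), max(block$end), block)
      } else {
        regions <- c(regions, split_component(chrom, block))
      }
    }
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$cnvr_id <- sprintf("cnvr_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cnvr_id", "chrom", "start", "end", "length", "n_calls",
          "sample_count", "n_gain_calls", "n_loss_calls", "shared",
          "trend", "members")]
}

empty_cnvrs <- function() {
  data.frame(cnvr_id = character(), chrom = character(), start = integer(),
             end = integer(), length = integer(), n_calls = integer(),
             sample_count = integer(), n_gain_calls = integer(),
             n_loss_calls = integer(), shared = logical(),
             trend = character(), members = I(list()),
             stringsAsFactors = FALSE)
}

# Internal: one CNVR row from the calls it contains
cnvr_row <- function(chrom, start, end, block) {
  n_gain <- sum(block$direction == "gain")
  n_loss <- sum(block$direction == "loss")
  trend <- if (n_loss == 0L && n_gain > 0L) "gain"
           else if (n_gain == 0L && n_loss > 0L) "loss"
           else "inconsistent"
  data.frame(chrom = chrom, start = start, end = end,
             length = end - start + 1, n_calls = nrow(block),
             sample_count = length(unique(block$sample_id)),
             n_gain_calls = n_gain, n_loss_calls = n_loss,
             shared = length(unique(block$sample_id)) >= 2L,
             trend = trend, members = I(list(block$.row)),
             stringsAsFactors = FALSE)
}

# Internal: partition one merged component at call boundaries.
# Breakpoints are every distinct start and end+1; consecutive breakpoint
# pairs [b, b'-1] are the sub-regions, each inheriting covering calls.
split_component <- function(chrom, block) {
  bp <- sort(unique(c(block$start, block$end + 1L)))
  out <- list()
  for (i in seq_len(length(bp) - 1L)) {
    s <- bp[i]; e <- bp[i + 1L] - 1L
    covering <- block[block$start <= s & block$end >= e, , drop = FALSE]
    if (nrow(covering) == 0L) next  # cannot happen for a connected block
    out[[length(out) + 1L]] <- cnvr_row(chrom, s, e, covering)
  }
  out
}

#' Per-chromosome CNVR distribution summary
#'
#' One row per chromosome that carries at least one CNVR: counts, length
#' range, mean length (kb), total length (Mb), percentage of the
#' chromosome covered, and (when gene models are supplied) the number of
#' distinct genes overlapped.
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param gene_models optional gene-model data.frame from
#'   [read_gene_models()].
#' @return Data.frame with columns `chrom`, `n_cnvrs`, `min_length`,
#'   `max_length`, `mean_length_kb`, `total_length_mb`, `pct_chrom`
#'   (0-100 scale, rounded half-up to 2 decimals), `n_genes` (`NA` when
#'   no gene models given).
#' @export
summarize_chromosomes <- function(cnvrs, chrom_sizes, gene_models = NULL) {
  unknown <- setdiff(unique(cnvrs$chrom), names(chrom_sizes))
  if (length(unknown)) {
    abort("chromosome not in chrom_sizes: %s", paste(unknown, collapse = ", "))
  }
  if (nrow(cnvrs) == 0L) {
    return(data.frame(chrom = character(), n_cnvrs = integer(),
                      min_length = integer(), max_length = integer(),
                      mean_length_kb = numeric(), total_length_mb = numeric(),
                      pct_chrom = numeric(), n_genes = integer()))
  }
  ann <- if (!is.null(gene_models)) annotate_cnvrs(cnvrs, gene_models)
  rows <- lapply(unique(cnvrs$chrom), function(chrom) {
    sub <- cnvrs[cnvrs$chrom == chrom, , drop = FALSE]
    total <- sum(sub$length)
    n_genes <- if (is.null(ann)) NA_integer_ else {
      length(unique(unlist(ann$genes[ann$chrom == chrom])))
    }
    data.frame(chrom = chrom, n_cnvrs = nrow(sub),
               min_length = min(sub$length), max_length = max(sub$length),
               mean_length_kb = mean(sub$length) / 1e3,
               total_length_mb = total / 1e6,
               pct_chrom = round_half_up(100 * total / chrom_sizes[[chrom]], 2),
               n_genes = n_genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide CNVR map summary
#'
#' Region counts split by trend consistency, mean and total CNVR length,
#' the percentage of the autosomal genome covered, and the gain:loss
#' ratio counted over the contributing calls (not over regions).
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param chrom_sizes named vector of chromosome lengths in bp; the
#'   coverage denominator is the sum of the autosomal entries.
#' @param calls the call data.frame the map was built from (used for the
#'   gain:loss call ratio).
#' @return A list: `n_cnvrs`, `n_consistent`, `n_gain_trend`,
#'   `n_loss_trend`, `n_inconsistent`, `n_shared`, `mean_length_kb`,
#'   `total_length_mb`, `pct_genome`, `n_gain_calls`, `n_loss_calls`,
#'   `gain_loss_ratio` (`Inf` with label `"gains only"` when there are no
#'   loss calls), `gain_loss_label` (e.g. `"1.7:1"`).
#' @export
genome_summary <- function(cnvrs, chrom_sizes, calls = NULL) {
  autosome_bp <- sum(chrom_sizes[is_autosome(names(chrom_sizes))])
  if (nrow(cnvrs) == 0L) {
    return(list(n_cnvrs = 0L, n_consistent = 0L, n_gain_trend = 0L,
                n_loss_trend = 0L, n_inconsistent = 0L, n_shared = 0L,
                mean_length_kb = 0, total_length_mb = 0, pct_genome = 0,
                n_gain_calls = 0L, n_loss_calls = 0L,
                gain_loss_ratio = NA_real_, gain_loss_label = "no calls"))
  }
  total <- sum(cnvrs$length)
  n_gain_calls <- if (is.null(calls)) sum(cnvrs$n_gain_calls)
                  else sum(calls$direction == "gain")
  n_loss_calls <- if (is.null(calls)) sum(cnvrs$n_loss_calls)
                  else sum(calls$direction == "loss")
  ratio <- if (n_loss_calls == 0L && n_gain_calls == 0L) NA_real_
           else if (n_loss_calls == 0L) Inf
           else n_gain_calls / n_loss_calls
  label <- if (is.na(ratio)) "no calls"
           else if (is.infinite(ratio)) "gains only"
           else sprintf("%s:1", format(round_half_up(ratio, 1)))
  list(n_cnvrs = nrow(cnvrs),
       n_consistent = sum(cnvrs$trend != "inconsistent"),
       n_gain_trend = sum(cnvrs$trend == "gain"),
       n_loss_trend = sum(cnvrs$trend == "loss"),
       n_inconsistent = sum(cnvrs$trend == "inconsistent"),
       n_shared = sum(cnvrs$shared),
       mean_length_kb = mean(cnvrs$length) / 1e3,
       total_length_mb = total / 1e6,
       pct_genome = 100 * total / autosome_bp,
       n_gain_calls = n_gain_calls, n_loss_calls = n_loss_calls,
       gain_loss_ratio = ratio, gain_loss_label = label)
}

#' Write a CNVR map to TSV (and optionally BED)
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()].
#' @param path output TSV path (the `members` list-column is dropped).
#' @param bed_path optional BED path (0-based half-open, name =
#'   `cnvr_id:trend`).
#' @return `path`, invisibly.
#' @export
write_cnvr_map <- function(cnvrs, path, bed_path = NULL) {
  flat <- cnvrs[, setdiff(names(cnvrs), "members"), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = cnvrs$chrom, start = cnvrs$start - 1L,
                      end = cnvrs$end,
                      name = paste0(cnvrs$cnvr_id, ":", cnvrs$trend))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
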