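#' Reciprocal overlap (Jaccard) of two closed intervals
#'
#' Intersection length over union length, both in bp on 1-based
#' inclusive coordinates; 0 when the intervals do not overlap.
#'
#' @param start_a,end_a,start_b,end_b interval bounds (vectorized).
#' @return Numeric Jaccard fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(start_a, end_a, start_b, end_b) {
  inter <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b) + 1)
  un <- (end_a - start_a + 1) + (end_b - start_b + 1) - inter
  inter / un
}

#' Planted-event recovery benchmark for the run-length caller
#'
#' Simulates a matched case/control aCGH cohort with planted deletions
#' (log2 shift -1.0) and duplications (+0.58) whose boundaries are
#' aligned to probes, runs the caller at its defaults, and scores each
#' planted event as recovered when a same-sample, same-direction call
#' reaches the given reciprocal-overlap threshold. Also counts calls on
#' a noiseless null array (which must be zero at the default
#' thresholds).
#'
#' @param seed integer seed.
#' @param n_pairs case/control pairs (default 12).
#' @param chromosomes hg19 chromosomes to simulate (default six
#'   mid-sized ones, about 470 Mb).
#' @param mean_spacing probe spacing in bp (default 13000).
#' @param noise_sd log2 noise sd (default 0.15).
#' @param events_per_chrom planted event windows per chromosome
#'   (default 5).
#' @param event_probes range of probes per planted window (default
#'   8 to 10).
#' @param min_overlap reciprocal-overlap threshold counting as recovery
#'   (default 0.8).
#' @param params caller parameters (default [caller_params()]).
#' @return A list: `recovery_rate`, `n_planted`, `n_recovered`,
#'   `recovery_by_direction`, `null_calls` (call count on the noiseless
#'   null array), `n_calls`.
#' @export
evaluate_caller_recovery <- function(seed, n_pairs = 12,
                                     chromosomes = c("chr15", "chr16",
                                                     "chr17", "chr18",
                                                     "chr19", "chr20"),
                                     mean_spacing = 13000,
                                     noise_sd = 0.15,
                                     events_per_chrom = 5,
                                     event_probes = c(8, 10),
                                     min_overlap = 0.8,
                                     params = caller_params()) {
  seed <- check_seed(seed)
  chrom_sizes <- read_chrom_sizes(hg19_chrom_sizes_path())[chromosomes]
  pm <- make_probe_map(chrom_sizes, mean_spacing,
                       seed = derive_seed(seed, 101))

  # probe-aligned event windows, evenly spread along each chromosome,
  # alternating loss (-1.0) and gain (+0.58)
  spec <- list()
  flip <- TRUE
  sizes <- withr::with_seed(derive_seed(seed, 102), {
    sample(seq(event_probes[1], event_probes[2]),
           events_per_chrom * length(chromosomes), replace = TRUE)
  })
  for (ci in seq_along(chromosomes)) {
    chrom <- chromosomes[ci]
    pos <- pm$pos[pm$chrom == chrom]
    anchors <- floor(seq(100, length(pos) - 20,
                         length.out = events_per_chrom))
    for (ei in seq_along(anchors)) {
      k <- sizes[(ci - 1) * events_per_chrom + ei]
      i <- anchors[ei]
      spec[[length(spec) + 1L]] <- data.frame(
        chrom = chrom, start = pos[i], end = pos[i + k - 1],
        direction = if (flip) "loss" else "gain",
        shift = if (flip) -1.0 else 0.58,
        freq_case = 0.5, freq_control = 0.25)
      flip <- !flip
    }
  }
  spec <- do.call(rbind, spec)

  sim <- simulate_case_control_arrays(pm, n_pairs = n_pairs,
                                      event_spec = spec,
                                      noise_sd = noise_sd,
                                      seed = derive_seed(seed, 103))
  calls <- do.call(rbind, lapply(sim$arrays, call_cnvs, params = params))
  truth <- sim$truth

  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- calls[calls$sample_id == truth$sample_id[i] &
                    calls$chrom == truth$chrom[i] &
                    calls$direction == truth$direction[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    jac <- reciprocal_overlap(truth$start[i], truth$end[i],
                              cand$start, cand$end)
    recovered[i] <- any(jac >= min_overlap)
  }

  null_array <- simulate_sample_array(pm, NULL, noise_sd = 0,
                                      seed = derive_seed(seed, 104),
                                      sample_id = "null")
  null_calls <- nrow(call_cnvs(null_array, params))

  list(recovery_rate = mean(recovered), n_planted = nrow(truth),
       n_recovered = sum(recovered),
       recovery_by_direction = tapply(recovered, truth$direction, mean),
       null_calls = null_calls, n_calls = nrow(calls))
}

#' Category-recovery benchmark for the qPCR copy-number caller
#'
#' Simulates quadruplicate plates for samples with known copy numbers
#' 1, 2 and 3, runs the full delta-delta-Ct workflow, and reports the
#' fraction of samples categorized correctly (loss / normal / gain) and
#' whether the calibrator self-called at its known copy number.
#'
#' @param seed integer seed.
#' @param n_per_cn samples per true copy number (default 200).
#' @param replicates wells per sample (default 4).
#' @param ct_noise_sd per-well Ct noise sd in cycles (default 0.1).
#' @return A list: `accuracy`, `accuracy_by_cn`, `n_samples`,
#'   `calibrator_ok`, `calibrator_estimate`.
#' @export
evaluate_qpcr_recovery <- function(seed, n_per_cn = 200, replicates = 4,
                                   ct_noise_sd = 0.1) {
  seed <- check_seed(seed)
  true_cn <- stats::setNames(
    rep(c(1L, 2L, 3L), each = n_per_cn),
    sprintf("S%04d", seq_len(3 * n_per_cn)))
  true_cn <- c(CAL = 2L, true_cn)
  plate <- simulate_qpcr_plate(true_cn, calibrator_id = "CAL",
                               calibrator_cn = 2,
                               replicates = replicates,
                               ct_noise_sd = ct_noise_sd, seed = seed)
  res <- call_copy_numbers(plate)
  res <- res[match(names(true_cn), res$sample_id), ]
  truth_cat <- ifelse(true_cn < 2, "loss",
                      ifelse(true_cn == 2, "normal", "gain"))
  test_idx <- res$sample_id != "CAL"
  correct <- res$category[test_idx] == truth_cat[test_idx]
  cal <- res[res$sample_id == "CAL", ]
  list(accuracy = mean(correct),
       accuracy_by_cn = tapply(correct, true_cn[test_idx], mean),
       n_samples = sum(test_idx),
       calibrator_ok = cal$cn_estimate == 2,
       calibrator_estimate = cal$cn_estimate)
}

#' Parameter-recovery benchmark for the adjusted logistic model
#'
#' Repeatedly simulates case/control cohorts in which the deletion
#' carrier frequencies imply a known exposure odds ratio (carrier status
#' independent of the covariates within groups, so the covariate-adjusted
#' odds ratio equals the marginal one), fits the covariate-adjusted
#' logistic model, and summarizes estimate bias and Wald 95% CI
#' coverage.
#'
#' @param seed integer seed.
#' @param n_replicates simulated cohorts (default 500).
#' @param n_cases,n_controls group sizes (defaults 297 / 260).
#' @param freq_cases,freq_controls carrier frequencies; the defaults
#'   (0.5 and 0.2) give carrier odds of 1 vs 1/4, i.e. a true odds ratio
#'   of exactly 4, in a regime with no sparse cells so the Wald
#'   machinery being checked is applicable.
#' @param covariates adjustment columns (default the full set).
#' @return A list: `true_or`, `mean_or`, `mean_log_or`, `ci_coverage`,
#'   `n_replicates`, `n_used`, `n_covariate_separated`.
#' @export
evaluate_logistic_recovery <- function(seed, n_replicates = 500,
                                       n_cases = 297, n_controls = 260,
                                       freq_cases = 0.5,
                                       freq_controls = 0.2,
                                       covariates = c("gender", "age",
                                                      "bmi_class",
                                                      "bp_class",
                                                      "diabetes")) {
  seed <- check_seed(seed)
  odds <- function(p) p / (1 - p)
  true_or <- odds(freq_cases) / odds(freq_controls)
  ors <- covered <- rep(NA_real_, n_replicates)
  cov_sep <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- simulate_cohort_table(
      n_cases, n_controls, freq_cases, freq_controls,
      seed = derive_seed(seed, 200 + r))
    fit <- fit_logistic_regression(cohort, "status", "carrier",
                                   covariates)
    cov_sep[r] <- fit$separation
    if (!is.null(fit$exposure_or)) {
      ors[r] <- fit$exposure_or$or
      covered[r] <- fit$exposure_or$ci_low <= true_or &
        true_or <= fit$exposure_or$ci_high
    }
  }
  # score the exposure term; a sparse covariate cell that separates does
  # not invalidate it
  ok <- !is.na(ors) & is.finite(ors) & abs(log(ors)) < 15
  list(true_or = true_or, mean_or = mean(ors[ok]),
       mean_log_or = mean(log(ors[ok])),
       ci_coverage = mean(covered[ok]),
       n_replicates = n_replicates, n_used = sum(ok),
       n_covariate_separated = sum(cov_sep))
}
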