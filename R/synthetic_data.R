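#' Simulated inputs for the CNV pipeline
#'
#' @description
#' The functions documented here generate every input the pipeline
#' consumes -- probe grids, case/control aCGH cohorts with planted
#' copy-number events, qPCR plates, and cohort covariate tables -- with
#' known ground truth. All randomness flows from a single integer `seed`
#' argument per call, so generated data are bit-reproducible.
#'
#' @name synthetic-data
NULL

#' Generate a jittered probe map for a genome
#'
#' Emits `floor(length / mean_spacing)` probes per chromosome at
#' irregular positions: inter-probe gaps are drawn from an exponential
#' distribution with mean `mean_spacing` and rescaled to span the
#' chromosome, approximating the non-uniform probe placement of a
#' commercial aCGH design (a 180k-probe human array has a mean probe
#' spacing of about 13 kb).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param mean_spacing target mean inter-probe distance in bp
#'   (default 13000).
#' @param seed integer seed; identical arguments give identical maps.
#' @return A `probe_map`: data.frame with columns `chrom` (character) and
#'   `pos` (integer, 1-based, strictly increasing within a chromosome),
#'   carrying `chrom_sizes` as an attribute.
#' @examples
#' pm <- make_probe_map(c(chrTest = 130000), mean_spacing = 13000, seed = 1)
#' nrow(pm)  # 10 probes
#' @export
make_probe_map <- function(chrom_sizes, mean_spacing = 13000, seed) {
  if (length(chrom_sizes) == 0L) abort("no chromosomes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("'chrom_sizes' must be a named vector")
  }
  if (any(chrom_sizes <= 0)) abort("chromosome lengths must be positive")
  if (mean_spacing <= 0) abort("'mean_spacing' must be positive")
  seed <- check_seed(seed)

  pieces <- withr::with_seed(seed, {
    lapply(names(chrom_sizes), function(chrom) {
      len <- chrom_sizes[[chrom]]
      n <- floor(len / mean_spacing)
      if (n == 0L) {
        return(data.frame(chrom = character(), pos = integer()))
      }
      gaps <- stats::rexp(n, rate = 1 / mean_spacing)
      raw <- cumsum(gaps)
      # rescale so the last probe sits at the chromosome end
      pos <- floor(raw / raw[n] * (len - 1)) + 1
      # enforce strict monotonicity after integer rounding
      pos <- force_strictly_increasing(pos, len)
      data.frame(chrom = chrom, pos = as.integer(pos),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "chrom_sizes") <- chrom_sizes
  class(out) <- c("probe_map", "data.frame")
  out
}

# Internal: bump duplicated integer positions upward; positions stay <= cap
force_strictly_increasing <- function(pos, cap) {
  for (i in seq_along(pos)[-1]) {
    if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  }
  if (pos[length(pos)] > cap) {
    # extremely dense request: walk back down from the cap
    pos <- pmin(pos, cap - (length(pos) - seq_along(pos)))
    if (any(diff(pos) <= 0) || pos[1] < 1) {
      abort("cannot place %d distinct probes on a chromosome of %d bp",
            length(pos), cap)
    }
  }
  pos
}

#' Simulate one sample's log2-ratio track
#'
#' Probes inside a planted event get mean log2 ratio equal to the event's
#' `shift`; probes elsewhere get mean 0. I.i.d. Gaussian noise with
#' standard deviation `noise_sd` is added on top.
#'
#' @param probe_map a `probe_map` from [make_probe_map()].
#' @param planted data.frame of planted events for this sample, with
#'   columns `chrom`, `start`, `end` (1-based inclusive bp), `direction`
#'   (`"gain"`/`"loss"`) and `shift` (expected log2 ratio inside the
#'   event). May have zero rows.
#' @param noise_sd non-negative Gaussian noise sd on the log2 scale.
#' @param seed integer seed.
#' @param sample_id sample identifier stored in the output.
#' @return A `SampleArray`: data.frame with columns `sample_id`, `chrom`,
#'   `position`, `log2_ratio`.
#' @export
simulate_sample_array <- function(probe_map, planted = NULL, noise_sd = 0.15,
                                  seed, sample_id = "S1") {
  if (noise_sd < 0) abort("'noise_sd' must be >= 0")
  seed <- check_seed(seed)
  planted <- validate_planted(planted, probe_map)

  mu <- numeric(nrow(probe_map))
  if (nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      hit <- probe_map$chrom == planted$chrom[i] &
        probe_map$pos >= planted$start[i] & probe_map$pos <= planted$end[i]
      mu[hit] <- planted$shift[i]
    }
  }
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(nrow(probe_map), sd = noise_sd))
  } else {
    numeric(nrow(probe_map))
  }
  data.frame(sample_id = sample_id, chrom = probe_map$chrom,
             position = probe_map$pos, log2_ratio = mu + noise,
             stringsAsFactors = FALSE)
}

# Internal: normalise/validate a planted-event table against a probe map
validate_planted <- function(planted, probe_map) {
  if (is.null(planted) || NROW(planted) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      shift = numeric()))
  }
  need <- c("chrom", "start", "end", "direction", "shift")
  missing <- setdiff(need, names(planted))
  if (length(missing)) abort("planted events lack column(s): %s",
                             paste(missing, collapse = ", "))
  if (any(planted$end < planted$start)) abort("planted event has end < start")
  bad_dir <- !(planted$direction %in% c("gain", "loss"))
  if (any(bad_dir)) abort("planted direction must be 'gain' or 'loss'")
  if (any(planted$direction == "gain" & planted$shift <= 0) ||
      any(planted$direction == "loss" & planted$shift >= 0)) {
    abort("planted shift sign must match its direction")
  }
  unknown <- setdiff(unique(planted$chrom), unique(probe_map$chrom))
  if (length(unknown)) {
    abort("planted event on chromosome absent from probe map: %s",
          paste(unknown, collapse = ", "))
  }
  sizes <- attr(probe_map, "chrom_sizes")
  if (!is.null(sizes)) {
    over <- planted$end > sizes[planted$chrom] | planted$start < 1
    if (any(over)) abort("planted event outside chromosome bounds")
  }
  planted
}

#' Simulate a case/control aCGH cohort with planted CNVs
#'
#' For each region in `event_spec`, every case carries the event with
#' probability `freq_case` and every control with probability
#' `freq_control`. Carrier arrays receive the region's log2 `shift`;
#' all arrays receive i.i.d. Gaussian noise. The matched-pair design of
#' a small discovery cohort (12 patients, 12 matched controls) is the
#' default shape.
#'
#' @param probe_map a `probe_map`.
#' @param n_pairs number of case/control pairs (default 12).
#' @param event_spec data.frame with columns `chrom`, `start`, `end`,
#'   `direction`, `shift`, `freq_case`, `freq_control`. Regions on the
#'   same chromosome must not overlap, so per-sample planted events never
#'   overlap each other.
#' @param noise_sd Gaussian noise sd on log2 ratios (default 0.15).
#' @param seed integer seed.
#' @return A list with `arrays` (one `SampleArray` data.frame per subject,
#'   named `case_01`..., `ctrl_01`...) and `truth` (data.frame of planted
#'   events: `sample_id`, `chrom`, `start`, `end`, `direction`, `shift`,
#'   `group`).
#' @export
simulate_case_control_arrays <- function(probe_map, n_pairs = 12,
                                         event_spec, noise_sd = 0.15, seed) {
  if (n_pairs < 1) abort("'n_pairs' must be >= 1")
  seed <- check_seed(seed)
  need <- c("chrom", "start", "end", "direction", "shift",
            "freq_case", "freq_control")
  missing <- setdiff(need, names(event_spec))
  if (length(missing)) abort("event_spec lacks column(s): %s",
                             paste(missing, collapse = ", "))
  freqs <- c(event_spec$freq_case, event_spec$freq_control)
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must lie in [0, 1]")
  check_nonoverlapping(event_spec, "event_spec regions")

  ids <- c(sprintf("case_%02d", seq_len(n_pairs)),
           sprintf("ctrl_%02d", seq_len(n_pairs)))
  groups <- rep(c("case", "control"), each = n_pairs)

  # carrier draws first, then per-sample array noise, all from one seed
  carriers <- withr::with_seed(seed, {
    lapply(seq_len(nrow(event_spec)), function(i) {
      p <- ifelse(groups == "case",
                  event_spec$freq_case[i], event_spec$freq_control[i])
      stats::runif(length(ids)) < p
    })
  })

  truth_rows <- list()
  arrays <- vector("list", length(ids))
  names(arrays) <- ids
  for (s in seq_along(ids)) {
    carried <- vapply(carriers, `[`, logical(1), s)
    planted <- event_spec[carried, c("chrom", "start", "end",
                                     "direction", "shift"), drop = FALSE]
    arrays[[s]] <- simulate_sample_array(
      probe_map, planted, noise_sd,
      seed = derive_seed(seed, s), sample_id = ids[s])
    if (nrow(planted) > 0L) {
      planted$sample_id <- ids[s]
      planted$group <- groups[s]
      truth_rows[[length(truth_rows) + 1L]] <- planted
    }
  }
  truth <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows)
    rownames(out) <- NULL
    out[, c("sample_id", "chrom", "start", "end", "direction",
            "shift", "group")]
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), direction = character(),
               shift = numeric(), group = character())
  }
  list(arrays = arrays, truth = truth)
}

# Internal: error if intervals in a table overlap within a chromosome
check_nonoverlapping <- function(tab, what) {
  for (chrom in unique(tab$chrom)) {
    sub <- tab[tab$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      abort("%s overlap on %s; planted events must be disjoint", what, chrom)
    }
  }
  invisible(tab)
}

#' Simulate a TaqMan qPCR plate with replicate wells
#'
#' Target-assay Ct values are generated so that a sample's expected
#' delta-delta-Ct relative to the calibrator equals
#' `-log2(true_cn / calibrator_cn)`; the reference assay is centred on a
#' fixed 25-cycle constant (only Ct differences carry information).
#' Both wells of a replicate receive independent Gaussian Ct noise.
#'
#' @param true_cn named integer vector: true copy number per sample
#'   (all values >= 1). Must include `calibrator_id`.
#' @param calibrator_id sample to be used as calibrator (default the
#'   first sample).
#' @param calibrator_cn known copy number of the calibrator (default 2).
#' @param replicates wells per sample (default 4, i.e. quadruplicate).
#' @param ct_noise_sd Gaussian sd of each well's Ct, cycles (default 0.1).
#' @param seed integer seed.
#' @return A `QpcrPlate`: data.frame with columns `sample_id`, `well`,
#'   `target_ct`, `reference_ct`; the calibrator id and copy number are
#'   stored as attributes `calibrator_id` / `calibrator_cn`.
#' @export
simulate_qpcr_plate <- function(true_cn, calibrator_id = names(true_cn)[1],
                                calibrator_cn = 2, replicates = 4,
                                ct_noise_sd = 0.1, seed) {
  if (calibrator_cn <= 0) abort("'calibrator_cn' must be a positive integer")
  if (is.null(names(true_cn)) || any(!nzchar(names(true_cn)))) {
    abort("'true_cn' must be a named vector")
  }
  if (any(true_cn < 1)) abort("true copy numbers must be >= 1")
  if (replicates < 1) abort("'replicates' must be >= 1")
  if (!calibrator_id %in% names(true_cn)) {
    abort("calibrator '%s' missing from 'true_cn'", calibrator_id)
  }
  seed <- check_seed(seed)

  ref_ct <- 25.0          # fixed reference-assay centre, cycles
  calibrator_dct <- 1.0   # arbitrary fixed target-vs-reference offset

  n <- length(true_cn) * replicates
  ids <- rep(names(true_cn), each = replicates)
  # expected delta-Ct per sample: calibrator offset + ddCt
  ddct <- -log2(true_cn / calibrator_cn)
  mu_dct <- rep(calibrator_dct + ddct, each = replicates)

  withr::with_seed(seed, {
    target <- ref_ct + mu_dct + stats::rnorm(n, sd = ct_noise_sd)
    reference <- ref_ct + stats::rnorm(n, sd = ct_noise_sd)
  })
  plate <- data.frame(sample_id = ids,
                      well = rep(seq_len(replicates), length(true_cn)),
                      target_ct = target, reference_ct = reference,
                      stringsAsFactors = FALSE)
  attr(plate, "calibrator_id") <- calibrator_id
  attr(plate, "calibrator_cn") <- as.integer(calibrator_cn)
  plate
}

#' Default covariate marginals for the simulated validation cohort
#'
#' Per-group marginal distributions of gender, age, BMI class, blood
#' pressure class and diabetes history, matching the baseline profile of
#' a large fatty-liver case/control validation cohort (about 70% male,
#' mean age 45.5, cases strongly shifted toward higher BMI and blood
#' pressure).
#'
#' @return A list with components `case` and `control`, each holding
#'   `p_male`, `age_mean`, `age_sd`, `bmi_probs` (classes `<18.5`,
#'   `18.5-23.9`, `24.0-27.9`, `>=28`), `p_bp_high` and `p_diabetes`.
#' @export
default_covariate_spec <- function() {
  list(
    case = list(p_male = 209 / 297, age_mean = 45.66, age_sd = 11.76,
                bmi_probs = c(2, 99, 149, 47) / 297,
                p_bp_high = 86 / 297, p_diabetes = 12 / 297),
    control = list(p_male = 185 / 260, age_mean = 45.48, age_sd = 11.80,
                   bmi_probs = c(9, 193, 57, 1) / 260,
                   p_bp_high = 49 / 260, p_diabetes = 7 / 260)
  )
}

#' Simulate a case/control cohort covariate table
#'
#' Each subject gets a binary deletion-carrier status drawn with the
#' group-specific frequency, plus gender, age, BMI class, blood-pressure
#' class and diabetes history drawn independently from the group's
#' marginals. Because carrier status is independent of the covariates
#' within each group, the true covariate-adjusted exposure odds ratio
#' equals the odds ratio implied by the two carrier frequencies.
#'
#' @param n_cases,n_controls group sizes (defaults 297 and 260, the shape
#'   of a large qPCR validation cohort).
#' @param deletion_freq_cases,deletion_freq_controls carrier probabilities
#'   (defaults 15/297 and 4/260).
#' @param covariate_spec marginals as from [default_covariate_spec()].
#' @param seed integer seed.
#' @return A `CohortTable`: data.frame with columns `subject_id`, `status`
#'   (factor control/case), `carrier` (factor `two_copies`/`one_copy`),
#'   `gender`, `age`, `bmi_class`, `bp_class`, `diabetes`.
#' @export
simulate_cohort_table <- function(n_cases = 297, n_controls = 260,
                                  deletion_freq_cases = 15 / 297,
                                  deletion_freq_controls = 4 / 260,
                                  covariate_spec = default_covariate_spec(),
                                  seed) {
  if (n_cases <= 0 || n_controls <= 0) abort("group sizes must be positive")
  freqs <- c(deletion_freq_cases, deletion_freq_controls)
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must lie in [0, 1]")
  seed <- check_seed(seed)

  bmi_levels <- c("<18.5", "18.5-23.9", "24.0-27.9", ">=28")
  draw_group <- function(n, prefix, spec, freq) {
    data.frame(
      subject_id = sprintf("%s_%03d", prefix, seq_len(n)),
      carrier = ifelse(stats::runif(n) < freq, "one_copy", "two_copies"),
      gender = ifelse(stats::runif(n) < spec$p_male, "male", "female"),
      age = stats::rnorm(n, spec$age_mean, spec$age_sd),
      bmi_class = sample(bmi_levels, n, replace = TRUE, prob = spec$bmi_probs),
      bp_class = ifelse(stats::runif(n) < spec$p_bp_high,
                        "high", "normal"),
      diabetes = ifelse(stats::runif(n) < spec$p_diabetes, "yes", "no"),
      stringsAsFactors = FALSE
    )
  }
  out <- withr::with_seed(seed, {
    cases <- draw_group(n_cases, "case", covariate_spec$case,
                        deletion_freq_cases)
    cases$status <- "case"
    controls <- draw_group(n_controls, "ctrl", covariate_spec$control,
                           deletion_freq_controls)
    controls$status <- "control"
    rbind(cases, controls)
  })
  out$status <- factor(out$status, levels = c("control", "case"))
  out$carrier <- factor(out$carrier, levels = c("two_copies", "one_copy"))
  out$bmi_class <- factor(out$bmi_class, levels = bmi_levels)
  out$bp_class <- factor(out$bp_class, levels = c("normal", "high"))
  out$diabetes <- factor(out$diabetes, levels = c("no", "yes"))
  out$gender <- factor(out$gender, levels = c("female", "male"))
  rownames(out) <- NULL
  out[, c("subject_id", "status", "carrier", "gender", "age",
          "bmi_class", "bp_class", "diabetes")]
}

#' Write a sample's log2-ratio track to TSV
#'
#' Columns: `sample_id`, `chrom`, `position`, `log2_ratio`, with a header
#' line. Read back with [read_sample_array()].
#'
#' @param array a `SampleArray` data.frame (or several row-bound together).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_array <- function(array, path) {
  utils::write.table(
    array[, c("sample_id", "chrom", "position", "log2_ratio")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a planted-event truth table as BED
#'
#' On disk BED is 0-based half-open, so `start` is decremented by one;
#' the `name` column holds `sample_id:direction`.
#'
#' @param truth truth data.frame from [simulate_case_control_arrays()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$chrom, start = truth$start - 1L,
                    end = truth$end,
                    name = paste0(truth$sample_id, ":", truth$direction))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a qPCR plate to TSV
#'
#' Columns: `sample_id`, `well`, `target_ct`, `reference_ct`.
#'
#' @param plate a `QpcrPlate` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.table(
    plate[, c("sample_id", "well", "target_ct", "reference_ct")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
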