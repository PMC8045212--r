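test_that("probe maps have the expected density, order and bounds", {
  pm <- make_probe_map(c(chrA = 130000), mean_spacing = 13000, seed = 1)
  expect_equal(nrow(pm), 10L)

  # exact oracle: per-chromosome count is floor(length / spacing)
  sizes <- c(chrA = 2.5e7, chrB = 1.3e7, chrC = 999999)
  pm <- make_probe_map(sizes, mean_spacing = 13000, seed = 3)
  counts <- table(factor(pm$chrom, names(sizes)))
  expect_equal(as.vector(counts), as.vector(floor(sizes / 13000)))

  for (chrom in names(sizes)) {
    pos <- pm$pos[pm$chrom == chrom]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 1 & pos <= sizes[[chrom]]))
  }
})

test_that("a 3 Gb genome at 13 kb spacing yields a 180k-array scale map", {
  sizes <- setNames(rep(1e8, 30), sprintf("chr%d", 1:30))
  pm <- make_probe_map(sizes, mean_spacing = 13000, seed = 9)
  expect_equal(nrow(pm), sum(floor(sizes / 13000)))
  expect_gte(nrow(pm), 180000)
  expect_lte(nrow(pm), 231000)
})

test_that("generators are deterministic and reject bad input", {
  expect_identical(make_probe_map(c(chrA = 1e6), 1e4, seed = 7),
                   make_probe_map(c(chrA = 1e6), 1e4, seed = 7))
  expect_error(make_probe_map(numeric(), 13000, seed = 1),
               "no chromosomes")
  expect_error(make_probe_map(c(chrA = -5), 13000, seed = 1), "positive")
  expect_error(make_probe_map(c(chrA = 1e6), 0, seed = 1), "positive")

  pm <- make_probe_map(c(chrA = 1e6), 1e4, seed = 2)
  expect_identical(simulate_sample_array(pm, NULL, 0.1, seed = 5),
                   simulate_sample_array(pm, NULL, 0.1, seed = 5))
})

test_that("planted events shift exactly the probes they cover", {
  pm <- make_probe_map(c(chrA = 1e6), 1e4, seed = 2)

  null_arr <- simulate_sample_array(pm, NULL, noise_sd = 0, seed = 1)
  expect_true(all(null_arr$log2_ratio == 0))
  expect_equal(nrow(null_arr), nrow(pm))  # probe conservation

  ev <- data.frame(chrom = "chrA", start = 200000, end = 400000,
                   direction = "loss", shift = -1.0)
  arr <- simulate_sample_array(pm, ev, noise_sd = 0, seed = 1)
  inside <- arr$position >= 200000 & arr$position <= 400000
  expect_true(all(arr$log2_ratio[inside] == -1.0))
  expect_true(all(arr$log2_ratio[!inside] == 0))
})

test_that("background noise has near-zero mean at simulated scale", {
  pm <- make_probe_map(c(chrA = 1e8), 1e4, seed = 4)  # 10,000 probes
  arr <- simulate_sample_array(pm, NULL, noise_sd = 0.15, seed = 11)
  expect_lt(abs(mean(arr$log2_ratio)), 3 * 0.15 / sqrt(10000))
})

test_that("invalid planted events are rejected", {
  pm <- make_probe_map(c(chrA = 1e6), 1e4, seed = 2)
  bad_chrom <- data.frame(chrom = "chrZ", start = 1, end = 10,
                          direction = "loss", shift = -1)
  expect_error(simulate_sample_array(pm, bad_chrom, 0, seed = 1),
               "absent from probe map")
  outside <- data.frame(chrom = "chrA", start = 1, end = 2e6,
                        direction = "loss", shift = -1)
  expect_error(simulate_sample_array(pm, outside, 0, seed = 1),
               "outside chromosome")
  wrong_sign <- data.frame(chrom = "chrA", start = 1, end = 10,
                           direction = "gain", shift = -1)
  expect_error(simulate_sample_array(pm, wrong_sign, 0, seed = 1), "sign")
})

test_that("carrier assignment follows the event frequencies", {
  pm <- make_probe_map(c(chrA = 1e6), 1e5, seed = 2)
  spec <- data.frame(chrom = "chrA", start = 2e5, end = 6e5,
                     direction = "loss", shift = -1,
                     freq_case = 1.0, freq_control = 0.0)
  sim <- simulate_case_control_arrays(pm, n_pairs = 3, event_spec = spec,
                                      noise_sd = 0, seed = 1)
  expect_equal(length(sim$arrays), 6L)
  expect_equal(sort(sim$truth$sample_id),
               c("case_01", "case_02", "case_03"))

  spec$freq_case <- 0
  empty <- simulate_case_control_arrays(pm, 3, spec, 0, seed = 1)
  expect_equal(nrow(empty$truth), 0L)

  spec$freq_case <- 2
  expect_error(simulate_case_control_arrays(pm, 3, spec, 0, seed = 1),
               "\\[0, 1\\]")
})

test_that("empirical carrier frequency calibrates over many seeds", {
  pm <- make_probe_map(c(chrA = 1e6), 1e5, seed = 2)
  spec <- data.frame(chrom = "chrA", start = 2e5, end = 6e5,
                     direction = "loss", shift = -1,
                     freq_case = 0.5, freq_control = 0.0)
  n_seeds <- 200
  carriers <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_case_control_arrays(pm, 12, spec, 0, seed = s)
    sum(grepl("^case", sim$truth$sample_id))
  }, numeric(1))
  se_mean <- sqrt(12 * 0.5 * 0.5) / sqrt(n_seeds)
  expect_lt(abs(mean(carriers) - 6), 3 * se_mean)
})

test_that("overlapping planted regions are refused", {
  pm <- make_probe_map(c(chrA = 1e6), 1e5, seed = 2)
  spec <- data.frame(chrom = "chrA", start = c(1e5, 2e5),
                     end = c(3e5, 4e5), direction = "loss", shift = -1,
                     freq_case = 1, freq_control = 0)
  expect_error(simulate_case_control_arrays(pm, 2, spec, 0, seed = 1),
               "disjoint")
})

test_that("noiseless qPCR plates encode exact delta-delta-Ct dosages", {
  cn <- c(CAL = 2L, A = 2L, B = 1L, C = 4L)
  plate <- simulate_qpcr_plate(cn, calibrator_id = "CAL",
                               ct_noise_sd = 0, seed = 1)
  dct <- tapply(plate$target_ct - plate$reference_ct, plate$sample_id,
                mean)
  expect_equal(unname(dct["A"] - dct["CAL"]), 0)
  expect_equal(unname(dct["B"] - dct["CAL"]), 1)   # -log2(1/2)
  expect_equal(unname(dct["C"] - dct["CAL"]), -1)  # -log2(4/2)

  expect_error(simulate_qpcr_plate(cn, calibrator_cn = 0, seed = 1),
               "positive")
  expect_error(simulate_qpcr_plate(c(CAL = 2, X = 0), seed = 1), ">= 1")
  expect_identical(simulate_qpcr_plate(cn, seed = 3),
                   simulate_qpcr_plate(cn, seed = 3))
})

test_that("cohort tables honour carrier frequencies and group sizes", {
  co <- simulate_cohort_table(20, 10, 1.0, 0.0, seed = 1)
  expect_equal(nrow(co), 30L)
  expect_true(all(co$carrier[co$status == "case"] == "one_copy"))
  expect_true(all(co$carrier[co$status == "control"] == "two_copies"))
  expect_error(simulate_cohort_table(0, 10, 0.1, 0.1, seed = 1),
               "positive")
  expect_identical(simulate_cohort_table(50, 50, 0.2, 0.1, seed = 4),
                   simulate_cohort_table(50, 50, 0.2, 0.1, seed = 4))
})

test_that("default cohort carrier counts calibrate to 15 and 4", {
  n_seeds <- 500
  counts <- vapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort_table(seed = s)
    c(sum(co$status == "case" & co$carrier == "one_copy"),
      sum(co$status == "control" & co$carrier == "one_copy"))
  }, numeric(2))
  se_case <- sqrt(297 * (15 / 297) * (1 - 15 / 297)) / sqrt(n_seeds)
  se_ctrl <- sqrt(260 * (4 / 260) * (1 - 4 / 260)) / sqrt(n_seeds)
  expect_lt(abs(mean(counts[1, ]) - 15), 3 * se_case)
  expect_lt(abs(mean(counts[2, ]) - 4), 3 * se_ctrl)
})

test_that("sample arrays survive a write/read round trip", {
  pm <- make_probe_map(c(chr1 = 5e5), 5e4, seed = 6)
  arr <- simulate_sample_array(pm, NULL, 0.2, seed = 8, sample_id = "S9")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_array(arr, path)
  back <- read_sample_array(path)
  expect_equal(back$position, arr$position)
  expect_equal(back$log2_ratio, arr$log2_ratio, tolerance = 1e-12)
  expect_equal(back$sample_id, arr$sample_id)
})
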