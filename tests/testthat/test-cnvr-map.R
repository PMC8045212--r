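call_row <- function(sample_id, chrom, start, end, direction = "loss") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start,
             end = end, direction = direction, n_probes = 3L,
             mean_log2 = if (direction == "gain") 0.6 else -0.8,
             stringsAsFactors = FALSE)
}

test_that("merging classifies shared status and trend", {
  # identical loss calls in two samples: one shared, trend-consistent CNVR
  two <- rbind(call_row("S1", "chr1", 100, 200),
               call_row("S2", "chr1", 100, 200))
  r <- build_cnvrs(two)
  expect_equal(nrow(r), 1L)
  expect_true(r$shared)
  expect_equal(r$sample_count, 2L)
  expect_equal(r$trend, "loss")

  # a gain overlapping a loss: inconsistent trend
  mixed <- rbind(call_row("S1", "chr1", 100, 200, "gain"),
                 call_row("S2", "chr1", 150, 300, "loss"))
  r <- build_cnvrs(mixed)
  expect_equal(nrow(r), 1L)
  expect_equal(r$trend, "inconsistent")
  expect_equal(c(r$start, r$end), c(100, 300))

  # a singleton call is retained as an unshared region
  r <- build_cnvrs(call_row("S1", "chr1", 5, 50))
  expect_equal(nrow(r), 1L)
  expect_false(r$shared)
  expect_equal(r$sample_count, 1L)

  # bookkeeping errors
  expect_error(build_cnvrs(call_row("S1", "chr1", 200, 100)),
               "end < start")
})

test_that("merged components match a brute-force union-find oracle", {
  withr::local_seed(404)
  for (rep in 1:60) {
    calls <- random_calls(sample(1:30, 1))
    r <- build_cnvrs(calls, include_sex = TRUE)
    comp <- uf_components(calls)
    # same number of regions as graph components
    expect_equal(nrow(r), length(unique(comp)))
    # each component's span equals one region
    spans <- do.call(rbind, lapply(split(calls, comp), function(blk) {
      data.frame(chrom = blk$chrom[1], start = min(blk$start),
                 end = max(blk$end))
    }))
    spans <- spans[order(spans$chrom, spans$start), ]
    expect_equal(r$start, spans$start)
    expect_equal(r$end, spans$end)
    expect_equal(r$chrom, spans$chrom)
  }
})

test_that("region lengths conserve the bp union of the input calls", {
  withr::local_seed(505)
  for (rep in 1:20) {
    calls <- random_calls(sample(2:30, 1))
    r <- build_cnvrs(calls, include_sex = TRUE)
    union_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(
      GenomicRanges::GRanges(calls$chrom,
                             IRanges::IRanges(calls$start, calls$end)))))
    expect_equal(sum(r$length), union_bp)
    # regions on one chromosome never overlap each other
    for (chrom in unique(r$chrom)) {
      sub <- r[r$chrom == chrom, ]
      if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("merging is idempotent", {
  withr::local_seed(606)
  calls <- random_calls(25)
  r1 <- build_cnvrs(calls, include_sex = TRUE)
  as_calls <- data.frame(sample_id = r1$cnvr_id, chrom = r1$chrom,
                         start = r1$start, end = r1$end,
                         direction = "gain")
  r2 <- build_cnvrs(as_calls, include_sex = TRUE)
  expect_equal(r2[, c("chrom", "start", "end")],
               r1[, c("chrom", "start", "end")])
})

test_that("split mode tiles each component exactly at call boundaries", {
  withr::local_seed(707)
  for (rep in 1:20) {
    calls <- random_calls(sample(2:25, 1), chroms = "chr1")
    plain <- build_cnvrs(calls, include_sex = TRUE)
    split <- build_cnvrs(calls, split_mode = TRUE, include_sex = TRUE)
    # sub-regions tile the plain regions: same total bp, no overlap,
    # every plain region is a concatenation of sub-regions
    expect_equal(sum(split$length), sum(plain$length))
    expect_true(all(split$start[-1] > split$end[-nrow(split)]))
    boundaries <- sort(unique(c(calls$start, calls$end + 1)))
    expect_true(all(split$start %in% boundaries))
    expect_true(all((split$end + 1) %in% boundaries))
    # each sub-region's calls all cover it entirely
    for (i in seq_len(nrow(split))) {
      blk <- calls[split$members[[i]], ]
      expect_true(all(blk$start <= split$start[i] &
                        blk$end >= split$end[i]))
    }
  }
})

test_that("every region carries exactly one trend label", {
  withr::local_seed(808)
  calls <- random_calls(40)
  for (mode in c(FALSE, TRUE)) {
    r <- build_cnvrs(calls, split_mode = mode, include_sex = TRUE)
    expect_true(all(r$trend %in% c("gain", "loss", "inconsistent")))
    expect_equal(r$trend == "gain",
                 r$n_loss_calls == 0 & r$n_gain_calls > 0)
    expect_equal(r$trend == "loss",
                 r$n_gain_calls == 0 & r$n_loss_calls > 0)
  }
})

test_that("sex chromosomes are excluded unless requested", {
  calls <- rbind(call_row("S1", "chr1", 100, 200),
                 call_row("S1", "chrX", 100, 200),
                 call_row("S1", "chrY", 300, 400))
  expect_equal(build_cnvrs(calls)$chrom, "chr1")
  expect_equal(sort(build_cnvrs(calls, include_sex = TRUE)$chrom),
               c("chr1", "chrX", "chrY"))
})

test_that("chromosome summaries report coverage on the 0-100 scale", {
  calls <- call_row("S1", "chr1", 1, 1e6)
  r <- build_cnvrs(calls)
  s <- summarize_chromosomes(r, c(chr1 = 1e8, chr2 = 5e7))
  expect_equal(nrow(s), 1L)  # no row for chromosomes without regions
  expect_equal(s$pct_chrom, 1.00)
  expect_equal(s$total_length_mb, 1.0)
  expect_error(summarize_chromosomes(r, c(chr9 = 1e8)), "chr1")
})

test_that("genome summary aggregates lengths, trends and call ratio", {
  calls <- rbind(call_row("S1", "chr1", 1, 1e4),
                 call_row("S2", "chr2", 1, 3e4, "gain"))
  r <- build_cnvrs(calls)
  g <- genome_summary(r, c(chr1 = 1e8, chr2 = 1e8), calls)
  expect_equal(g$mean_length_kb, 20)
  expect_equal(g$total_length_mb, 0.04)
  expect_equal(g$n_cnvrs, g$n_consistent + g$n_inconsistent)
  expect_equal(g$pct_genome, 100 * 4e4 / 2e8)
  expect_equal(g$gain_loss_ratio, 1)

  only_gains <- call_row("S1", "chr1", 1, 1e4, "gain")
  g2 <- genome_summary(build_cnvrs(only_gains), c(chr1 = 1e8), only_gains)
  expect_equal(g2$gain_loss_label, "gains only")
  expect_equal(g2$gain_loss_ratio, Inf)

  # a sex-only call set leaves an empty autosomal map, summarised as zeros
  g0 <- genome_summary(build_cnvrs(call_row("S1", "chrX", 1, 2)),
                       c(chr1 = 1e8))
  expect_equal(g0$n_cnvrs, 0L)
  expect_equal(g0$total_length_mb, 0)
})
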