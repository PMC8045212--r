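# Independent oracles and fixture builders used across the suite.

# O(n^2) reference caller: a call is any (i, j) probe window on one
# chromosome where every probe satisfies the threshold, the window is at
# least min_probes long, and neither flanking probe satisfies it.
brute_force_calls <- function(pos, ratio, params) {
  qualifies <- function(x, dir) {
    if (dir == "gain") {
      if (params$gain_threshold == 0 && params$loss_threshold == 0) x > 0
      else x >= params$gain_threshold
    } else {
      if (params$gain_threshold == 0 && params$loss_threshold == 0) x < 0
      else x <= params$loss_threshold
    }
  }
  n <- length(pos)
  out <- list()
  for (dir in c("gain", "loss")) {
    q <- qualifies(ratio, dir)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (!all(q[i:j])) next
        if (j - i + 1 < params$min_probes) next
        left_ok <- i == 1 || !q[i - 1]
        right_ok <- j == n || !q[j + 1]
        gap_ok <- is.null(params$max_probe_gap) ||
          all(diff(pos[i:j]) <= params$max_probe_gap)
        if (!is.null(params$max_probe_gap)) {
          left_ok <- left_ok ||
            (i > 1 && pos[i] - pos[i - 1] > params$max_probe_gap)
          right_ok <- right_ok ||
            (j < n && pos[j + 1] - pos[j] > params$max_probe_gap)
        }
        if (left_ok && right_ok && gap_ok) {
          out[[length(out) + 1L]] <- data.frame(
            start = pos[i], end = pos[j], direction = dir,
            n_probes = j - i + 1, mean_log2 = mean(ratio[i:j]))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      direction = character(), n_probes = integer(),
                      mean_log2 = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

# Union-find over intervals: components of the pairwise-overlap graph.
# Returns a component id per row of `iv` (columns chrom, start, end).
uf_components <- function(iv) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (iv$chrom[i] == iv$chrom[j] &&
          iv$start[i] <= iv$end[j] && iv$start[j] <= iv$end[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Random per-sample interval sets for merge tests
random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(60, n, replace = TRUE)
  data.frame(sample_id = sample(sprintf("S%d", 1:5), n, replace = TRUE),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             direction = sample(c("gain", "loss"), n, replace = TRUE),
             n_probes = 3L, mean_log2 = 0.5, stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
exact_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tiny well-formed log2 TSV on disk
write_toy_array_file <- function(path, rows = 3) {
  df <- data.frame(sample_id = "S1", chrom = "chr1",
                   position = seq_len(rows) * 100L,
                   log2_ratio = rep(0, rows))
  write_sample_array(df, path)
  path
}

# Expand 2x2 counts (exposed/unexposed x case/control) to subject rows
expand_counts_to_cohort <- function(a, b, c, d) {
  data.frame(
    status = factor(rep(c("case", "case", "control", "control"),
                        c(a, b, c, d)), levels = c("control", "case")),
    carrier = factor(rep(c("one_copy", "two_copies",
                           "one_copy", "two_copies"), c(a, b, c, d)),
                     levels = c("two_copies", "one_copy")))
}
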