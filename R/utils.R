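#' Round half away from zero
#'
#' Deterministic "schoolbook" rounding used for all reported figures
#' (copy-number integers, percentages, table statistics). Unlike base
#' [round()], which rounds half to even, 0.5 always rounds up (and -0.5
#' down), so printed values are reproducible across platforms.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(5.0505, 1)  # 5.1
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded for reporting
#'
#' @param k count of interest.
#' @param n total count; must be positive.
#' @param digits decimal places kept (default 1).
#' @return `100 * k / n`, rounded half-up.
#' @examples
#' proportion_pct(15, 297)  # 5.1
#' @export
proportion_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  round_half_up(100 * k / n, digits)
}

# Internal: stop() with call.=FALSE and sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal: check a scalar seed
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("'seed' must be a single finite integer")
  }
  as.integer(seed)
}

# Internal: derive a per-stage child seed from a global seed.
# Deterministic, keeps results within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009) %% .Machine$integer.max)
}

# Internal: chromosomes regarded as autosomes (hg19 naming, with or
# without the "chr" prefix)
is_autosome <- function(chrom) {
  core <- sub("^chr", "", chrom)
  grepl("^[0-9]+$", core)
}
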