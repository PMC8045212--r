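#' Read gene models from BED or GTF
#'
#' BED input (0-based, half-open) is converted to 1-based inclusive
#' coordinates on read; GTF input (already 1-based inclusive) is filtered
#' to `gene` feature rows and the `gene_name` (or `gene_id`) attribute is
#' taken as the symbol. The file format is chosen from the extension
#' (`.bed`, `.gtf`/`.gff`). Duplicate symbols are allowed (a symbol may
#' map to several loci).
#'
#' @param path path to a `.bed` or `.gtf` file.
#' @return Data.frame with columns `symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `strand` (`+`, `-` or `*`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr19\t56370485\t56416408\tNLRP4", bed)
#' read_gene_models(bed)  # start converts to 56370486
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    read_gene_bed(path)
  } else if (ext %in% c("gtf", "gff")) {
    read_gene_gtf(path)
  } else {
    abort("unknown gene-model extension '.%s' (expected .bed or .gtf)", ext)
  }
}

read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(empty_gene_models())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4L) abort("unparseable BED line %d in %s", i, path)
    start0 <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start0) || is.na(end) || end <= start0) {
      abort("unparseable BED line %d in %s", i, path)
    }
    data.frame(symbol = f[4], chrom = f[1], start = start0 + 1L, end = end,
               strand = if (length(f) >= 6L && f[6] %in% c("+", "-"))
                 f[6] else "*",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_gene_gtf <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  orig <- which(keep)
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 9L) abort("unparseable GTF line %d in %s", orig[i], path)
    if (f[3] != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || end < start) {
      abort("unparseable GTF line %d in %s", orig[i], path)
    }
    symbol <- gtf_attr(f[9], "gene_name")
    if (is.na(symbol)) symbol <- gtf_attr(f[9], "gene_id")
    if (is.na(symbol)) abort("GTF line %d lacks gene_name/gene_id", orig[i])
    rows[[length(rows) + 1L]] <- data.frame(
      symbol = symbol, chrom = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_gene_models())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '[ =]+"?([^";]+)"?'), attrs))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

empty_gene_models <- function() {
  data.frame(symbol = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' Write gene models as GTF gene rows
#'
#' @param genes gene-model data.frame as from [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  lines <- sprintf(
    '%s\tcnvcohort\tgene\t%d\t%d\t.\t%s\t.\tgene_name "%s";',
    genes$chrom, genes$start, genes$end,
    ifelse(genes$strand %in% c("+", "-"), genes$strand, "."), genes$symbol)
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path path to the chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) abort("chrom.sizes needs two columns")
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(len) | len != floor(len) | len <= 0)) {
    abort("non-integer chromosome length in %s", path)
  }
  if (anyDuplicated(tab[[1]])) {
    abort("duplicate chromosome in %s: %s", path,
          tab[[1]][duplicated(tab[[1]])][1])
  }
  stats::setNames(len, tab[[1]])
}

#' Path of the bundled hg19 chrom.sizes file
#'
#' Chromosome lengths of the GRCh37/hg19 human assembly (chr1-chr22,
#' chrX, chrY), in UCSC chrom.sizes format.
#'
#' @return File path inside the installed package.
#' @export
hg19_chrom_sizes_path <- function() {
  system.file("extdata", "hg19.chrom.sizes", package = "cnvcohort",
              mustWork = TRUE)
}

#' Annotate CNVRs with overlapping genes
#'
#' A gene is listed for a region when the two closed intervals share at
#' least one bp on the same chromosome (whole gene span; strand is
#' ignored, as copy-number events are strand-agnostic). Gene lists are
#' deduplicated and ordered by gene start, then symbol.
#'
#' @param cnvrs CNVR data.frame from [build_cnvrs()] (or any table with
#'   `chrom`, `start`, `end`).
#' @param genes gene-model data.frame from [read_gene_models()].
#' @return The input `cnvrs` with two added columns: `n_genes` and
#'   `genes` (list-column of symbol vectors; `gene_symbols` gives the
#'   comma-joined form).
#' @export
annotate_cnvrs <- function(cnvrs, genes) {
  if (nrow(cnvrs) == 0L) {
    cnvrs$n_genes <- integer(0)
    cnvrs$genes <- I(list())
    cnvrs$gene_symbols <- character(0)
    return(cnvrs)
  }
  gene_lists <- rep(list(character(0)), nrow(cnvrs))
  if (nrow(genes) > 0L) {
    lv <- union(unique(cnvrs$chrom), unique(genes$chrom))
    q <- GenomicRanges::GRanges(
      factor(cnvrs$chrom, lv), IRanges::IRanges(cnvrs$start, cnvrs$end))
    s <- GenomicRanges::GRanges(
      factor(genes$chrom, lv), IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      g <- genes[sh[qh == i], , drop = FALSE]
      g <- g[order(g$start, g$symbol), , drop = FALSE]
      gene_lists[[i]] <- unique(g$symbol)
    }
  }
  cnvrs$n_genes <- vapply(gene_lists, length, integer(1))
  cnvrs$genes <- I(gene_lists)
  cnvrs$gene_symbols <- vapply(
    gene_lists, function(g) paste(g, collapse = ","), character(1))
  cnvrs
}

#' Write annotated CNVRs to TSV
#'
#' Columns: `cnvr_id`, `chrom`, `start`, `end`, `trend`, `n_genes`,
#' `gene_symbols`.
#'
#' @param annotated output of [annotate_cnvrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_cnvrs <- function(annotated, path) {
  cols <- intersect(c("cnvr_id", "chrom", "start", "end", "trend",
                      "sample_count", "n_genes", "gene_symbols"),
                    names(annotated))
  utils::write.table(annotated[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
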