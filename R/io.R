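#' Read and write BED intervals
#'
#' BED is 0-based half-open on disk; in memory the package uses 1-based
#' inclusive intervals, so `read_bed()` adds 1 to starts and `write_bed()`
#' subtracts it.
#'
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive), plus `name`
#'   if a fourth column is present.
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  out <- tibble(chrom = tb[[1]], start = tb[[2]] + 1L, end = tb[[3]])
  if (ncol(tb) >= 4) out$name <- tb[[4]]
  out
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(
    tibble(chrom = intervals$chrom, start = intervals$start - 1L,
           end = intervals$end),
    path, col_names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' A TSV with columns `sample`, `pop`, `sex` (`M`/`F`).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_metadata <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample", "pop", "sex") %in% names(tb)))
  tb
}

#' Read a SweepFinder2-style CLR grid
#'
#' Whitespace-delimited two-column files (`location`, `LR`), one per
#' chromosome, or a combined file with a leading `chrom` column.
#'
#' @param path File path.
#' @param chrom Chromosome label to attach when the file has two columns.
#' @return Tibble `chrom`, `pos`, `clr`.
#' @export
read_sweepfinder <- function(path, chrom = NULL) {
  tb <- readr::read_table(path, show_col_types = FALSE)
  if (ncol(tb) >= 3) {
    out <- tibble(chrom = as.character(tb[[1]]), pos = as.numeric(tb[[2]]),
                  clr = as.numeric(tb[[3]]))
  } else {
    if (is.null(chrom)) abort("two-column grid needs a `chrom` label")
    out <- tibble(chrom = chrom, pos = as.numeric(tb[[1]]),
                  clr = as.numeric(tb[[2]]))
  }
  out
}

#' Read an Ne trajectory table
#'
#' A TSV with columns `time_years` and `ne` (one demographic trajectory,
#' e.g. rescaled PSMC output; see [rescale_psmc()]).
#'
#' @param path File path.
#' @return Tibble `time_years`, `ne`.
#' @export
read_ne_trajectory <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("time_years", "ne") %in% names(tb)))
  tb
}

#' Extract CDS and annotation intervals from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` returning 1-based inclusive
#' interval tibbles for a feature type.
#'
#' @param path GFF3 path.
#' @param type Feature type to extract (e.g. `"CDS"`, `"exon"`).
#' @return Tibble `chrom`, `start`, `end`, `strand`, `gene` (from the
#'   `Parent` or `ID` attribute where present).
#' @export
read_gff3 <- function(path, type = "CDS") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read GFF3")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == type]
  md <- S4Vectors::mcols(gr)
  gene <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)), gene = gene)
}
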