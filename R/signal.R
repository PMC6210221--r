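#' Mean gene-body signal from a bedGraph track
#'
#' Aggregates a base-pair signal track (e.g. ChIP-seq fold change over
#' control) into one mean value per gene body. Intervals follow the BED
#' convention (0-based, half-open). With `zero_fill = TRUE` (default) bases
#' of the gene body not covered by the track count as signal 0, matching the
#' `mean0` output of the UCSC `bigWigAverageOverBed` tool; with
#' `zero_fill = FALSE` the mean is taken over covered bases only (the tool's
#' plain `mean`; `NA` for genes with no covered base).
#'
#' @param signal bedGraph file path, or a [GenomicRanges::GRanges] with a
#'   numeric `score` column.
#' @param genes BED file path (>= 4 columns: chrom, start, end, name), or a
#'   named `GRanges` of gene bodies.
#' @param zero_fill count uncovered bases as 0 (default `TRUE`).
#' @return named numeric vector of per-gene mean signal, in `genes` order.
#' @export
aggregate_genebody_signal <- function(signal, genes, zero_fill = TRUE) {
  if (is.character(signal))
    signal <- rtracklayer::import(signal, format = "bedGraph")
  if (is.character(genes))
    genes <- rtracklayer::import(genes, format = "BED")
  if (is.null(names(genes))) {
    if (is.null(genes$name)) stop("gene intervals need names (BED column 4)")
    names(genes) <- genes$name
  }
  if (any(GenomicRanges::width(genes) < 1))
    stop("gene interval with end <= start")
  if (length(signal) > 0 && any(signal$score < 0, na.rm = TRUE))
    stop("signal values must be non-negative (fold change vs control)")

  out <- setNames(numeric(length(genes)), names(genes))
  if (length(signal) == 0) {
    if (!zero_fill) out[] <- NA_real_
    return(out)
  }

  chroms <- union(as.character(GenomeInfoDb::seqlevels(signal)),
                  as.character(GenomeInfoDb::seqlevels(genes)))
  GenomeInfoDb::seqlevels(signal) <- chroms
  GenomeInfoDb::seqlevels(genes) <- chroms
  endmax <- function(gr) {
    e <- vapply(split(GenomicRanges::end(gr),
                      as.character(GenomicRanges::seqnames(gr))),
                max, numeric(1))
    e[chroms]
  }
  sl <- pmax(endmax(signal), endmax(genes), na.rm = TRUE)
  names(sl) <- chroms
  GenomeInfoDb::seqlengths(signal) <- sl
  GenomeInfoDb::seqlengths(genes) <- sl

  cov <- GenomicRanges::coverage(signal, weight = "score")
  if (!zero_fill) covered <- GenomicRanges::coverage(signal)
  by_chr <- split(genes, GenomicRanges::seqnames(genes))
  for (chr in names(by_chr)) {
    g <- by_chr[[chr]]
    if (length(g) == 0) next
    sums <- IRanges::viewSums(IRanges::Views(cov[[chr]], IRanges::ranges(g)))
    if (zero_fill) {
      denom <- GenomicRanges::width(g)
    } else {
      pos <- covered[[chr]] > 0L
      denom <- IRanges::viewSums(IRanges::Views(pos, IRanges::ranges(g)))
      denom[denom == 0] <- NA_real_
    }
    out[names(g)] <- sums / denom
  }
  out
}
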