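# shared internal helpers

#' Pearson chi-squared test on a 2x2 (or larger) contingency table
#'
#' Thin wrapper around [stats::chisq.test()] without continuity correction;
#' the uncorrected Pearson statistic is the one used throughout the
#' proximity-vs-coregulation and feature-vs-class comparisons. If any row or
#' column margin is zero the test is skipped with a warning and `NA`s are
#' returned (observed counts are still meaningful).
#'
#' @param tab integer matrix of observed counts.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `df`, `p.value`, `expected` (all `NA` when
#'   a margin is zero).
#' @export
pearson_chisq <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("contingency table has a zero margin; chi-squared test skipped")
    return(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                expected = NULL))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}

# equal-count bins by empirical quantiles, ties kept together.
# +Inf (e.g. similarity of identical epigenetic profiles) goes to the top
# bin, -Inf to the bottom; NA propagates. Returns integer bin ids 1..<=n.
quantile_bins <- function(x, n) {
  fin <- is.finite(x)
  if (!any(fin)) stop("no finite values to bin")
  br <- unique(stats::quantile(x[fin], probs = seq(0, 1, length.out = n + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) stop("too few distinct values to bin")
  b <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  nb <- length(br) - 1L
  b[!is.na(x) & x == Inf] <- nb
  b[!is.na(x) & x == -Inf] <- 1L
  as.integer(b)
}

# canonical unordered pair orientation: gene_a < gene_b lexicographically
canonicalize_pairs <- function(dt) {
  swap <- dt$gene_a > dt$gene_b
  if (any(swap)) {
    tmp <- dt$gene_a[swap]
    dt[swap, gene_a := dt$gene_b[swap]]
    dt[swap, gene_b := tmp]
  }
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
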