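#' Bundle per-gene post-transcriptional annotations
#'
#' Container for the annotations used to compare buffered and sustained
#' pairs: miRNA target sets, CDS lengths, ribosome-occupancy profiles
#' (log2 of ribosome signal scaled by mRNA), translation rates and
#' non-exponential-degradation (NED) flags, plus optional protein-complex
#' ids and subcellular compartments.
#'
#' @param mirna named list (gene -> character vector of miRNA ids).
#' @param cds_length named numeric vector (bp, > 0).
#' @param ribosome numeric matrix, genes x time points, of log2
#'   ribosome/mRNA ratios.
#' @param translation_rate named numeric vector (> 0 where present).
#' @param ned named logical vector (protein non-exponentially degraded).
#' @param complex_id optional named vector of complex/pathway ids.
#' @param localization optional named vector of subcellular compartments.
#' @return list of class `pair_annotation`.
#' @export
pair_annotation <- function(mirna = NULL, cds_length = NULL, ribosome = NULL,
                            translation_rate = NULL, ned = NULL,
                            complex_id = NULL, localization = NULL) {
  if (!is.null(cds_length) && any(cds_length <= 0, na.rm = TRUE))
    stop("CDS lengths must be positive")
  if (!is.null(translation_rate) && any(translation_rate <= 0, na.rm = TRUE))
    stop("translation rates must be strictly positive")
  structure(list(mirna = mirna, cds_length = cds_length, ribosome = ribosome,
                 translation_rate = translation_rate, ned = ned,
                 complex_id = complex_id, localization = localization),
            class = "pair_annotation")
}

#' Classify mRNA-coexpressed pairs as buffered or sustained
#'
#' Sustained = coregulated on both the mRNA and the protein layer;
#' buffered = coregulated on mRNA but not on protein. Pairs that are not
#' mRNA-coregulated fall outside the classified universe (`NA`). The two
#' statuses partition the mRNA-coregulated pairs.
#'
#' @param pairs pair table with `coregulated_mrna` and `coregulated_both`.
#' @return new pair table with a `status` column
#'   (`"sustained"` / `"buffered"` / `NA`).
#' @export
classify_pairs <- function(pairs) {
  pairs <- data.table::copy(pairs)
  pairs[, status := fifelse(coregulated_mrna,
                            fifelse(coregulated_both, "sustained", "buffered"),
                            NA_character_)]
  pairs[]
}

#' Shared miRNA count per pair, compared across classes
#'
#' Counts miRNAs targeting both genes of each classified pair and compares
#' the counts of sustained versus buffered pairs with a two-sided
#' Mann-Whitney test. Pairs with a missing miRNA annotation on either gene
#' are excluded and counted.
#'
#' @param pairs classified pair table (see [classify_pairs()]).
#' @param ann a [pair_annotation()] with `mirna`.
#' @return list with `pairs` (gene_a, gene_b, status, n_shared),
#'   `n_excluded`, and `test` (Mann-Whitney statistic and p value,
#'   sustained vs buffered).
#' @export
shared_mirnas <- function(pairs, ann) {
  sets <- ann$mirna
  if (is.null(sets)) stop("annotation lacks miRNA target sets")
  cls <- pairs[!is.na(status)]
  has <- cls$gene_a %in% names(sets) & cls$gene_b %in% names(sets)
  n_excluded <- sum(!has)
  cls <- cls[has]
  n_shared <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                     cls$gene_a, cls$gene_b, USE.NAMES = FALSE)
  out <- cls[, .(gene_a, gene_b, status)][, n_shared := n_shared]
  test <- list(statistic = NA_real_, p.value = NA_real_)
  if (all(c("sustained", "buffered") %in% out$status)) {
    ht <- suppressWarnings(stats::wilcox.test(
      out[status == "sustained", n_shared],
      out[status == "buffered", n_shared]))
    test <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  } else {
    warning("one of the classes has no annotated pairs; Mann-Whitney skipped")
  }
  list(pairs = out[], n_excluded = n_excluded, test = test)
}

#' Similar-CDS-length flag per pair
#'
#' Two genes have similar coding-sequence lengths when the ratio of the
#' longer to the shorter CDS is strictly below `max_ratio` (default 1.5).
#'
#' @param pairs classified pair table.
#' @param ann a [pair_annotation()] with `cds_length`.
#' @param max_ratio strict upper bound on the long/short ratio.
#' @return list with `pairs` (gene_a, gene_b, status, flag), `n_excluded`,
#'   and `test` (Pearson chi-squared of status x flag).
#' @export
cds_similarity <- function(pairs, ann, max_ratio = 1.5) {
  len <- ann$cds_length
  if (is.null(len)) stop("annotation lacks CDS lengths")
  if (any(len <= 0, na.rm = TRUE)) stop("CDS lengths must be positive")
  binary_pair_feature(pairs, function(a, b) {
    r <- pmax(len[a], len[b]) / pmin(len[a], len[b])
    r < max_ratio
  }, names(len)[!is.na(len)])
}

#' Correlated-ribosome-occupancy flag per pair
#'
#' Pearson correlation of the two genes' log2 ribosome/mRNA occupancy
#' profiles; raw p values from the t transform are Holm-adjusted over all
#' tested pairs; the flag requires PCC > `pcc_thresh` and adjusted
#' p < `alpha`. Pairs with a profile shorter than 3 points are excluded.
#'
#' @param pairs classified pair table.
#' @param ann a [pair_annotation()] with `ribosome`.
#' @param pcc_thresh PCC threshold (default 0.5, strict).
#' @param alpha Holm-adjusted p threshold (default 0.001, strict).
#' @return list with `pairs` (gene_a, gene_b, status, pcc, p, padj, flag),
#'   `n_excluded`, and `test` (chi-squared of status x flag).
#' @export
ribosome_profile_correlation <- function(pairs, ann, pcc_thresh = 0.5,
                                         alpha = 0.001) {
  prof <- ann$ribosome
  if (is.null(prof)) stop("annotation lacks ribosome profiles")
  usable <- rownames(prof)[rowSums(!is.na(prof)) >= 3]
  cls <- pairs[!is.na(status)]
  has <- cls$gene_a %in% usable & cls$gene_b %in% usable
  n_excluded <- sum(!has)
  cls <- cls[has]
  stats_pair <- function(a, b) {
    xa <- prof[a, ]; xb <- prof[b, ]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < 3) return(c(NA_real_, NA_real_))
    r <- stats::cor(xa[ok], xb[ok])
    n <- sum(ok)
    t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE))
  }
  rp <- t(mapply(stats_pair, cls$gene_a, cls$gene_b, USE.NAMES = FALSE))
  out <- cls[, .(gene_a, gene_b, status)]
  out[, `:=`(pcc = rp[, 1], p = rp[, 2])]
  drop <- is.na(out$pcc)
  n_excluded <- n_excluded + sum(drop)
  out <- out[!drop]
  out[, padj := stats::p.adjust(p, method = "holm")]
  out[, flag := pcc > pcc_thresh & padj < alpha]
  ht <- class_flag_chisq(out)
  list(pairs = out[], n_excluded = n_excluded, test = ht)
}

#' Similar-translation-rate flag per pair
#'
#' The flag is `TRUE` when the absolute log2 ratio of the two genes'
#' translation rates is at most `max_log2_ratio` (inclusive, default 1).
#'
#' @param pairs classified pair table.
#' @param ann a [pair_annotation()] with `translation_rate`.
#' @param max_log2_ratio inclusive bound on |log2(rate_a / rate_b)|.
#' @return list with `pairs`, `n_excluded`, `test` as in [cds_similarity()].
#' @export
translation_rate_similarity <- function(pairs, ann, max_log2_ratio = 1) {
  rate <- ann$translation_rate
  if (is.null(rate)) stop("annotation lacks translation rates")
  binary_pair_feature(pairs, function(a, b) {
    abs(log2(rate[a] / rate[b])) <= max_log2_ratio
  }, names(rate)[!is.na(rate)])
}

#' Contains-NED flag per pair
#'
#' Flags pairs coding at least one non-exponentially degraded protein
#' (logical OR of the two genes' NED flags) and tests the class x flag
#' association with a Pearson chi-squared.
#'
#' @param pairs classified pair table.
#' @param ann a [pair_annotation()] with `ned`.
#' @return list with `pairs`, `n_excluded`, `test` as in [cds_similarity()].
#' @export
ned_pairs <- function(pairs, ann) {
  ned <- ann$ned
  if (is.null(ned)) stop("annotation lacks NED flags")
  binary_pair_feature(pairs, function(a, b) ned[a] | ned[b],
                      names(ned)[!is.na(ned)])
}

# shared machinery for binary pair features: compute flag on annotated
# classified pairs, chi-squared of class x flag
binary_pair_feature <- function(pairs, flag_fun, annotated_genes) {
  cls <- pairs[!is.na(status)]
  has <- cls$gene_a %in% annotated_genes & cls$gene_b %in% annotated_genes
  n_excluded <- sum(!has)
  cls <- cls[has]
  out <- cls[, .(gene_a, gene_b, status)]
  out[, flag := flag_fun(gene_a, gene_b)]
  list(pairs = out[], n_excluded = n_excluded, test = class_flag_chisq(out))
}

class_flag_chisq <- function(dt) {
  tab <- table(factor(dt$status, c("sustained", "buffered")),
               factor(dt$flag, c(TRUE, FALSE)))
  ht <- pearson_chisq(tab)
  list(table = tab, statistic = ht$statistic, df = ht$df, p.value = ht$p.value)
}

#' All five post-transcriptional feature comparisons
#'
#' Runs [shared_mirnas()], [cds_similarity()],
#' [ribosome_profile_correlation()], [translation_rate_similarity()] and
#' [ned_pairs()] on one classified pair table and collects the test
#' summaries, with per-feature exclusion counts.
#'
#' @param pairs pair table (will be classified if `status` is absent).
#' @param ann a [pair_annotation()].
#' @return list with `features` (named list of the five results) and
#'   `summary` (`data.table`: feature, n_pairs, n_excluded, statistic,
#'   p.value).
#' @export
posttranscriptional_features <- function(pairs, ann) {
  if (!"status" %in% names(pairs)) pairs <- classify_pairs(pairs)
  feats <- list(
    shared_mirnas = shared_mirnas(pairs, ann),
    cds_similarity = cds_similarity(pairs, ann),
    ribosome_profile = ribosome_profile_correlation(pairs, ann),
    translation_rate = translation_rate_similarity(pairs, ann),
    ned = ned_pairs(pairs, ann)
  )
  summary <- rbindlist(lapply(names(feats), function(f) {
    x <- feats[[f]]
    data.table(feature = f, n_pairs = nrow(x$pairs),
               n_excluded = x$n_excluded,
               statistic = x$test$statistic %||% NA_real_,
               p.value = x$test$p.value %||% NA_real_)
  }))
  list(features = feats, summary = summary)
}
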