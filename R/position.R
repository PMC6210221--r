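#' TSS distance between annotated genes
#'
#' Absolute base-pair separation between the outermost transcription start
#' sites of two genes on the same chromosome; `NA` for inter-chromosomal
#' pairs (no linear distance is defined across chromosomes).
#'
#' @param ann gene annotation `data.table` with columns `gene`, `chromosome`,
#'   `tss` (first base of the outermost TSS; >= 0).
#' @param gene_a,gene_b character vectors of gene ids (recycled pairwise).
#' @return numeric vector of distances in bp (`NA` = different chromosomes).
#' @export
tss_distance <- function(ann, gene_a, gene_b) {
  ann <- as.data.table(ann)
  ia <- match(gene_a, ann$gene); ib <- match(gene_b, ann$gene)
  if (anyNA(ia) || anyNA(ib)) stop("unannotated gene id(s)")
  out <- abs(ann$tss[ia] - ann$tss[ib])
  out[ann$chromosome[ia] != ann$chromosome[ib]] <- NA_real_
  out
}

#' Annotate a pair table with TSS distances
#'
#' Adds `same_chromosome` and `distance` (bp, `NA` inter-chromosomal)
#' columns. Pairs whose genes lack annotation are dropped with a message.
#'
#' @param pairs pair table keyed by `gene_a`, `gene_b`.
#' @param ann gene annotation with `gene`, `chromosome`, `tss`.
#' @return new pair table with distance columns.
#' @export
annotate_pair_distances <- function(pairs, ann) {
  ann <- as.data.table(ann)
  pairs <- data.table::copy(pairs)
  ia <- match(pairs$gene_a, ann$gene); ib <- match(pairs$gene_b, ann$gene)
  keep <- !is.na(ia) & !is.na(ib)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " pair(s) with unannotated genes")
    pairs <- pairs[keep]; ia <- ia[keep]; ib <- ib[keep]
  }
  pairs[, same_chromosome := ann$chromosome[ia] == ann$chromosome[ib]]
  pairs[, distance := fifelse(same_chromosome,
                              abs(ann$tss[ia] - ann$tss[ib]), NA_real_)]
  pairs[]
}

#' Flag close-by gene pairs
#'
#' `close_by` is `TRUE` for same-chromosome pairs whose TSS separation is
#' strictly below `threshold` (default 50 kb); inter-chromosomal pairs are
#' never close-by.
#'
#' @param pairs pair table with `same_chromosome` and `distance` columns
#'   (see [annotate_pair_distances()]).
#' @param threshold separation threshold in bp (default `50000`).
#' @return new pair table with a `close_by` column.
#' @export
classify_closeby <- function(pairs, threshold = 50000) {
  pairs <- data.table::copy(pairs)
  pairs[, close_by := !is.na(distance) & same_chromosome & distance < threshold]
  pairs[]
}

#' Close-by versus coregulation contingency tests
#'
#' Builds two 2x2 contingency tables over all pairs: rows close-by/other,
#' columns (1) mRNA-coregulated or not and (2) coregulated on both layers or
#' not, and runs a Pearson chi-squared test (no continuity correction) on
#' each. The headline fractions -- the percentage of close-by pairs
#' coregulated at the mRNA level and at both levels -- are always reported,
#' even when a zero margin forces the test to be skipped.
#'
#' @param pairs pair table with `close_by`, `coregulated_mrna` and
#'   `coregulated_both` columns.
#' @param correct Yates continuity correction (default `FALSE`).
#' @return list with elements `mrna` and `both`, each holding `table`,
#'   `statistic`, `df`, `p.value`, and `fractions` (named percentages of
#'   coregulated pairs among close-by and other pairs).
#' @export
closeby_contingency <- function(pairs, correct = FALSE) {
  one <- function(flagcol) {
    cb <- factor(fifelse(pairs$close_by, "close_by", "other"),
                 levels = c("close_by", "other"))
    cr <- factor(fifelse(pairs[[flagcol]], "coregulated", "not"),
                 levels = c("coregulated", "not"))
    tab <- table(cb, cr)
    ht <- pearson_chisq(tab, correct = correct)
    frac <- 100 * prop.table(tab, margin = 1)[, "coregulated"]
    list(table = tab, statistic = ht$statistic, df = ht$df,
         p.value = ht$p.value, fractions = frac)
  }
  list(mrna = one("coregulated_mrna"), both = one("coregulated_both"))
}

#' Positional clustering score and labels
#'
#' For every gene with at least `k` other genes on its chromosome, computes
#' the mean TSS distance to its `k` nearest same-chromosome neighbors. The
#' eligible genes are sorted by increasing score; the smallest `tail`
#' fraction are labelled `"most"` (most positionally clustered), the largest
#' `tail` fraction `"least"`. Genes tied with the boundary score are included
#' in the label, so with ties a label can exceed the nominal fraction;
#' ineligible genes are labelled `"neither"` and counted in a message.
#'
#' @param ann gene annotation with `gene`, `chromosome`, `tss`.
#' @param k number of nearest neighbors (default 5).
#' @param tail labelled fraction at each extreme (default 0.05).
#' @return `data.table` with `gene`, `chromosome`, `score` (bp; `NA` if
#'   ineligible) and `label` in `{"most", "least", "neither"}`.
#' @export
positional_clustering <- function(ann, k = 5, tail = 0.05) {
  ann <- as.data.table(ann)
  setorderv(ann <- data.table::copy(ann), c("chromosome", "tss", "gene"))
  score_chr <- function(tss) {
    n <- length(tss)
    if (n < k + 1) return(rep(NA_real_, n))
    vapply(seq_len(n), function(i) {
      d <- sort(abs(tss[-i] - tss[i]), method = "radix")  # stable for ties
      mean(d[seq_len(k)])
    }, numeric(1))
  }
  ann[, score := score_chr(tss), by = chromosome]
  n_inel <- sum(is.na(ann$score))
  if (n_inel > 0)
    message(n_inel, " gene(s) with < ", k, " same-chromosome neighbors left unlabelled")
  ann[, label := "neither"]
  elig <- ann[!is.na(score)]
  n_tail <- floor(tail * nrow(elig))
  if (n_tail >= 1) {
    s <- sort(elig$score)
    lo <- s[n_tail]                      # "most" clustered = smallest scores
    hi <- s[nrow(elig) - n_tail + 1]     # "least" clustered = largest scores
    ann[!is.na(score) & score <= lo, label := "most"]
    ann[!is.na(score) & score >= hi, label := "least"]
  }
  ann[, .(gene, chromosome, score, label)]
}
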