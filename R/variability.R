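#' Expression variability (coefficient of variation) per gene
#'
#' CV of the offset log2 ratios over a gene's non-missing tissues:
#' `sd(value + offset) / mean(value + offset)`, with the sample (n-1)
#' standard deviation. The offset (default +10) keeps the denominator away
#' from zero for unchanged genes whose log2 ratio is ~0; an offset that
#' still leaves a non-positive mean raises an error (cannot happen while
#' |log2 ratio| < offset). Genes with fewer than two non-missing tissues
#' are excluded.
#'
#' @param m an `ExpressionMatrix`.
#' @param offset constant added to the log2 ratios (default 10).
#' @return `data.table`: gene, n, mean, sd, cv -- one row per retained gene.
#' @export
expression_cv <- function(m, offset = 10) {
  vals <- unclass(m) + offset
  n <- rowSums(!is.na(vals))
  keep <- n >= 2
  vals <- vals[keep, , drop = FALSE]
  mu <- rowMeans(vals, na.rm = TRUE)
  if (any(mu <= 0))
    stop("mean + offset <= 0 for gene(s): ",
         paste(utils::head(rownames(vals)[mu <= 0], 5), collapse = ", "))
  sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
  data.table(gene = rownames(vals), n = n[keep], mean = mu, sd = sdv,
             cv = sdv / mu)
}

#' Merge mRNA and protein variability into one table
#'
#' @param mrna,protein `ExpressionMatrix` objects.
#' @param offset CV offset (default 10).
#' @return `data.table`: gene, cv_mrna, cv_protein (inner join on gene).
#' @export
variability_table <- function(mrna, protein, offset = 10) {
  a <- expression_cv(mrna, offset)[, .(gene, cv_mrna = cv)]
  b <- expression_cv(protein, offset)[, .(gene, cv_protein = cv)]
  merge(a, b, by = "gene")
}

#' Compare expression variability between two gene groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the CV values of two
#' gene groups, run separately on every CV column present (`cv_mrna`,
#' `cv_protein`, or a bare `cv`). Small tie-free samples use the exact null
#' distribution, larger ones the normal approximation with tie correction;
#' groups smaller than 3 genes additionally trigger a warning.
#'
#' @param v a table from [expression_cv()] or [variability_table()].
#' @param genes_a,genes_b character vectors of gene ids (non-empty,
#'   disjoint interpretation is the caller's responsibility).
#' @return `data.table`: layer, n_a, n_b, median_a, median_b, statistic
#'   (Mann-Whitney U of group a), p.value.
#' @export
compare_cv_groups <- function(v, genes_a, genes_b) {
  cols <- intersect(c("cv_mrna", "cv_protein", "cv"), names(v))
  if (length(cols) == 0) stop("no CV column found")
  res <- list()
  for (col in cols) {
    xa <- v[[col]][v$gene %in% genes_a]
    xb <- v[[col]][v$gene %in% genes_b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) == 0 || length(xb) == 0) stop("empty group for ", col)
    if (length(xa) < 3 || length(xb) < 3)
      warning("group with < 3 genes; exact Mann-Whitney used")
    # exact for small tie-free samples, otherwise normal approximation with
    # tie correction (wilcox.test defaults)
    ht <- suppressWarnings(stats::wilcox.test(xa, xb))
    res[[col]] <- data.table(
      layer = sub("^cv_?", "", col),
      n_a = length(xa), n_b = length(xb),
      median_a = stats::median(xa), median_b = stats::median(xb),
      statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  rbindlist(res)
}

#' Group mean raw expression (confound check)
#'
#' Mean TPM per gene group, computed on the raw (pre-normalization) TPM
#' matrix. Used alongside [compare_cv_groups()] to verify that a
#' variability difference between groups is not a by-product of an
#' expression-level difference.
#'
#' @param raw_tpm numeric gene x tissue matrix of raw TPM.
#' @param groups named list of character vectors of gene ids.
#' @return `data.table`: group, n_genes, mean_tpm.
#' @export
mean_expression_check <- function(raw_tpm, groups) {
  rbindlist(lapply(names(groups), function(g) {
    genes <- intersect(groups[[g]], rownames(raw_tpm))
    data.table(group = g, n_genes = length(genes),
               mean_tpm = mean(raw_tpm[genes, , drop = FALSE], na.rm = TRUE))
  }))
}

#' Stratify genes by mean gene-body signal of one mark
#'
#' Splits genes into equal-count groups (default terciles) of their mean
#' signal for one histone mark across tissues -- e.g. to compare expression
#' variability across H3K36me3 strata. The group edges are attached as the
#' `"edges"` attribute.
#'
#' @param profiles an [epigenetic_profile()].
#' @param mark histone mark name (default `"H3K36me3"`).
#' @param n_groups number of strata (default 3).
#' @return named integer vector (gene -> stratum, 1 = lowest signal).
#' @export
stratify_by_signal <- function(profiles, mark = "H3K36me3", n_groups = 3) {
  sel <- attr(profiles, "marks") == mark
  if (!any(sel)) stop("mark not present in profiles: ", mark)
  avg <- rowMeans(unclass(profiles)[, sel, drop = FALSE], na.rm = TRUE)
  out <- setNames(quantile_bins(avg, n_groups), rownames(profiles))
  attr(out, "edges") <- unique(stats::quantile(avg, seq(0, 1, length.out = n_groups + 1),
                                               names = FALSE))
  out
}
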