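#' Pairwise-complete Pearson correlation for one expression layer
#'
#' Computes the Pearson correlation coefficient for every unordered gene pair
#' over the tissues where both genes are observed (pairwise-complete
#' observations), together with the overlap count and the two-sided p value
#' from the exact t transform with `n_overlap - 2` degrees of freedom.
#' Pairs with fewer than `min_overlap` shared tissues, and pairs where a gene
#' has zero variance over the overlap (undefined PCC), are omitted; the
#' number of such omissions is reported via `message()`.
#'
#' The input should already be column-centered ([center_per_experiment()]);
#' centering a column shifts both genes equally in that tissue and therefore
#' does not change any pairwise PCC, but it is applied upstream so that
#' exported matrices share one convention.
#'
#' @param m an `ExpressionMatrix` (genes x tissues).
#' @param min_overlap minimum jointly observed tissues per pair (default 8).
#' @return a `data.table` with columns `gene_a`, `gene_b` (canonical order,
#'   `gene_a < gene_b`), `pcc`, `n_overlap`, `p`.
#' @export
pairwise_pcc <- function(m, min_overlap = 8) {
  x <- t(unclass(m))                       # tissues x genes
  ok <- !is.na(x)
  n <- crossprod(ok)                       # genes x genes overlap counts
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  dt <- data.table(
    gene_a = colnames(x)[ut[, 1]],
    gene_b = colnames(x)[ut[, 2]],
    pcc = r[ut],
    n_overlap = as.integer(n[ut])
  )
  n_total <- nrow(dt)
  dt <- dt[n_overlap >= min_overlap]
  n_low <- n_total - nrow(dt)
  n_bad <- dt[, sum(is.na(pcc))]
  dt <- dt[!is.na(pcc)]
  if (n_low > 0 || n_bad > 0)
    message(sprintf("omitted %d pair(s) with overlap < %d and %d with undefined PCC",
                    n_low, min_overlap, n_bad))
  # pairwise-complete correlations can exceed |1| by rounding
  dt[, pcc := pmin(1, pmax(-1, pcc))]
  tstat <- dt$pcc * sqrt((dt$n_overlap - 2) / pmax(1 - dt$pcc^2, .Machine$double.eps))
  dt[, p := 2 * stats::pt(abs(tstat), df = n_overlap - 2, lower.tail = FALSE)]
  dt <- canonicalize_pairs(dt)
  setkeyv(dt, c("gene_a", "gene_b"))
  dt[]
}

#' Combine per-layer correlation tables into one pair table
#'
#' Inner join on the canonical gene pair: only pairs passing the overlap
#' filter on both layers are kept, so every stored pair has `n_overlap >= 8`
#' (or the chosen minimum) on each layer.
#'
#' @param mrna_pairs,protein_pairs outputs of [pairwise_pcc()].
#' @return a `data.table` keyed by `gene_a`, `gene_b` with per-layer columns
#'   `pcc_mrna`, `n_mrna`, `p_mrna`, `pcc_protein`, `n_protein`, `p_protein`.
#' @export
combine_layers <- function(mrna_pairs, protein_pairs) {
  a <- data.table::copy(mrna_pairs)
  setnames(a, c("pcc", "n_overlap", "p"), c("pcc_mrna", "n_mrna", "p_mrna"))
  b <- data.table::copy(protein_pairs)
  setnames(b, c("pcc", "n_overlap", "p"), c("pcc_protein", "n_protein", "p_protein"))
  out <- merge(a, b, by = c("gene_a", "gene_b"))
  setkeyv(out, c("gene_a", "gene_b"))
  out[]
}

#' Benjamini-Hochberg adjustment of a pair table layer
#'
#' Standard step-up BH over all stored pairs of the given layer (the
#' adjustment family is the set of pairs that passed the overlap filter).
#' Adds/overwrites the `padj_<layer>` column.
#'
#' @param pairs a pair table with a `p_<layer>` column (or `p` for a
#'   single-layer table from [pairwise_pcc()]).
#' @param layer `"mrna"` or `"protein"`.
#' @return a new pair table with the adjusted-p column added.
#' @export
adjust_bh <- function(pairs, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  pairs <- data.table::copy(pairs)
  pcol <- if (paste0("p_", layer) %in% names(pairs)) paste0("p_", layer) else "p"
  if (!pcol %in% names(pairs)) stop("no raw p-value column for layer ", layer)
  pairs[, (paste0("padj_", layer)) := stats::p.adjust(get(pcol), method = "BH")]
  pairs[]
}

#' Call coregulated gene pairs
#'
#' A pair is coregulated on a layer when its PCC exceeds `pcc_thresh`
#' (strictly; negative correlations never qualify) and its BH-adjusted p
#' value is below `alpha` (strictly). `coregulated_both` requires both layers
#' to pass. Adds logical flag columns for every layer with an adjusted-p
#' column present.
#'
#' @param pairs pair table with `pcc_<layer>` and `padj_<layer>` columns.
#' @param pcc_thresh PCC call threshold (default 0.5).
#' @param alpha adjusted-p call threshold (default 0.05).
#' @return a new pair table with `coregulated_mrna` / `coregulated_protein`
#'   (as available) and, when both exist, `coregulated_both`.
#' @export
call_coregulation <- function(pairs, pcc_thresh = 0.5, alpha = 0.05) {
  pairs <- data.table::copy(pairs)
  done <- character(0)
  for (layer in c("mrna", "protein")) {
    pc <- paste0("pcc_", layer); pa <- paste0("padj_", layer)
    if (all(c(pc, pa) %in% names(pairs))) {
      pairs[, (paste0("coregulated_", layer)) :=
              get(pc) > pcc_thresh & get(pa) < alpha]
      done <- c(done, layer)
    }
  }
  if (length(done) == 0) stop("no layer with both PCC and adjusted-p columns")
  if (length(done) == 2)
    pairs[, coregulated_both := coregulated_mrna & coregulated_protein]
  pairs[]
}

#' Per-layer correlation pipeline
#'
#' Convenience wrapper chaining the standard steps: overlap filtering,
#' per-experiment centering, pairwise PCC on each layer, layer merge, BH
#' adjustment per layer and coregulation calls.
#'
#' @param mrna,protein `ExpressionMatrix` objects.
#' @param min_overlap minimum jointly observed tissues (default 8).
#' @param pcc_thresh,alpha coregulation call thresholds.
#' @return pair table with correlations, adjusted p values and flags.
#' @export
build_pair_table <- function(mrna, protein, min_overlap = 8,
                             pcc_thresh = 0.5, alpha = 0.05) {
  flt <- filter_min_overlap(mrna, protein, min_tissues = min_overlap)
  mp <- pairwise_pcc(center_per_experiment(flt$mrna), min_overlap = min_overlap)
  pp <- pairwise_pcc(center_per_experiment(flt$protein), min_overlap = min_overlap)
  pairs <- combine_layers(mp, pp)
  pairs <- adjust_bh(pairs, "mrna")
  pairs <- adjust_bh(pairs, "protein")
  call_coregulation(pairs, pcc_thresh = pcc_thresh, alpha = alpha)
}

#' Chromosome coregulation map
#'
#' Orders the genes of one chromosome by TSS and returns the square PCC
#' matrix of the requested layer (diagonal 1, pairs absent from the table
#' `NA`), plus a binned mean-PCC versus TSS-separation curve (equal-count
#' separation bins) as a plain summary of how coregulation decays with
#' linear distance.
#'
#' @param pairs pair table with `pcc_<layer>` columns.
#' @param ann gene annotation `data.table` with `gene`, `chromosome`, `tss`.
#' @param chromosome chromosome identifier to map.
#' @param layer `"mrna"` or `"protein"`.
#' @param n_bins number of separation bins for the decay curve (default 10).
#' @return list with `matrix` (TSS-ordered, symmetric), `genes` (ordered ids),
#'   `tss`, and `decay` (`data.table`: bin, n, mean_separation, mean_pcc).
#' @export
chromosome_coregulation_map <- function(pairs, ann, chromosome,
                                        layer = c("mrna", "protein"),
                                        n_bins = 10) {
  layer <- match.arg(layer)
  ann <- as.data.table(ann)
  keep <- ann$chromosome == chromosome   # plain vector: arg must not be
  chr_ann <- ann[keep]                   # shadowed by the column of same name
  if (nrow(chr_ann) == 0) stop("unknown chromosome: ", chromosome)
  setorderv(chr_ann, c("tss", "gene"))
  genes <- chr_ann$gene
  pcol <- paste0("pcc_", layer)
  if (!pcol %in% names(pairs)) pcol <- "pcc"
  sub <- pairs[gene_a %in% genes & gene_b %in% genes]
  m <- matrix(NA_real_, length(genes), length(genes), dimnames = list(genes, genes))
  diag(m) <- 1
  ia <- match(sub$gene_a, genes); ib <- match(sub$gene_b, genes)
  m[cbind(ia, ib)] <- sub[[pcol]]
  m[cbind(ib, ia)] <- sub[[pcol]]
  sep <- abs(chr_ann$tss[ia] - chr_ann$tss[ib])
  decay <- NULL
  if (nrow(sub) >= n_bins) {
    b <- quantile_bins(sep, n_bins)
    decay <- data.table(bin = b, separation = sep, pcc = sub[[pcol]])[
      , .(n = .N, mean_separation = mean(separation), mean_pcc = mean(pcc)),
      keyby = bin]
  }
  list(matrix = m, genes = genes, tss = chr_ann$tss, decay = decay)
}
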