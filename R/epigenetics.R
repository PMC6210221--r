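#' Construct an epigenetic profile matrix
#'
#' Gene x feature matrix of mean gene-body ChIP-seq signal, one feature per
#' (histone mark, tissue) combination. Features must be identical across
#' genes; values are non-negative fold changes over control.
#'
#' @param values numeric matrix, gene rownames, one column per feature.
#' @param marks,tissues character vectors parallel to the columns. If
#'   missing, they are parsed from column names of the form `mark.tissue`.
#' @return the matrix with class `EpigeneticProfile` and `marks`/`tissues`
#'   attributes.
#' @export
epigenetic_profile <- function(values, marks = NULL, tissues = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("profile matrix needs gene rownames")
  if (is.null(marks) || is.null(tissues)) {
    parts <- strsplit(colnames(values), ".", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("cannot parse mark/tissue from column names; supply marks= and tissues=")
    marks <- vapply(parts, `[`, "", 1)
    tissues <- vapply(parts, `[`, "", 2)
  }
  if (length(marks) != ncol(values) || length(tissues) != ncol(values))
    stop("marks/tissues must have one entry per column")
  if (any(values < 0, na.rm = TRUE)) stop("epigenetic signal must be non-negative")
  colnames(values) <- paste(marks, tissues, sep = ".")
  structure(values, marks = marks, tissues = tissues,
            class = c("EpigeneticProfile", class(values)))
}

#' Read an epigenetic profile from a long-format TSV
#'
#' Expects columns `gene`, `mark`, `tissue`, `signal` (header required) and
#' pivots them into a gene x (mark, tissue) matrix; combinations absent for
#' a gene become `NA` (such genes are excluded from similarity downstream).
#'
#' @param path TSV file path.
#' @return an [epigenetic_profile()].
#' @export
load_epigenetic_profile <- function(path) {
  long <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1:3, numeric = 4))
  setnames(long, c("gene", "mark", "tissue", "signal"))
  long[, feature := paste(mark, tissue, sep = ".")]
  wide <- data.table::dcast(long, gene ~ feature, value.var = "signal")
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$gene
  feats <- unique(long[, .(feature, mark, tissue)])
  feats <- feats[match(colnames(m), feature)]
  epigenetic_profile(m, marks = feats$mark, tissues = feats$tissue)
}

#' Epigenetic similarity as inverted Mahalanobis distance
#'
#' Computes, for every unordered gene pair, the Mahalanobis distance between
#' the two genes' (mark, tissue) signal vectors,
#' `d(a, b) = sqrt((x_a - x_b)' S^-1 (x_a - x_b))`, and reports the
#' similarity `1 / d`. Identical profiles (d = 0) get similarity `Inf`,
#' which downstream binning places in the top similarity bin.
#'
#' The covariance `S` defaults to the empirical feature covariance over all
#' profiled genes; any user-specified covariance can be supplied. When `S`
#' is near-singular (reciprocal condition number below `rcond_tol`) a ridge
#' `epsilon * mean(diag(S)) * I` is added; if it is still not positive
#' definite an error reports the condition number. Genes with any missing
#' feature are excluded with a message.
#'
#' @param profiles an [epigenetic_profile()] (>= 2 complete genes).
#' @param covariance optional feature covariance matrix (default empirical).
#' @param epsilon ridge scale relative to the mean diagonal (default 1e-6).
#' @param rcond_tol reciprocal-condition-number threshold below which the
#'   ridge is applied (default 1e-12).
#' @return `data.table` with `gene_a`, `gene_b` (canonical order),
#'   `mahal_dist`, `similarity`; the covariance used is attached as the
#'   `"covariance"` attribute.
#' @export
mahalanobis_similarity <- function(profiles, covariance = NULL,
                                   epsilon = 1e-6, rcond_tol = 1e-12) {
  x <- unclass(profiles)
  complete <- stats::complete.cases(x)
  if (any(!complete))
    message("excluding ", sum(!complete), " gene(s) with missing features")
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2) stop("need >= 2 genes with complete features")
  S <- if (is.null(covariance)) stats::cov(x) else as.matrix(covariance)
  if (!isTRUE(all.equal(dim(S), rep(ncol(x), 2))))
    stop("covariance dimension does not match the feature count")
  if (rcond(S) < rcond_tol)
    S <- S + diag(epsilon * mean(diag(S)), ncol(S))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("covariance is singular after regularization (kappa = %.3g)",
                 kappa(S)))
  # whitening: d_Mahalanobis(a, b) = d_Euclidean(y_a, y_b) with y = x R^-1,
  # S = R'R, because (xa-xb)' S^-1 (xa-xb) = ||(xa-xb) R^-1||^2
  y <- t(backsolve(ch, t(x), transpose = TRUE))
  d <- as.matrix(stats::dist(y))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.table(gene_a = rownames(x)[ut[, 1]],
                    gene_b = rownames(x)[ut[, 2]],
                    mahal_dist = d[ut])
  out[, similarity := 1 / mahal_dist]   # d = 0 -> Inf sentinel
  out <- canonicalize_pairs(out)
  setkeyv(out, c("gene_a", "gene_b"))
  data.table::setattr(out, "covariance", S)
  out[]
}

#' Merge epigenetic similarity into a pair table
#'
#' @param pairs pair table keyed by `gene_a`, `gene_b`.
#' @param sim output of [mahalanobis_similarity()].
#' @return new pair table with `mahal_dist` and `similarity` columns
#'   (`NA` for pairs without profiles).
#' @export
annotate_pair_similarity <- function(pairs, sim) {
  out <- merge(data.table::copy(pairs),
               sim[, .(gene_a, gene_b, mahal_dist, similarity)],
               by = c("gene_a", "gene_b"), all.x = TRUE)
  setkeyv(out, c("gene_a", "gene_b"))
  out[]
}

#' Tissue-specific epigenetic enrichment per cluster
#'
#' For each (cluster, mark, tissue): observed = median signal of the
#' cluster's genes; expected = median signal of all clustered genes in that
#' (mark, tissue); enrichment = log2(observed / expected). Per (cluster,
#' mark), the coefficient of variation of the observed/expected ratio across
#' tissues summarizes how tissue-dependent the enrichment is (low CV =
#' a stable, archetype-like chromatin state; high CV = tissue-specific
#' regulation). An expected median of 0 leaves the enrichment `NA`.
#'
#' @param profiles an [epigenetic_profile()].
#' @param clusters named vector (gene -> cluster id) or a clustering object
#'   from [kmeans_pcc()] / [kmeans_select_k()].
#' @return list with `enrichment` (`data.table`: cluster, mark, tissue,
#'   observed, expected, log2_enrichment) and `mark_cv` (`data.table`:
#'   cluster, mark, cv).
#' @export
cluster_epigenetic_enrichment <- function(profiles, clusters) {
  if (inherits(clusters, "coex_clusters")) clusters <- clusters$cluster
  genes <- intersect(rownames(profiles), names(clusters))
  if (length(genes) == 0) stop("no overlap between profiles and clustering")
  x <- unclass(profiles)[genes, , drop = FALSE]
  cl <- clusters[genes]
  long <- data.table(
    gene = rep(genes, times = ncol(x)),
    cluster = rep(cl, times = ncol(x)),
    mark = rep(attr(profiles, "marks"), each = length(genes)),
    tissue = rep(attr(profiles, "tissues"), each = length(genes)),
    value = as.vector(x)
  )
  exp_tab <- long[!is.na(value), .(expected = stats::median(value)),
                  by = .(mark, tissue)]
  obs_tab <- long[!is.na(value), .(observed = stats::median(value)),
                  by = .(cluster, mark, tissue)]
  enr <- merge(obs_tab, exp_tab, by = c("mark", "tissue"))
  enr[, ratio := fifelse(expected > 0, observed / expected, NA_real_)]
  enr[, log2_enrichment := log2(ratio)]
  if (anyNA(enr$ratio))
    message(sum(is.na(enr$ratio)), " enrichment value(s) undefined (expected median 0)")
  cvt <- enr[, .(cv = stats::sd(ratio, na.rm = TRUE) /
                   mean(ratio, na.rm = TRUE)), by = .(cluster, mark)]
  setorderv(enr, c("cluster", "mark", "tissue"))
  list(enrichment = enr[, .(cluster, mark, tissue, observed, expected,
                            ratio, log2_enrichment)],
       mark_cv = cvt)
}

#' Coregulation as a function of epigenetic similarity
#'
#' Bins pairs into equal-count similarity bins and reports, per bin and per
#' layer, the percentage of pairs called coregulated. With planted
#' epigenetics-driven mRNA coexpression the mRNA curve rises with similarity
#' while the protein curve stays flat (buffering).
#'
#' @param pairs pair table with `similarity` and coregulation flag columns.
#' @param n_bins number of equal-count similarity bins (default 10).
#' @return `data.table`: bin, n, mean_similarity, plus one
#'   `pct_coregulated_<layer>` column per available flag.
#' @export
similarity_vs_coregulation <- function(pairs, n_bins = 10) {
  dt <- pairs[!is.na(similarity)]
  if (nrow(dt) == 0) stop("no pairs with similarity values")
  b <- quantile_bins(dt$similarity, n_bins)
  dt <- data.table::copy(dt)[, bin := b]
  flags <- intersect(c("coregulated_mrna", "coregulated_protein"), names(dt))
  if (length(flags) == 0) stop("no coregulation flag columns present")
  fin <- dt$similarity[is.finite(dt$similarity)]
  out <- dt[, c(list(n = .N,
                     mean_similarity = mean(pmin(similarity, max(fin)))),
                lapply(.SD, function(f) 100 * mean(f))),
            keyby = bin, .SDcols = flags]
  setnames(out, flags, sub("^coregulated", "pct_coregulated", flags))
  out[]
}
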