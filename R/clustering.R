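#' Correlation-profile matrix for clustering
#'
#' Represents each gene by its vector of PCCs to every other gene on one
#' layer: a symmetric gene x gene matrix with unit diagonal. Pairs absent
#' from the table (failed the overlap filter, or undefined PCC) are imputed
#' as 0 -- no evidence of coregulation.
#'
#' @param pairs pair table with a `pcc_<layer>` (or `pcc`) column.
#' @param layer `"mrna"` or `"protein"`.
#' @param genes optional gene universe (default: all genes in the table).
#' @return numeric matrix, genes x genes.
#' @export
pcc_profile_matrix <- function(pairs, layer = c("mrna", "protein"), genes = NULL) {
  layer <- match.arg(layer)
  pcol <- if (paste0("pcc_", layer) %in% names(pairs)) paste0("pcc_", layer) else "pcc"
  genes <- genes %||% sort(unique(c(pairs$gene_a, pairs$gene_b)))
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  diag(m) <- 1
  sub <- pairs[gene_a %in% genes & gene_b %in% genes]
  ia <- match(sub$gene_a, genes); ib <- match(sub$gene_b, genes)
  v <- sub[[pcol]]
  v[is.na(v)] <- 0
  m[cbind(ia, ib)] <- v
  m[cbind(ib, ia)] <- v
  m
}

#' K-means clustering of correlation profiles at fixed k
#'
#' Lloyd/Hartigan-Wong k-means (squared Euclidean) on the rows of a
#' correlation-profile matrix, keeping the best of `nstart` random
#' initializations. The random seed is set and recorded so the clustering is
#' reproducible bit-for-bit.
#'
#' @param profiles matrix from [pcc_profile_matrix()] (rows = genes).
#' @param k number of clusters.
#' @param nstart random restarts (default 3).
#' @param max_iter iteration cap (default 20).
#' @param seed RNG seed (default 1).
#' @return object of class `coex_clusters`: list with `k`, `cluster` (named
#'   integer vector), `variance_explained` (between-SS / total-SS), `seed`,
#'   `totss`, `betweenss`, `withinss`.
#' @export
kmeans_pcc <- function(profiles, k, nstart = 3, max_iter = 20, seed = 1) {
  if (nrow(profiles) <= k) stop("need more genes than clusters")
  totss_chk <- sum(sweep(profiles, 2, colMeans(profiles))^2)
  if (totss_chk < .Machine$double.eps * length(profiles))
    stop("degenerate input: all correlation profiles identical (total SS = 0)")
  set.seed(seed)
  km <- stats::kmeans(profiles, centers = k, nstart = nstart, iter.max = max_iter)
  structure(list(k = k,
                 cluster = setNames(km$cluster, rownames(profiles)),
                 variance_explained = km$betweenss / km$totss,
                 seed = seed, totss = km$totss, betweenss = km$betweenss,
                 withinss = km$withinss),
            class = "coex_clusters")
}

#' @export
print.coex_clusters <- function(x, ...) {
  cat(sprintf("k-means clustering: k = %d, %d genes, %.1f%% variance explained (seed %d)\n",
              x$k, length(x$cluster), 100 * x$variance_explained, x$seed))
  print(table(x$cluster))
  invisible(x)
}

#' K-means with the 50%-variance k-selection rule
#'
#' Scans k upward from 2 and selects the first k whose clustering explains
#' at least `target` of the variance (between sum of squares over total sum
#' of squares), the rule used to pick three mRNA and five protein clusters
#' in the tissue analysis. The scanned trajectory is attached as the
#' `"trajectory"` attribute; if no k up to `k_max` reaches the target an
#' error reports the trajectory.
#'
#' @inheritParams kmeans_pcc
#' @param k_max largest k to try (default 30).
#' @param target variance-explained threshold (default 0.5).
#' @return a `coex_clusters` object for the selected k.
#' @export
kmeans_select_k <- function(profiles, k_max = 30, target = 0.5,
                            nstart = 3, max_iter = 20, seed = 1) {
  traj <- numeric(0)
  for (k in 2:k_max) {
    fit <- kmeans_pcc(profiles, k, nstart = nstart, max_iter = max_iter,
                      seed = seed)
    traj[as.character(k)] <- fit$variance_explained
    if (fit$variance_explained >= target) {
      attr(fit, "trajectory") <- traj
      return(fit)
    }
  }
  stop("no k <= ", k_max, " reaches ", round(100 * target),
       "% variance explained; trajectory: ",
       paste(sprintf("k=%s: %.3f", names(traj), traj), collapse = ", "))
}

#' Subcellular localization enrichment per cluster
#'
#' Observed = percentage of a cluster's annotated genes in a compartment;
#' expected = that compartment's percentage among all annotated clustered
#' genes; enrichment = log2(observed / expected). Each (cluster,
#' compartment) cell is tested with a Pearson chi-squared on the 2x2 table
#' (in cluster or not) x (in compartment or not). Genes annotated to more
#' than one compartment must have been removed upstream.
#'
#' @param clusters named vector (gene -> cluster) or `coex_clusters` object.
#' @param localization named character vector (gene -> compartment, e.g.
#'   `"nucleus"`, `"mitochondrion"`, `"ER/Golgi"`).
#' @param compartments compartments to evaluate (default: all present).
#' @return `data.table`: cluster, compartment, n_cluster, observed_pct,
#'   expected_pct, log2_enrichment, chisq, p.value.
#' @export
localization_enrichment <- function(clusters, localization,
                                    compartments = NULL) {
  if (inherits(clusters, "coex_clusters")) clusters <- clusters$cluster
  genes <- intersect(names(clusters), names(localization))
  if (length(genes) == 0) stop("no localized genes in the clustering")
  cl <- clusters[genes]; loc <- localization[genes]
  compartments <- compartments %||% sort(unique(loc))
  missing_comp <- setdiff(compartments, unique(loc))
  if (length(missing_comp) > 0) {
    warning("compartment(s) absent from data skipped: ",
            paste(missing_comp, collapse = ", "))
    compartments <- setdiff(compartments, missing_comp)
  }
  res <- list()
  for (k in sort(unique(cl))) {
    for (comp in compartments) {
      in_cl <- cl == k; in_comp <- loc == comp
      obs <- 100 * mean(in_comp[in_cl])
      expd <- 100 * mean(in_comp)
      tab <- table(factor(in_cl, c(TRUE, FALSE)), factor(in_comp, c(TRUE, FALSE)))
      ht <- pearson_chisq(tab)
      res[[length(res) + 1]] <- data.table(
        cluster = k, compartment = comp, n_cluster = sum(in_cl),
        observed_pct = obs, expected_pct = expd,
        log2_enrichment = log2(obs / expd),
        chisq = ht$statistic, p.value = ht$p.value)
    }
  }
  rbindlist(res)
}

#' Cross-tabulate two cluster assignments
#'
#' Contingency table of cluster memberships, e.g. mRNA clusters against
#' protein clusters over their common gene universe, to find shared modules
#' across layers.
#'
#' @param a,b `coex_clusters` objects or named cluster vectors.
#' @return a contingency `table` (rows = clusters of `a`).
#' @export
cluster_overlap <- function(a, b) {
  if (inherits(a, "coex_clusters")) a <- a$cluster
  if (inherits(b, "coex_clusters")) b <- b$cluster
  genes <- intersect(names(a), names(b))
  if (length(genes) == 0) stop("cluster assignments share no genes")
  table(a = a[genes], b = b[genes])
}
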