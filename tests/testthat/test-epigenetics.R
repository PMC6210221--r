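toy_profiles <- function(values, genes = sprintf("g%02d", seq_len(nrow(values)))) {
  nm <- ncol(values)
  rownames(values) <- genes
  epigenetic_profile(values, marks = rep("H3K4me3", nm),
                     tissues = sprintf("t%02d", seq_len(nm)))
}

test_that("identity covariance reduces Mahalanobis to Euclidean distance", {
  vals <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 4), c(1, 1, 1, 1))
  prof <- toy_profiles(vals)
  sim <- mahalanobis_similarity(prof, covariance = diag(4))
  expect_equal(sim[gene_a == "g01" & gene_b == "g02", mahal_dist], 3)
  expect_equal(sim[gene_a == "g01" & gene_b == "g02", similarity], 1 / 3)
  # identical profiles: zero distance, infinite-similarity sentinel
  expect_equal(sim[gene_a == "g01" & gene_b == "g03", mahal_dist], 0)
  expect_equal(sim[gene_a == "g01" & gene_b == "g03", similarity], Inf)
})

test_that("pair distances equal the explicit quadratic-form oracle", {
  # needs clearly more genes than features: with n = p + 1 points the
  # whitened configuration is a regular simplex and all distances tie
  set.seed(21)
  vals <- matrix(rlnorm(32), nrow = 8)
  prof <- toy_profiles(vals)
  sim <- mahalanobis_similarity(prof)
  S <- attr(sim, "covariance")
  for (i in seq_len(nrow(sim))) {
    da <- oracle_mahalanobis(vals[match(sim$gene_a[i], rownames(prof)), ],
                             vals[match(sim$gene_b[i], rownames(prof)), ], S)
    expect_equal(sim$mahal_dist[i], da, tolerance = 1e-8)
  }
  # similarity ranking is the exact reverse of distance ranking
  expect_equal(order(sim$similarity), rev(order(sim$mahal_dist)))
})

test_that("Mahalanobis distances survive invertible affine transforms", {
  set.seed(22)
  vals <- matrix(rlnorm(60), nrow = 10)
  A <- matrix(rnorm(36), 6); while (abs(det(A)) < 0.1) A <- matrix(rnorm(36), 6)
  shifted <- vals %*% A + rep(1, 10) %o% runif(6, 0, 2)
  shifted <- shifted - min(shifted)            # keep signals non-negative
  d1 <- mahalanobis_similarity(toy_profiles(vals))
  d2 <- mahalanobis_similarity(toy_profiles(shifted))
  expect_equal(d1$mahal_dist, d2$mahal_dist, tolerance = 1e-6)
})

test_that("genes with missing features are excluded from similarity", {
  vals <- matrix(rlnorm(16), nrow = 4)
  vals[2, 3] <- NA
  prof <- toy_profiles(vals)
  expect_message(sim <- mahalanobis_similarity(prof, covariance = diag(4)),
                 "excluding 1 gene")
  expect_false("g02" %in% c(sim$gene_a, sim$gene_b))
})

test_that("long-format profile TSV round-trips into the matrix layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tmark\ttissue\tsignal",
               "g1\tH3K4me3\tliver\t2.5", "g1\tH3K27me3\tliver\t0.5",
               "g2\tH3K4me3\tliver\t1.0", "g2\tH3K27me3\tliver\t3.0"), path)
  prof <- load_epigenetic_profile(path)
  expect_setequal(rownames(prof), c("g1", "g2"))
  expect_equal(unclass(prof)["g1", "H3K4me3.liver"], 2.5)
  expect_equal(unclass(prof)["g2", "H3K27me3.liver"], 3.0)
})

test_that("cluster enrichment is log2 of cluster median over global median", {
  # 4 genes, one feature: cluster A = {4, 8}, cluster B = {2, 4}
  vals <- matrix(c(4, 8, 2, 4), ncol = 1)
  prof <- toy_profiles(vals, genes = c("a1", "a2", "b1", "b2"))
  cl <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  enr <- cluster_epigenetic_enrichment(prof, cl)$enrichment
  # global median = 4; cluster A median 6 -> log2(1.5); B median 3 -> log2(0.75)
  expect_equal(enr[cluster == "A", log2_enrichment], log2(6 / 4))
  expect_equal(enr[cluster == "B", log2_enrichment], log2(3 / 4))
  # a cluster whose median equals the global median scores 0
  vals2 <- matrix(c(2, 6, 2, 6), ncol = 1)
  prof2 <- toy_profiles(vals2, genes = c("a1", "a2", "b1", "b2"))
  enr2 <- cluster_epigenetic_enrichment(prof2, cl)$enrichment
  expect_equal(enr2$log2_enrichment, c(0, 0))
})

test_that("planted archetypes show stable enrichment with low CV", {
  panel <- default_panel()
  arch <- setNames(panel$truth$archetype, panel$truth$gene)
  res <- cluster_epigenetic_enrichment(panel$profiles, arch)
  k4 <- res$enrichment[cluster == "A1" & mark == "H3K4me3", log2_enrichment]
  expect_true(all(k4 > 0))                     # active mark high in A1 everywhere
  cv_a1 <- res$mark_cv[cluster == "A1" & mark == "H3K4me3", cv]
  cv_var <- res$mark_cv[cluster == "variable" & mark == "H3K4me3", cv]
  expect_lt(cv_a1, cv_var)                     # archetype stable, variable not
})

test_that("similarity bins aggregate coregulation consistently", {
  set.seed(23)
  n <- 500
  pairs <- data.table::data.table(
    gene_a = sprintf("a%03d", 1:n), gene_b = sprintf("b%03d", 1:n),
    similarity = runif(n), coregulated_mrna = FALSE,
    coregulated_protein = FALSE)
  out <- similarity_vs_coregulation(pairs)
  expect_equal(out$pct_coregulated_mrna, rep(0, 10))
  # one bin reproduces the overall fraction
  pairs[, coregulated_mrna := runif(n) < 0.2]
  one <- similarity_vs_coregulation(pairs, n_bins = 1)
  expect_equal(one$pct_coregulated_mrna, 100 * mean(pairs$coregulated_mrna))
  expect_equal(sum(similarity_vs_coregulation(pairs)$n), n)
})

test_that("epigenetically driven coexpression rises with similarity on mRNA only", {
  rec <- default_recovery()
  svc <- similarity_vs_coregulation(rec$pairs)
  lo <- svc[bin <= 3]; hi <- svc[bin >= 8]
  # strong planted rise on the mRNA layer ...
  expect_gt(mean(hi$pct_coregulated_mrna), mean(lo$pct_coregulated_mrna) + 10)
  expect_gt(cor(svc$bin, svc$pct_coregulated_mrna, method = "spearman"), 0.9)
  # ... with no corresponding protein increase (what protein coregulation
  # exists comes from the functional modules, not epigenetic similarity)
  expect_lt(mean(hi$pct_coregulated_protein),
            mean(lo$pct_coregulated_protein) + 1)
})
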