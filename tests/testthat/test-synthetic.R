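test_that("generator configs are validated", {
  expect_error(generator_config(rho_fun = 1), "\\[0, 1\\)")
  expect_error(generator_config(rho_epi = 0.7, rho_prox = 0.4),
               "negative residual variance")
  expect_error(generator_config(missing_mrna = 1), "\\[0, 1\\)")
  expect_error(generator_config(n_modules = 10, module_size = 100),
               "more genes than exist")
  expect_s3_class(generator_config(rho_fun = 0, rho_epi = 0, rho_prox = 0),
                  "generator_config")
})

test_that("the same seed reproduces the panel bit-for-bit", {
  a <- simulate_tissue_panel(generator_config(n_genes = 120), seed = 5)
  b <- simulate_tissue_panel(generator_config(n_genes = 120), seed = 5)
  expect_identical(unclass(a$mrna), unclass(b$mrna))
  expect_identical(unclass(a$protein), unclass(b$protein))
  expect_identical(a$truth, b$truth)
  expect_identical(unclass(a$profiles), unclass(b$profiles))
  expect_identical(a$pair_annotation$mirna, b$pair_annotation$mirna)
  c <- simulate_tissue_panel(generator_config(n_genes = 120), seed = 6)
  expect_false(identical(unclass(a$mrna), unclass(c$mrna)))
})

test_that("missingness rates land within one percent of the configuration", {
  panel <- default_panel()
  expect_lt(abs(mean(is.na(panel$mrna)) - 0.067), 0.01)
  expect_lt(abs(mean(is.na(panel$protein)) - 0.155), 0.01)
})

test_that("planted labels respect the generator's geometric promises", {
  panel <- default_panel()
  pt <- pair_truth(panel$truth)
  ann <- panel$annotation
  pos <- pt[planted == "positional"]
  d <- tss_distance(ann, pos$gene_a, pos$gene_b)
  expect_true(all(d < 2e5))
  tr <- setNames(panel$truth$archetype, panel$truth$gene)
  epi <- pt[planted == "epigenetic"]
  expect_true(all(tr[epi$gene_a] == tr[epi$gene_b]))
  expect_true(all(tr[epi$gene_a] %in% c("A1", "A2")))
  md <- setNames(panel$truth$module, panel$truth$gene)
  fun <- pt[planted == "functional"]
  expect_true(all(md[fun$gene_a] == md[fun$gene_b]))
})

test_that("null configuration yields uncorrelated layers and rare calls", {
  cfg <- generator_config(rho_fun = 0, rho_epi = 0, rho_prox = 0,
                          clustered_noise_scale = 1)
  panel <- simulate_tissue_panel(cfg, seed = 55)
  pairs <- suppressMessages(build_pair_table(panel$mrna, panel$protein))
  expect_lt(abs(mean(pairs$pcc_mrna)), 0.01)
  expect_lt(abs(mean(pairs$pcc_protein)), 0.01)
  expect_lt(mean(pairs$coregulated_mrna), 1e-3)
  expect_lt(mean(pairs$coregulated_both), 1e-3)
})

test_that("module pairs hit the configured correlation on both layers", {
  cfg <- generator_config(rho_fun = 0.8, rho_epi = 0, rho_prox = 0,
                          protein_noise_sd = 1)
  rs_m <- c(); rs_p <- c()
  for (s in 1:5) {
    panel <- simulate_tissue_panel(cfg, seed = 200 + s)
    md <- panel$truth[!is.na(module)]
    for (m in unique(md$module)) {
      genes <- md[module == m, gene]
      cm <- cor(t(unclass(panel$mrna)[genes, ]), use = "pairwise.complete.obs")
      cp <- cor(t(unclass(panel$protein)[genes, ]), use = "pairwise.complete.obs")
      rs_m <- c(rs_m, cm[upper.tri(cm)]); rs_p <- c(rs_p, cp[upper.tri(cp)])
    }
  }
  expect_lt(abs(mean(rs_m) - 0.8), 0.05)
  expect_lt(abs(mean(rs_p) - 0.8), 0.05)
})

test_that("empirical pair correlations match the factor-model covariance", {
  cfg <- generator_config(n_genes = 100, n_modules = 2, module_size = 10)
  devs <- c()
  for (w in 1:30) {
    panel <- simulate_tissue_panel(cfg, seed = 300 + w)
    tr <- panel$truth
    r <- cor(t(unclass(panel$mrna)), use = "pairwise.complete.obs")
    ut <- which(upper.tri(r), arr.ind = TRUE)
    same_mod <- !is.na(tr$module[ut[, 1]]) & !is.na(tr$module[ut[, 2]]) &
      tr$module[ut[, 1]] == tr$module[ut[, 2]]
    arch_a <- tr$archetype[ut[, 1]]; arch_b <- tr$archetype[ut[, 2]]
    arch_sign <- ifelse(arch_a %in% c("A1", "A2") & arch_b %in% c("A1", "A2"),
                        ifelse(arch_a == arch_b, 1, -1), 0)
    nb_sizes <- table(tr$neighborhood)
    same_nb <- tr$neighborhood[ut[, 1]] == tr$neighborhood[ut[, 2]]
    multi <- nb_sizes[as.character(tr$neighborhood[ut[, 1]])] > 1
    theory <- cfg$rho_fun * same_mod + cfg$rho_epi * arch_sign +
      cfg$rho_prox * (same_nb & multi)
    grp <- round(theory, 3)
    for (g in unique(grp)) {
      emp <- mean(r[ut][grp == g], na.rm = TRUE)
      devs <- c(devs, emp - g)
    }
  }
  expect_lt(mean(abs(devs)), 0.05)
})

test_that("protein layer of non-module pairs is buffered to zero correlation", {
  # on the raw generator output (before per-experiment centering, which
  # introduces a small common-mean component) buffering is exact
  panel <- default_panel()
  pt <- pair_truth(panel$truth)
  r <- cor(t(unclass(panel$protein)), use = "pairwise.complete.obs")
  ia <- match(pt$gene_a, rownames(r)); ib <- match(pt$gene_b, rownames(r))
  rp <- r[cbind(ia, ib)]
  expect_lt(abs(mean(rp[pt$planted != "functional"], na.rm = TRUE)), 0.01)
  expect_gt(mean(rp[pt$planted == "functional"], na.rm = TRUE), 0.5)
})

test_that("full-pipeline recovery reproduces the planted architecture", {
  rec <- default_recovery()
  pr <- rec$planted_recovery
  buf_m <- pr[planted %in% c("positional", "epigenetic"),
              sum(frac_coregulated_mrna * n) / sum(n)]
  buf_p <- pr[planted %in% c("positional", "epigenetic"),
              sum(frac_coregulated_protein * n) / sum(n)]
  expect_gte(buf_m, 4 * buf_p)
  expect_gt(buf_m, 0.1)
  expect_gte(rec$clustering$ari_protein_module, 0.8)
  expect_gt(rec$clustering$ari_mrna_archetype, 0.3)
  expect_gt(rec$classification$accuracy, 0.9)
  # functional coupling is tighter on the protein layer (complex-like)
  expect_gt(rec$module_pcc$median_pcc_protein, rec$module_pcc$median_pcc_mrna)
  # localization of the planted mitochondrial module is recoverable
  loc <- localization_enrichment(rec$clustering$protein,
                                 default_panel()$pair_annotation$localization)
  best <- loc[compartment == "mitochondrion"][which.max(log2_enrichment)]
  expect_gt(best$log2_enrichment, 0)
  expect_lt(best$p.value, 0.05)
})
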