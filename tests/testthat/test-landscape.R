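# synthetic pair table with independent continuous axes and a controllable
# coregulation rate -- a clean null for the landscape machinery
null_pairs <- function(n = 5000, rate = 0.1, seed = 61) {
  set.seed(seed)
  data.table::data.table(
    gene_a = sprintf("a%05d", 1:n), gene_b = sprintf("b%05d", 1:n),
    same_chromosome = TRUE,
    distance = runif(n, 1e3, 1e8),
    similarity = 1 / runif(n, 0.5, 20),
    pcc_mrna = rnorm(n, 0, 0.2),
    coregulated_mrna = runif(n) < rate)
}

test_that("landscape bins partition the eligible pairs into a balanced grid", {
  pairs <- null_pairs()
  l <- build_landscape(pairs, "mrna")
  expect_equal(sum(l$grid$n), nrow(pairs))
  expect_equal(nrow(l$grid), 100)
  for (ax in c("dist_bin", "sim_bin")) {
    counts <- table(l$pairs[[ax]])
    expect_equal(length(counts), 10L)
    expect_lte(max(counts) / min(counts), 1.2)
  }
  # inter-chromosomal pairs are not eligible
  pairs2 <- data.table::copy(pairs)
  pairs2[1:500, same_chromosome := FALSE]
  pairs2[1:500, distance := NA_real_]
  expect_equal(sum(build_landscape(pairs2, "mrna")$grid$n), nrow(pairs) - 500)
  expect_error(build_landscape(pairs[1:50], "mrna"), "eligible")
})

test_that("null landscape is flat at the planted rate", {
  pairs <- null_pairs(n = 20000, rate = 0.1)
  l <- build_landscape(pairs, "mrna")
  # every bin within 5 binomial SDs of the planted 10%
  tol <- 5 * sqrt(0.1 * 0.9 / min(l$grid$n)) * 100
  expect_true(all(abs(l$grid$pct_coregulated - 10) < tol))
})

test_that("a single coregulated pair lights exactly one bin", {
  pairs <- null_pairs(rate = 0)
  pairs[123, coregulated_mrna := TRUE]
  l <- build_landscape(pairs, "mrna")
  expect_equal(sum(l$grid$pct_coregulated > 0, na.rm = TRUE), 1L)
})

test_that("infinite similarity lands in the top similarity bin", {
  pairs <- null_pairs()
  pairs[7, similarity := Inf]
  l <- build_landscape(pairs, "mrna")
  expect_equal(l$pairs[gene_a == pairs$gene_a[7], sim_bin], 10L)
})

test_that("sector tests are calibrated under the null and detect shifts", {
  pairs <- null_pairs(n = 6000)
  l <- build_landscape(pairs, "mrna")
  st <- sector_test(l, n_repeats = 200, seed = 5)
  expect_setequal(st$name, c("close_similar", "far_similar",
                             "far_dissimilar", "close_dissimilar"))
  # same distribution as the background: mean p stays near uniform-mean
  expect_true(all(st$mean_p > 0.2 & st$mean_p < 0.8))
  # single repeat with a fixed seed is reproducible
  s1 <- sector_test(l, n_repeats = 1, seed = 99)
  s2 <- sector_test(l, n_repeats = 1, seed = 99)
  expect_identical(s1$mean_p, s2$mean_p)

  # shift the close/similar sector's PCCs upward by 0.5: detected strongly
  shifted <- data.table::copy(l)
  in_sec <- shifted$pairs$dist_bin <= 3 & shifted$pairs$sim_bin >= 8
  shifted$pairs[in_sec, pcc := pcc + 0.5]
  st2 <- sector_test(shifted, n_repeats = 200, seed = 5)
  expect_lt(st2[name == "close_similar", mean_p], 0.001)
  # the untouched opposite corner stays unremarkable
  expect_gt(st2[name == "far_dissimilar", mean_p], 0.05)
})

test_that("sector p values are calibrated under a global null", {
  # one exact-KS p per independent null world (background excluding the
  # sector, so sector and background are independent samples and the p
  # values are i.i.d. across worlds). The exact p lives on a discrete
  # lattice and is therefore conservative between attainable points; the
  # calibration property that matters is that the test never over-rejects
  # at any level, with the distribution centred near uniform.
  n_worlds <- 500
  ps <- vapply(seq_len(n_worlds), function(w) {
    l <- build_landscape(null_pairs(n = 1500, seed = 6000 + w), "mrna")
    sector_test(l, n_repeats = 1, seed = w, exact = TRUE,
                exclude_sector = TRUE)$mean_p[1]
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    mc <- 3 * sqrt(alpha * (1 - alpha) / n_worlds)
    expect_lte(mean(ps <= alpha), alpha + mc)
  }
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_gt(mean(ps <= 0.5), 0.35)   # conservative, but not degenerate
})

test_that("zoom conserves pairs and orders mean distances", {
  pairs <- null_pairs(n = 8000)
  l <- build_landscape(pairs, "mrna")
  z <- zoom_column(l)
  expect_equal(nrow(z$pairs), sum(l$pairs$dist_bin == 1))
  expect_equal(sum(z$grid$n), nrow(z$pairs))
  md <- z$grid[, .(m = sum(n * mean_distance, na.rm = TRUE) / sum(n)),
               keyby = dist_bin]$m
  expect_true(all(diff(md) > 0))
  expect_lt(max(z$pairs$distance), max(l$pairs$distance))
})

test_that("short-range ripple shows up only in the closest zoomed columns", {
  rec <- default_recovery()
  l <- build_landscape(rec$pairs, "mrna")
  z <- zoom_column(l)
  by_dist <- z$grid[, .(pct = sum(n * pct_coregulated, na.rm = TRUE) / sum(n)),
                    keyby = dist_bin]
  # neighborhood pairs (< 200 kb) sit in the closest zoom columns
  expect_gt(mean(by_dist$pct[1:2]), mean(by_dist$pct[8:10]) + 10)
})

test_that("protein landscape of buffered data stays flat across seeds", {
  for (s in 1:5) {
    panel <- simulate_tissue_panel(generator_config(), seed = 500 + s)
    pairs <- suppressMessages(build_pair_table(panel$mrna, panel$protein))
    pairs <- annotate_pair_distances(pairs, panel$annotation)
    pairs <- annotate_pair_similarity(pairs,
                                      mahalanobis_similarity(panel$profiles))
    l <- build_landscape(pairs, "protein")
    st <- sector_test(l, n_repeats = 50, seed = s)
    expect_true(all(st$mean_p > 0.01))
  }
})
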