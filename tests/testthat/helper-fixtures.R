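# shared fixtures and brute-force oracles used across test files

# small expression matrix with controllable missingness
toy_expr <- function(values, layer = "mrna",
                     genes = sprintf("g%02d", seq_len(nrow(values))),
                     tissues = sprintf("t%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, tissues)
  expression_matrix(values, layer)
}

# one default synthetic panel + recovery report, generated once per test run
.panel_cache <- new.env(parent = emptyenv())
default_panel <- function() {
  if (is.null(.panel_cache$panel))
    .panel_cache$panel <- simulate_tissue_panel(generator_config(), seed = 42)
  .panel_cache$panel
}
default_recovery <- function() {
  if (is.null(.panel_cache$recovery))
    .panel_cache$recovery <- suppressMessages(
      recovery_report(default_panel(), seed = 7))
  .panel_cache$recovery
}

## ---- brute-force oracles (kept deliberately naive) ----

# two-pass Pearson correlation and two-sided t-test p on the joint overlap
oracle_pcc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * pt(-abs(t), df = n - 2))
}

# step-up Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# step-down Holm from the definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in 1:m) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Mahalanobis distance by explicit quadratic form
oracle_mahalanobis <- function(xa, xb, S) {
  d <- xa - xb
  sqrt(drop(t(d) %*% solve(S) %*% d))
}

# Pearson chi-squared statistic sum((O-E)^2 / E)
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Mann-Whitney U of x against y plus exact two-sided p by full enumeration
oracle_mw <- function(x, y) {
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(ix) {
    sum(outer(pooled[ix], pooled[-ix], ">")) +
      0.5 * sum(outer(pooled[ix], pooled[-ix], "=="))
  })
  mu <- nx * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  list(u = u, p = p)
}

# two-sample KS statistics from the ecdf definition, plus exact p for the
# two-sided case by enumeration of all group assignments (tie-free data)
oracle_ks <- function(x, y, alternative = "two.sided") {
  grid <- sort(c(x, y))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  d <- switch(alternative,
              two.sided = max(abs(fx - fy)),
              less = max(fy - fx),       # x stochastically greater
              greater = max(fx - fy))
  pooled <- c(x, y)
  nx <- length(x)
  combs <- utils::combn(length(pooled), nx)
  ds <- apply(combs, 2, function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
    fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
    switch(alternative,
           two.sided = max(abs(fa - fb)),
           less = max(fb - fa),
           greater = max(fa - fb))
  })
  list(d = d, p = mean(ds >= d - 1e-12))
}
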