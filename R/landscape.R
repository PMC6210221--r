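#' Genomic-distance by epigenetic-similarity coregulation landscape
#'
#' Bins all eligible gene pairs into a 10 x 10 grid: equal-count deciles of
#' TSS distance crossed with equal-count deciles of epigenetic similarity
#' (ties kept together; infinite similarity of identical profiles falls in
#' the top similarity bin). Only intra-chromosomal pairs carry a linear
#' distance, so inter-chromosomal pairs are excluded. Per bin the pair
#' count, the percentage of pairs called coregulated on the requested layer,
#' and the mean pair distance are reported. Distance bin 1 holds the
#' closest pairs, similarity bin 1 the least similar.
#'
#' @param pairs pair table with `distance`, `same_chromosome`, `similarity`,
#'   `pcc_<layer>` and `coregulated_<layer>` columns.
#' @param layer `"mrna"` or `"protein"`.
#' @param n_bins bins per axis (default 10).
#' @return object of class `coex_landscape`: list with `pairs` (eligible
#'   pairs with `dist_bin`, `sim_bin`, `pcc`, `coregulated`), `grid`
#'   (`data.table`: dist_bin, sim_bin, n, pct_coregulated, mean_distance),
#'   `layer`, `n_bins`.
#' @export
build_landscape <- function(pairs, layer = c("mrna", "protein"), n_bins = 10) {
  layer <- match.arg(layer)
  pcol <- paste0("pcc_", layer); fcol <- paste0("coregulated_", layer)
  need <- c("distance", "same_chromosome", "similarity", pcol, fcol)
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) stop("pair table lacks column(s): ", paste(miss, collapse = ", "))
  elig <- pairs[same_chromosome & is.finite(distance) & !is.na(similarity) &
                  !is.na(get(pcol)) & !is.na(get(fcol))]
  if (nrow(elig) < n_bins * n_bins)
    stop("only ", nrow(elig), " eligible pairs; need >= ", n_bins * n_bins)
  dt <- elig[, .(gene_a, gene_b, distance, similarity,
                 pcc = get(pcol), coregulated = get(fcol))]
  dt[, dist_bin := quantile_bins(distance, n_bins)]
  dt[, sim_bin := quantile_bins(similarity, n_bins)]
  grid <- dt[, .(n = .N, pct_coregulated = 100 * mean(coregulated),
                 mean_distance = mean(distance)),
             keyby = .(dist_bin, sim_bin)]
  # make absent bin combinations explicit zeros
  full <- CJ(dist_bin = seq_len(max(dt$dist_bin)),
             sim_bin = seq_len(max(dt$sim_bin)))
  grid <- grid[full, on = c("dist_bin", "sim_bin")]
  grid[is.na(n), `:=`(n = 0L, pct_coregulated = NA_real_, mean_distance = NA_real_)]
  structure(list(pairs = dt, grid = grid, layer = layer, n_bins = n_bins),
            class = "coex_landscape")
}

#' @export
print.coex_landscape <- function(x, ...) {
  cat(sprintf("coregulation landscape [%s layer]: %d pairs in %d x %d bins\n",
              x$layer, nrow(x$pairs), max(x$grid$dist_bin), max(x$grid$sim_bin)))
  invisible(x)
}

#' Percent-coregulated grid of a landscape
#'
#' @param l a `coex_landscape`.
#' @return numeric matrix (distance bins x similarity bins) of the per-bin
#'   coregulated percentage.
#' @export
landscape_matrix <- function(l) {
  nd <- max(l$grid$dist_bin); ns <- max(l$grid$sim_bin)
  m <- matrix(NA_real_, nd, ns,
              dimnames = list(paste0("dist", seq_len(nd)),
                              paste0("sim", seq_len(ns))))
  m[cbind(l$grid$dist_bin, l$grid$sim_bin)] <- l$grid$pct_coregulated
  m
}

sector_definitions <- function(n_bins, sector_size) {
  s <- sector_size
  lo <- seq_len(s); hi <- n_bins - s + seq_len(s)
  list(close_similar    = list(dist = lo, sim = hi),  # sector 1
       far_similar      = list(dist = hi, sim = hi),  # sector 2
       far_dissimilar   = list(dist = hi, sim = lo),  # sector 3
       close_dissimilar = list(dist = lo, sim = lo))  # sector 4
}

#' Resampling Kolmogorov-Smirnov tests of landscape corner sectors
#'
#' Each corner sector is the `sector_size` x `sector_size` block of bins in
#' one corner of the landscape grid (1 = close/similar, 2 = far/similar,
#' 3 = far/dissimilar, 4 = close/dissimilar). For every repeat, a random
#' background sample of pairs equal in size to the sector is drawn without
#' replacement from all eligible pairs (sector pairs included unless
#' `exclude_sector`), and a two-sample KS test compares the sector's PCC
#' values against the background's; with `alternative = "greater"` the test
#' is one-sided for the sector being stochastically greater. The arithmetic
#' mean of the raw p values over repeats is reported per sector.
#'
#' @param l a `coex_landscape`.
#' @param sector_size corner block size in bins (default 3).
#' @param n_repeats background resamples (default 1000).
#' @param seed RNG seed.
#' @param alternative `"greater"` (sector PCCs stochastically greater,
#'   default) or `"two.sided"`.
#' @param exclude_sector drop the sector's own pairs from the background
#'   pool (default `FALSE`).
#' @param exact use the exact two-sample KS null distribution instead of
#'   the asymptotic tail (default `FALSE`; the asymptotic p is slightly
#'   non-uniform at moderate sector sizes, which matters only when the raw
#'   p values themselves are the object of study).
#' @return `data.table`: sector id (1-4), sector name, n_pairs, mean_p;
#'   seed and parameters in attributes.
#' @export
sector_test <- function(l, sector_size = 3, n_repeats = 1000, seed = 1,
                        alternative = c("greater", "two.sided"),
                        exclude_sector = FALSE, exact = FALSE) {
  alternative <- match.arg(alternative)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  defs <- sector_definitions(l$n_bins, sector_size)
  pool_all <- l$pairs$pcc
  # ks.test alternative "less": CDF of x lies below that of y, i.e. x
  # stochastically greater -- the direction meant by sector "greater"
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  set.seed(seed)
  out <- vector("list", length(defs))
  for (i in seq_along(defs)) {
    def <- defs[[i]]
    in_sector <- l$pairs$dist_bin %in% def$dist & l$pairs$sim_bin %in% def$sim
    v <- l$pairs$pcc[in_sector]
    if (length(v) == 0) stop("sector ", names(defs)[i], " is empty")
    pool <- if (exclude_sector) pool_all[!in_sector] else pool_all
    ps <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      bg <- pool[sample.int(length(pool), length(v))]
      ps[r] <- suppressWarnings(
        stats::ks.test(v, bg, alternative = ks_alt, exact = exact)$p.value)
    }
    out[[i]] <- data.table(sector = i, name = names(defs)[i],
                           n_pairs = length(v), mean_p = mean(ps))
  }
  res <- rbindlist(out)
  data.table::setattr(res, "seed", seed)
  data.table::setattr(res, "sector_size", sector_size)
  data.table::setattr(res, "n_repeats", n_repeats)
  res[]
}

#' Magnify the closest-distance column of a landscape
#'
#' Takes the pairs of the closest distance decile (distance bin 1) and
#' re-bins their distances into `n_bins` fresh deciles while keeping the
#' original similarity bins, zooming into the short-range regime where a
#' transcriptional ripple effect operates. The pair count is conserved and
#' the mean distance decreases strictly from the farthest to the closest
#' zoomed column.
#'
#' @param l a `coex_landscape`.
#' @param n_bins distance bins after the zoom (default: as the source).
#' @return a `coex_landscape` for the zoomed pairs (attribute
#'   `"zoomed" = TRUE`).
#' @export
zoom_column <- function(l, n_bins = NULL) {
  n_bins <- n_bins %||% l$n_bins
  sub <- l$pairs[dist_bin == 1L]
  dt <- data.table::copy(sub)
  dt[, dist_bin := quantile_bins(distance, n_bins)]
  grid <- dt[, .(n = .N, pct_coregulated = 100 * mean(coregulated),
                 mean_distance = mean(distance)),
             keyby = .(dist_bin, sim_bin)]
  full <- CJ(dist_bin = seq_len(max(dt$dist_bin)),
             sim_bin = seq_len(max(l$pairs$sim_bin)))
  grid <- grid[full, on = c("dist_bin", "sim_bin")]
  grid[is.na(n), `:=`(n = 0L, pct_coregulated = NA_real_, mean_distance = NA_real_)]
  structure(list(pairs = dt, grid = grid, layer = l$layer, n_bins = n_bins),
            class = "coex_landscape", zoomed = TRUE)
}
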