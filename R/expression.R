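#' Construct an expression matrix
#'
#' The central container of the package: a numeric gene x tissue matrix of
#' log2 ratios (missing values allowed) tagged with its expression layer.
#' Rows are genes, columns are tissues; both dimnames must be unique.
#'
#' @param values numeric matrix with gene rownames and tissue colnames.
#' @param layer `"mrna"` or `"protein"`.
#' @return the matrix with class `ExpressionMatrix` and a `layer` attribute.
#' @export
expression_matrix <- function(values, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and tissue colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate tissue names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(values, layer = layer, class = c("ExpressionMatrix", class(values)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s layer]: %d genes x %d tissues, %.1f%% missing\n",
              attr(x, "layer"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Layer tag of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return `"mrna"` or `"protein"`.
#' @export
expr_layer <- function(x) attr(x, "layer")

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row; the first column holds gene identifiers, the
#' remaining columns one tissue each. Empty cells and `NA` are read as
#' missing. Duplicate gene identifiers and non-numeric cells are rejected
#' with an error naming the offending row/column.
#'
#' @param path TSV file path.
#' @param layer `"mrna"` or `"protein"`.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  if (ncol(raw) < 2) stop("expected a gene-id column plus at least one tissue column")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed numeric cell at gene '%s', tissue '%s': '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, ], drop = TRUE][1]))
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num, layer)
}

#' Write an expression matrix to a tab-separated file
#'
#' Inverse of [load_expression()]: missing values are written as empty cells
#' so that a write/read round trip is value-identical including missingness.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Median-ratio normalization of a TPM matrix
#'
#' Converts raw TPM abundances into per-gene log2 ratios relative to each
#' gene's median across tissues (the RNA analogue of a Super-SILAC reference):
#' `value[g, t] = log2(TPM[g, t] / median(TPM[g, ]))`, the median taken over
#' the gene's non-missing tissues. A TPM of exactly 0 is treated as a dropout
#' and set to missing *before* the median is computed (`zero_as_missing`);
#' genes whose median is 0 or undefined are dropped with a warning. By
#' construction each retained gene row has median 0 over its non-missing
#' entries (up to the even-count quantile interpolation).
#'
#' @param raw numeric gene x tissue matrix of TPM values (>= 0).
#' @param zero_as_missing treat TPM == 0 as missing (default `TRUE`).
#' @return an `ExpressionMatrix` on the mRNA layer.
#' @export
normalize_tpm <- function(raw, zero_as_missing = TRUE) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (zero_as_missing) raw[raw == 0] <- NA_real_
  med <- apply(raw, 1, stats::median, na.rm = TRUE)
  drop <- !is.finite(med) | med == 0
  if (any(drop)) {
    warning(sum(drop), " gene(s) with zero or undefined median TPM dropped: ",
            paste(utils::head(rownames(raw)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    raw <- raw[!drop, , drop = FALSE]
    med <- med[!drop]
  }
  expression_matrix(log2(raw / med), layer = "mrna")
}

#' Restrict two layers to genes with sufficient shared tissue coverage
#'
#' Keeps genes measured in at least `min_tissues` tissues simultaneously
#' (non-missing on both layers in the same tissue), the coverage rule used
#' before any correlation is computed. Matrices are restricted to the common
#' gene set and a shared tissue ordering.
#'
#' @param mrna,protein `ExpressionMatrix` objects sharing a tissue namespace.
#' @param min_tissues minimum number of jointly observed tissues (default 8).
#' @return list with elements `mrna` and `protein`, gene-aligned.
#' @export
filter_min_overlap <- function(mrna, protein, min_tissues = 8) {
  tissues <- intersect(colnames(mrna), colnames(protein))
  if (length(tissues) == 0) stop("no shared tissues between the two layers")
  genes <- intersect(rownames(mrna), rownames(protein))
  if (length(genes) == 0) stop("no shared genes between the two layers")
  m <- mrna[genes, tissues, drop = FALSE]
  p <- protein[genes, tissues, drop = FALSE]
  joint <- rowSums(!is.na(m) & !is.na(p))
  keep <- joint >= min_tissues
  if (!any(keep)) stop("no gene has >= ", min_tissues, " jointly observed tissues")
  list(mrna = expression_matrix(m[keep, , drop = FALSE], "mrna"),
       protein = expression_matrix(p[keep, , drop = FALSE], "protein"))
}

#' Center each tissue column at zero
#'
#' Subtracts the per-tissue mean over non-missing entries, so that every
#' experiment (tissue column) is centered at 0 before correlations are
#' computed.
#'
#' @param m an `ExpressionMatrix`.
#' @return the centered `ExpressionMatrix`.
#' @export
center_per_experiment <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  out <- sweep(unclass(m), 2, mu, "-")
  expression_matrix(out, attr(m, "layer"))
}

#' Average replicate tissue columns into one
#'
#' Collapses columns that map to the same canonical tissue name by averaging
#' their non-missing values (e.g. kidney cortex and medulla into a single
#' kidney column). Columns not named in `map` are kept unchanged.
#'
#' @param m an `ExpressionMatrix`.
#' @param map named character vector: `c(old_column = "canonical_name", ...)`.
#' @return an `ExpressionMatrix` with collapsed columns.
#' @export
collapse_tissue_replicates <- function(m, map) {
  canon <- colnames(m)
  hit <- canon %in% names(map)
  canon[hit] <- unname(map[canon[hit]])
  groups <- split(seq_len(ncol(m)), canon)
  out <- vapply(groups, function(ix) rowMeans(m[, ix, drop = FALSE], na.rm = TRUE),
                numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  # preserve first-appearance column order
  ord <- order(vapply(groups, min, integer(1)))
  expression_matrix(out[, ord, drop = FALSE], attr(m, "layer"))
}
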