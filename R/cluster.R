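# Semi-unsupervised clustering: probes (rows) are clustered
# agglomeratively while samples (columns) stay fixed in known
# (cancer, tissue) blocks.

#' Hierarchical clustering order for one matrix axis
#'
#' Agglomerative clustering (default Euclidean distance, average linkage /
#' UPGMA) of the rows or columns of a beta matrix. Missing values are
#' mean-imputed within each clustered item before distances are computed.
#'
#' @param m Numeric matrix.
#' @param axis `"rows"` (default) or `"columns"`.
#' @param metric Distance metric for `stats::dist` (default `"euclidean"`).
#' @param linkage Agglomeration method for `stats::hclust` (default
#'   `"average"`).
#' @return A `cluster_result`: list with `order` (leaf permutation),
#'   `labels`, `merge`, `height`, the `hclust` object, `metric`, `linkage`.
#' @export
hierarchical_order <- function(m, axis = c("rows", "columns"),
                               metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  x <- if (axis == "rows") m else t(m)
  if (nrow(x) < 2L) stop("need >= 2 items on the clustered axis")
  if (anyNA(x)) {
    for (i in seq_len(nrow(x))) {
      miss <- is.na(x[i, ])
      if (all(miss)) stop("item ", rownames(x)[i], " is entirely missing")
      x[i, miss] <- mean(x[i, ], na.rm = TRUE)
    }
  }
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  structure(list(order = hc$order, labels = hc$labels, merge = hc$merge,
                 height = hc$height, hclust = hc, metric = metric,
                 linkage = linkage, imputation = "per-item mean"),
            class = "cluster_result")
}

#' Export a cluster tree as a Newick string
#' @param result A [hierarchical_order()] result.
#' @param path Optional file to write the tree to.
#' @return Newick string, invisibly if `path` is given.
#' @export
cluster_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  tree <- ape::as.phylo(result$hclust)
  nwk <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

# Column order with samples grouped in (cancer, tissue) blocks, preserving
# the original within-group order (the "semi-unsupervised" contract).
grouped_column_order <- function(sample_ids, manifest) {
  manifest <- validate_manifest(manifest)
  groups <- manifest_groups(manifest)
  ordered <- unlist(groups$samples)
  ordered[ordered %in% sample_ids]
}

#' Export a heatmap of a row-ordered matrix with fixed column blocks
#'
#' Writes a TSV twin of the reordered matrix (bit-exact values) and,
#' optionally, a rendered heatmap. Columns are never reordered within a
#' (cancer, tissue) block.
#'
#' @param m Beta matrix.
#' @param row_order Permutation of `1..nrow(m)` (e.g. the `order` of
#'   [hierarchical_order()]).
#' @param manifest Optional sample manifest; if given, columns are arranged
#'   in (cancer, tissue) blocks with per-block annotation colours.
#' @param path Optional PNG path for the rendered heatmap (via `pheatmap`).
#' @param tsv_path Optional path for the reordered TSV.
#' @return The reordered matrix, invisibly.
#' @export
heatmap_export <- function(m, row_order, manifest = NULL, path = NULL,
                           tsv_path = NULL) {
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix")
  if (length(row_order) != nrow(m) ||
      !setequal(row_order, seq_len(nrow(m)))) {
    stop("row_order must be a permutation of 1..", nrow(m))
  }
  col_order <- colnames(m)
  ann_col <- NULL
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    col_order <- grouped_column_order(colnames(m), manifest)
    if (length(col_order) != ncol(m)) {
      stop("manifest does not cover all matrix samples")
    }
    idx <- match(col_order, manifest$sample_id)
    ann_col <- data.frame(cancer = manifest$cancer_code[idx],
                          tissue = manifest$tissue_type[idx],
                          row.names = col_order)
  }
  out <- m[row_order, col_order, drop = FALSE]
  if (!is.null(tsv_path)) write_beta_matrix(out, tsv_path)
  if (!is.null(path)) {
    pheatmap::pheatmap(out, cluster_rows = FALSE, cluster_cols = FALSE,
                       annotation_col = ann_col, show_colnames = ncol(out) <= 30,
                       filename = path, silent = TRUE)
  }
  invisible(out)
}
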