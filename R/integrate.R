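# Methylation-expression integration: pair filtered CpGs with expression
# features of their annotated genes and keep strongly correlated pairs.
# Deliberately plain per-pair Pearson correlation on matched samples (the
# latent-space multi-omics integration of the original workflow is out of
# scope); output metadata says so.

#' Candidate probe-transcript pairs
#'
#' One candidate per (probe, expression feature) where the feature maps to a
#' gene the probe is annotated to (case-insensitive symbol match) and the
#' two matrices share at least 3 samples for the pair.
#'
#' @param annotation Probe annotation data frame.
#' @param beta Beta matrix (probes x samples).
#' @param expression Expression matrix (features x samples).
#' @param feature_genes Optional named character vector mapping feature ids
#'   to gene symbols; by default a feature's own id is taken as its gene
#'   symbol.
#' @return Data frame with `probe_id`, `feature_id`, `gene_symbol`.
#' @export
match_probe_transcript <- function(annotation, beta, expression,
                                   feature_genes = NULL) {
  shared <- intersect(colnames(beta), colnames(expression))
  if (length(shared) == 0L) stop("no shared samples between beta and expression")
  feats <- rownames(expression)
  fg <- if (is.null(feature_genes)) stats::setNames(feats, feats)
        else feature_genes[feats]
  fg_up <- toupper(fg)
  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  gene_lists <- split_multi(ann$gene_symbols)
  out <- vector("list", nrow(beta))
  for (i in seq_len(nrow(beta))) {
    genes <- toupper(gene_lists[[i]])
    if (length(genes) == 0L) next
    hit <- which(fg_up %in% genes)
    if (length(hit) == 0L) next
    out[[i]] <- data.frame(probe_id = rownames(beta)[i],
                           feature_id = feats[hit],
                           gene_symbol = unname(fg[hit]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(probe_id = character(), feature_id = character(),
                      gene_symbol = character(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation of matched probe-transcript pairs
#'
#' Computes, for each candidate pair, the Pearson correlation between probe
#' beta values and (by default log2(FPKM+1)-transformed) expression over the
#' shared non-missing samples, and keeps pairs with `|r| >= cutoff`. Pairs
#' with fewer than 3 complete samples or zero variance in either vector are
#' dropped with a message.
#'
#' @param pairs Candidate pairs from [match_probe_transcript()].
#' @param beta Beta matrix.
#' @param expression Expression matrix (FPKM scale).
#' @param cutoff Absolute-correlation cutoff in \[0, 1\] (default 0.6).
#' @param log2_transform Log2(FPKM+1)-transform expression first (default
#'   `TRUE`).
#' @return Data frame `probe_id`, `feature_id`, `gene_symbol`, `r`, `n`,
#'   `direction` (`positive`/`negative`), with attribute `metadata`.
#' @export
correlate_pairs <- function(pairs, beta, expression, cutoff = 0.6,
                            log2_transform = TRUE) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  shared <- intersect(colnames(beta), colnames(expression))
  if (length(shared) == 0L) stop("no shared samples between beta and expression")
  expr <- expression[, shared, drop = FALSE]
  if (log2_transform) expr <- log2(expr + 1)
  b <- beta[, shared, drop = FALSE]
  keep <- vector("list", nrow(pairs))
  dropped <- 0L
  for (i in seq_len(nrow(pairs))) {
    x <- b[pairs$probe_id[i], ]
    y <- expr[pairs$feature_id[i], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) { dropped <- dropped + 1L; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      dropped <- dropped + 1L
      next
    }
    r <- stats::cor(x[ok], y[ok], method = "pearson")
    if (abs(r) < cutoff) next
    keep[[i]] <- data.frame(probe_id = pairs$probe_id[i],
                            feature_id = pairs$feature_id[i],
                            gene_symbol = pairs$gene_symbol[i],
                            r = r, n = sum(ok),
                            direction = if (r >= 0) "positive" else "negative",
                            stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    message(dropped, " pair(s) dropped (fewer than 3 complete samples or ",
            "zero variance)")
  }
  out <- do.call(rbind, keep)
  if (is.null(out)) {
    out <- data.frame(probe_id = character(), feature_id = character(),
                      gene_symbol = character(), r = numeric(), n = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    method = "per-pair Pearson correlation on matched samples",
    note = "plain correlation, not a latent-component correlation",
    cutoff = cutoff, log2_transform = log2_transform)
  out
}
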