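# Comparative tumor-vs-normal differential methylation: Mann-Whitney rank
# test per probe, BH adjustment, log2 fold change of group mean betas, and
# volcano classification, usually on a pathway-restricted probe subset.

#' Mann-Whitney U test for two independent groups
#'
#' U counts (tumor, normal) pairs with tumor > normal, ties counted 1/2.
#' The two-sided p-value is exact (network enumeration) when the smaller
#' group has at most 8 values and there are no ties, otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param tumor_values,normal_values Numeric vectors; missing values are
#'   dropped, at least one value must remain in each group.
#' @return List with `u` and `p_value`.
#' @export
mann_whitney_u <- function(tumor_values, normal_values) {
  x <- tumor_values[!is.na(tumor_values)]
  y <- normal_values[!is.na(normal_values)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups need >= 1 non-missing value")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(u = u, p_value = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && min(n1, n2) <= 8L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  list(u = u, p_value = min(p, 1))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return q-values in the original order, each >= its raw p, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change of group mean beta values
#'
#' `log2((mean(tumor) + epsilon) / (mean(normal) + epsilon))`; the epsilon
#' guards zero means (an all-unmethylated group).
#'
#' @param tumor_values,normal_values Numeric vectors (missing dropped).
#' @param epsilon Small positive guard, default `1e-6`.
#' @param stat `"mean"` (default) or `"median"` group summary.
#' @return Finite log2 ratio.
#' @export
log2_fold_change <- function(tumor_values, normal_values, epsilon = 1e-6,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  mt <- f(tumor_values, na.rm = TRUE)
  mn <- f(normal_values, na.rm = TRUE)
  if (is.na(mt) || is.na(mn)) stop("both groups need >= 1 non-missing value")
  log2((mt + epsilon) / (mn + epsilon))
}

#' Volcano classification of one test result
#'
#' Hypermethylated if significant and `log2_fc > fc_cut`; hypomethylated if
#' significant and `log2_fc < -fc_cut`; otherwise not significant. Both
#' comparisons are strict.
#'
#' @param q_or_p Significance value compared against `alpha` (strict `<`).
#' @param log2_fc Log2 fold change.
#' @param alpha Significance cutoff in (0, 1), default 0.05.
#' @param fc_cut Positive fold-change cutoff, default 1.
#' @return Character vector over inputs: `"hyper"`, `"hypo"` or
#'   `"not_significant"`.
#' @export
volcano_classify <- function(q_or_p, log2_fc, alpha = 0.05, fc_cut = 1) {
  stopifnot(alpha > 0, alpha < 1, fc_cut > 0)
  out <- rep("not_significant", length(q_or_p))
  sig <- !is.na(q_or_p) & q_or_p < alpha
  out[sig & log2_fc > fc_cut] <- "hyper"
  out[sig & log2_fc < -fc_cut] <- "hypo"
  out
}

#' Pathway-restricted differential methylation
#'
#' Subsets the beta matrix to probes of a gene set (optionally restricted to
#' CpG islands / promoter probes), then for each cancer runs a per-probe
#' tumor-vs-normal Mann-Whitney test with log2 fold change of mean betas,
#' adjusts p-values (BH by default, within the tested subset and per
#' cancer), and classifies each probe on the volcano plane.
#'
#' @param m Beta matrix.
#' @param manifest Sample manifest.
#' @param annotation Probe annotation.
#' @param gene_set Gene symbols (or a [read_gene_sets()] element); `NULL`
#'   keeps all annotated probes.
#' @param region_filter,promoter_only Passed to [subset_probes()].
#' @param adjust `"BH"` (default, gate on FDR q) or `"none"` (gate on raw p).
#' @param alpha Significance cutoff (default 0.05).
#' @param fc_cut Log2 fold-change cutoff (default 1).
#' @param fc_stat `"mean"` (default) or `"median"` fold-change summary.
#' @param epsilon Guard for [log2_fold_change()].
#' @return List with `records` (one row per probe per cancer: u_statistic,
#'   p_value, q_value, log2_fc, neg_log10_p, volcano_class), `summary` (per
#'   cancer: n_hyper, n_hypo, n_genes over significant probes), and
#'   `metadata` (the options used).
#' @export
run_pathway_diffmeth <- function(m, manifest, annotation, gene_set = NULL,
                                 region_filter = NULL, promoter_only = FALSE,
                                 adjust = c("BH", "none"), alpha = 0.05,
                                 fc_cut = 1, fc_stat = c("mean", "median"),
                                 epsilon = 1e-6) {
  adjust <- match.arg(adjust)
  fc_stat <- match.arg(fc_stat)
  groups <- manifest_groups(manifest, m)
  sub <- subset_probes(m, annotation, gene_set, region_filter, promoter_only)
  cancers <- unique(groups$cancer_code)
  meta <- list(adjust = adjust, alpha = alpha, fc_cut = fc_cut,
               fc_stat = fc_stat, epsilon = epsilon,
               adjust_scope = "per cancer, within the tested probe subset",
               n_probes_tested = nrow(sub))
  empty <- data.frame(probe_id = character(), cancer_code = character(),
                      u_statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), log2_fc = numeric(),
                      neg_log10_p = numeric(), volcano_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sub) == 0L) {
    warning("empty probe subset: no tests run")
    return(list(records = empty,
                summary = data.frame(cancer_code = character(),
                                     n_hyper = integer(), n_hypo = integer(),
                                     n_genes = integer()),
                metadata = meta))
  }
  gene_lists <- split_multi(annotation$gene_symbols[
    match(rownames(sub), annotation$probe_id)])
  names(gene_lists) <- rownames(sub)
  rec_list <- vector("list", length(cancers))
  sum_list <- vector("list", length(cancers))
  for (k in seq_along(cancers)) {
    cc <- cancers[k]
    ts <- groups$samples[[which(groups$cancer_code == cc &
                                groups$tissue_type == "primary_tumor")]]
    ns <- groups$samples[[which(groups$cancer_code == cc &
                                groups$tissue_type == "normal_tissue")]]
    tm <- sub[, ts, drop = FALSE]
    nm <- sub[, ns, drop = FALSE]
    res <- lapply(seq_len(nrow(sub)), function(i) {
      mw <- mann_whitney_u(tm[i, ], nm[i, ])
      c(mw$u, mw$p_value,
        log2_fold_change(tm[i, ], nm[i, ], epsilon, fc_stat))
    })
    res <- do.call(rbind, res)
    q <- bh_adjust(res[, 2L])
    gate <- if (adjust == "BH") q else res[, 2L]
    vc <- volcano_classify(gate, res[, 3L], alpha, fc_cut)
    rec_list[[k]] <- data.frame(
      probe_id = rownames(sub), cancer_code = cc,
      u_statistic = res[, 1L], p_value = res[, 2L], q_value = q,
      log2_fc = res[, 3L], neg_log10_p = -log10(pmax(res[, 2L], 1e-300)),
      volcano_class = vc, stringsAsFactors = FALSE)
    sig_genes <- unique(toupper(unlist(
      gene_lists[rownames(sub)[vc != "not_significant"]])))
    sum_list[[k]] <- data.frame(cancer_code = cc,
                                n_hyper = sum(vc == "hyper"),
                                n_hypo = sum(vc == "hypo"),
                                n_genes = length(sig_genes))
  }
  list(records = do.call(rbind, rec_list),
       summary = do.call(rbind, sum_list),
       metadata = meta)
}

#' Volcano plot of differential methylation records
#'
#' Log2 fold change against -log10 p, dashed cutoff lines, hypermethylated
#' probes in green and hypomethylated in red.
#'
#' @param records The `records` data frame of [run_pathway_diffmeth()].
#' @param path Optional PNG/SVG output path (written via `ggplot2::ggsave`).
#' @param alpha,fc_cut Cutoff lines to draw.
#' @return The ggplot object, invisibly.
#' @export
plot_volcano <- function(records, path = NULL, alpha = 0.05, fc_cut = 1) {
  p <- ggplot2::ggplot(records, ggplot2::aes(
         x = .data$log2_fc, y = .data$neg_log10_p,
         colour = .data$volcano_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(hyper = "forestgreen",
                                            hypo = "red3",
                                            not_significant = "grey60")) +
    ggplot2::geom_vline(xintercept = c(-fc_cut, fc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(~cancer_code) +
    ggplot2::labs(x = "log2 fold change (beta)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
  invisible(p)
}
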