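# Synthetic multi-cancer cohort generator. Group beta values are drawn from
# Beta distributions (honouring the [0,1] support): a "high" methylated
# state, a "low" unmethylated state and a "mid" background state. Planted
# probes receive the group pattern their class requires; background probes
# are mid-state in every group.

#' Configuration for a simulated cohort
#'
#' @param cancer_codes 2-12 cancer code labels.
#' @param n_tumor,n_normal Paired sample counts per cancer (defaults 20/10).
#' @param n_background_probes Probes with no group structure (default 500).
#' @param planted Data frame with columns `call_class` (one of
#'   `cancer_hyper`, `cancer_hypo`, `tissue_hyper`, `tissue_hypo`),
#'   `target_cancer`, `count`; or `NULL` for background only.
#' @param high_state,low_state,mid_state Beta-distribution shape pairs for
#'   the methylated, unmethylated and background states. Defaults
#'   `(50, 5)` (mean ~0.91), `(2, 30)` (mean ~0.06) and `(10, 10)`
#'   (mean 0.5) give strong separation around the 0.6/0.3 thresholds.
#' @param missing_rate Probability a cell is set missing, in \[0, 1).
#' @param expression Optional `list(rho = , base_log2 = , slope = )`; if
#'   given, matched expression is generated for the planted probes via
#'   [simulate_expression()].
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(cancer_codes, n_tumor = 20L, n_normal = 10L,
                              n_background_probes = 500L, planted = NULL,
                              high_state = c(50, 5), low_state = c(2, 30),
                              mid_state = c(10, 10), missing_rate = 0,
                              expression = NULL, seed = 1L) {
  cancer_codes <- as.character(cancer_codes)
  if (length(cancer_codes) < 2L || length(cancer_codes) > 12L) {
    stop("need between 2 and 12 cancer codes (got ", length(cancer_codes), ")")
  }
  if (anyDuplicated(cancer_codes)) stop("duplicate cancer codes")
  stopifnot(n_tumor >= 1L, n_normal >= 1L, n_background_probes >= 0L,
            missing_rate >= 0, missing_rate < 1,
            all(c(high_state, low_state, mid_state) > 0))
  if (!is.null(planted)) {
    need <- c("call_class", "target_cancer", "count")
    if (!all(need %in% colnames(planted))) {
      stop("planted needs columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(planted$call_class, CALL_CLASSES)
    if (length(bad) > 0L) stop("unknown call_class: ", paste(bad, collapse = ", "))
    bad <- setdiff(planted$target_cancer, cancer_codes)
    if (length(bad) > 0L) {
      stop("planted target cancer(s) not in cancer_codes: ",
           paste(bad, collapse = ", "))
    }
    if (any(planted$count < 1L)) stop("planted counts must be >= 1")
  }
  structure(list(cancer_codes = cancer_codes, n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 n_background_probes = as.integer(n_background_probes),
                 planted = planted, high_state = high_state,
                 low_state = low_state, mid_state = mid_state,
                 missing_rate = missing_rate, expression = expression,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Which state each (cancer, tissue) group takes for a planted class.
plant_states <- function(call_class, target_cancer, groups) {
  is_target <- groups$cancer_code == target_cancer
  is_tumor <- groups$tissue_type == "primary_tumor"
  switch(call_class,
    cancer_hyper = ifelse(is_target & is_tumor, "high", "low"),
    cancer_hypo  = ifelse(is_target & is_tumor, "low", "high"),
    tissue_hyper = ifelse(is_target, "high", "low"),
    tissue_hypo  = ifelse(is_target, "low", "high"),
    stop("unknown call class: ", call_class))
}

#' Simulate a paired multi-cancer methylation cohort
#'
#' Generates a beta matrix over planted-then-background probes, the matching
#' manifest, a truth table of planted (class, target) labels, a per-probe
#' gene annotation (planted probes: CpG island, promoter-associated;
#' background probes: open sea, gene body), gene sets for the planted and
#' background genes, and optionally matched expression.
#'
#' Beta values are drawn row by row (probes in fixed order, groups in
#' manifest order) from a single stream seeded with `config$seed`, so
#' enlarging `n_background_probes` never perturbs earlier probes' draws.
#' Missingness uses a separate stream (`seed + 1`), expression a third
#' (`seed + 2`).
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort`: list with `beta`, `manifest`, `truth`,
#'   `annotation`, `gene_sets`, optional `expression`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cc <- config$cancer_codes
  manifest <- do.call(rbind, lapply(cc, function(c1) {
    data.frame(
      sample_id = c(sprintf("%s_T%02d", c1, seq_len(config$n_tumor)),
                    sprintf("%s_N%02d", c1, seq_len(config$n_normal))),
      cancer_code = c1,
      tissue_type = rep(TISSUE_TYPES, c(config$n_tumor, config$n_normal)),
      stringsAsFactors = FALSE)
  }))
  groups <- manifest_groups(manifest)

  planted <- config$planted
  truth_rows <- list()
  if (!is.null(planted) && nrow(planted) > 0L) {
    truth_rows <- lapply(seq_len(nrow(planted)), function(i) {
      data.frame(call_class = planted$call_class[i],
                 target_cancer = planted$target_cancer[i],
                 stringsAsFactors = FALSE)[rep(1L, planted$count[i]), ,
                                           drop = FALSE]
    })
  }
  truth <- do.call(rbind, c(truth_rows,
                            list(data.frame(call_class = character(),
                                            target_cancer = character()))))
  n_planted <- nrow(truth)
  n_probes <- n_planted + config$n_background_probes
  if (n_probes == 0L) stop("no probes to simulate")
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  if (n_planted > 0L) {
    truth <- data.frame(probe_id = probe_ids[seq_len(n_planted)], truth,
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(probe_id = character(), call_class = character(),
                        target_cancer = character(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL

  shapes <- list(high = config$high_state, low = config$low_state,
                 mid = config$mid_state)
  group_sizes <- lengths(groups$samples)
  sample_order <- unlist(groups$samples)

  set.seed(config$seed)
  beta <- matrix(NA_real_, n_probes, nrow(manifest),
                 dimnames = list(probe_ids, sample_order))
  for (i in seq_len(n_probes)) {
    states <- if (i <= n_planted) {
      plant_states(truth$call_class[i], truth$target_cancer[i], groups)
    } else {
      rep("mid", nrow(groups))
    }
    row <- unlist(lapply(seq_len(nrow(groups)), function(g) {
      sh <- shapes[[states[g]]]
      stats::rbeta(group_sizes[g], sh[1L], sh[2L])
    }))
    beta[i, ] <- row
  }
  beta <- beta[, manifest$sample_id, drop = FALSE]

  if (config$missing_rate > 0) {
    set.seed(config$seed + 1L)
    mask <- matrix(stats::runif(length(beta)) < config$missing_rate,
                   nrow(beta), ncol(beta))
    beta[mask] <- NA_real_
  }

  genes <- sprintf("G%05d", seq_len(n_probes))
  is_planted <- seq_len(n_probes) <= n_planted
  annotation <- probe_annotation(
    probe_id = probe_ids,
    gene_symbols = genes,
    region_class = ifelse(is_planted, "island", "open_sea"),
    gene_region = ifelse(is_planted, "promoter_associated", "body"))
  gene_sets <- list()
  if (n_planted > 0L) {
    gene_sets$planted <- list(name = "planted",
                              description = "genes of planted probes",
                              genes = genes[is_planted])
  }
  if (config$n_background_probes > 0L) {
    gene_sets$background <- list(name = "background",
                                 description = "genes of background probes",
                                 genes = genes[!is_planted])
  }
  gene_sets$all <- list(name = "all", description = "all simulated genes",
                        genes = genes)

  cohort <- structure(list(beta = beta, manifest = manifest, truth = truth,
                           annotation = annotation, gene_sets = gene_sets,
                           config = config),
                      class = "simulated_cohort")
  if (!is.null(config$expression)) {
    ex <- config$expression
    cohort$expression <- simulate_expression(
      cohort, rho = ex$rho,
      base_log2 = if (is.null(ex$base_log2)) 8 else ex$base_log2,
      slope = if (is.null(ex$slope)) 1.5 else ex$slope,
      seed = config$seed + 2L)
  }
  cohort
}

#' Simulate expression matched to planted probes
#'
#' For each planted (promoter) probe, builds a gene expression vector whose
#' log2(FPKM+1) value is an affine function of the probe's standardized beta
#' values plus Gaussian noise, so that the expected Pearson correlation
#' between beta and log2(FPKM+1) equals `rho`. With `rho = -1` the noise
#' term vanishes and the correlation is exactly -1.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param rho Target correlation, `|rho| < 1` or exactly ±1 (noise-free).
#' @param base_log2,slope Affine map from the latent score to log2(FPKM+1)
#'   (defaults 8 and 1.5 keep FPKM essentially always positive).
#' @param seed Seed for the noise stream.
#' @return Expression matrix (genes x samples, FPKM scale).
#' @export
simulate_expression <- function(cohort, rho = -0.9, base_log2 = 8,
                                slope = 1.5, seed = cohort$config$seed + 2L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  truth <- cohort$truth
  if (nrow(truth) == 0L) stop("cohort has no planted probes")
  ann <- cohort$annotation
  genes <- ann$gene_symbols[match(truth$probe_id, ann$probe_id)]
  set.seed(seed)
  ns <- ncol(cohort$beta)
  expr <- matrix(NA_real_, nrow(truth), ns,
                 dimnames = list(genes, colnames(cohort$beta)))
  noise_sd <- sqrt(1 - rho^2)
  for (i in seq_len(nrow(truth))) {
    x <- cohort$beta[truth$probe_id[i], ]
    xs <- as.numeric(scale(x))
    y <- rho * xs + if (noise_sd > 0) noise_sd * stats::rnorm(ns) else 0
    expr[i, ] <- pmax(2^(base_log2 + slope * y) - 1, 0)
  }
  expr
}

#' Write a simulated cohort in the dialects the readers accept
#'
#' Writes `beta.tsv`, `manifest.tsv`, `annotation.csv` (450K dialect),
#' `gene_sets.gmt`, `truth.tsv` and, if present, `expression.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             annotation = file.path(dir, "annotation.csv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_beta_matrix(cohort$beta, paths["beta"])
  write_sample_manifest(cohort$manifest, paths["manifest"])
  write_probe_annotation(cohort$annotation, paths["annotation"])
  write_gene_sets(cohort$gene_sets, paths["gene_sets"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$expression)) {
    paths <- c(paths, expression = file.path(dir, "expression.tsv"))
    write_beta_matrix(cohort$expression, paths["expression"],
                      id_name = "feature_id")
  }
  invisible(paths)
}
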