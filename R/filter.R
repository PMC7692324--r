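# Quartile-based probe classification: the core feature-selection
# algorithm. Each probe is compared, one cancer at a time as "target",
# against hyper/hypomethylation thresholds using the Q1/Q3 of every
# (cancer, tissue) sample group.

CALL_CLASSES <- c("cancer_hyper", "cancer_hypo", "tissue_hyper", "tissue_hypo")
CALL_LABELS <- c(cancer_hyper = "Cancer-specific hypermethylation",
                 cancer_hypo = "Cancer-specific hypomethylation",
                 tissue_hyper = "Tissue-specific hypermethylation",
                 tissue_hypo = "Tissue-specific hypomethylation")

#' Configuration for the quartile filter
#'
#' @param hyper_threshold Beta value a group's quartile must exceed to count
#'   as hypermethylated (default 0.6, i.e. 60% methylated). Strict
#'   inequality.
#' @param hypo_threshold Beta value a group's quartile must stay under to
#'   count as hypomethylated (default 0.3). Strict inequality; must be below
#'   `hyper_threshold`.
#' @param min_group_size Minimum non-missing values per (cancer, tissue)
#'   group for a probe to be callable (default 2).
#' @param quantile_method `"linear"` (interpolation between order statistics,
#'   the numpy default; `stats::quantile` type 7) or `"nearest"`
#'   (nearest-rank, type 3). Calls near the thresholds can depend on this, so
#'   the choice is recorded in run metadata.
#' @param max_cancers Maximum number of cancer types filtered simultaneously
#'   (default 12).
#' @return A `filter_config` list.
#' @export
filter_config <- function(hyper_threshold = 0.6, hypo_threshold = 0.3,
                          min_group_size = 2L,
                          quantile_method = c("linear", "nearest"),
                          max_cancers = 12L) {
  quantile_method <- match.arg(quantile_method)
  stopifnot(is.numeric(hyper_threshold), is.numeric(hypo_threshold))
  if (!(hypo_threshold >= 0 && hypo_threshold < hyper_threshold &&
        hyper_threshold <= 1)) {
    stop("need 0 <= hypo_threshold < hyper_threshold <= 1 (got ",
         hypo_threshold, ", ", hyper_threshold, ")")
  }
  if (min_group_size < 1L) stop("min_group_size must be >= 1")
  structure(list(hyper_threshold = hyper_threshold,
                 hypo_threshold = hypo_threshold,
                 min_group_size = as.integer(min_group_size),
                 quantile_method = quantile_method,
                 max_cancers = as.integer(max_cancers)),
            class = "filter_config")
}

quantile_type <- function(config) if (config$quantile_method == "linear") 7L else 3L

# Sample groups in manifest order: for each cancer (order of first
# appearance), a primary_tumor and a normal_tissue group.
manifest_groups <- function(manifest, m = NULL) {
  manifest <- validate_manifest(manifest)
  if (!is.null(m)) {
    unknown <- setdiff(colnames(m), manifest$sample_id)
    if (length(unknown) > 0L) {
      stop("matrix sample(s) absent from manifest: ",
           paste(unknown, collapse = ", "))
    }
    manifest <- manifest[manifest$sample_id %in% colnames(m), , drop = FALSE]
  }
  cancers <- unique(manifest$cancer_code)
  groups <- expand.grid(tissue_type = TISSUE_TYPES, cancer_code = cancers,
                        stringsAsFactors = FALSE)[, 2:1]
  groups$label <- paste(groups$cancer_code, groups$tissue_type, sep = "|")
  groups$samples <- lapply(seq_len(nrow(groups)), function(i) {
    manifest$sample_id[manifest$cancer_code == groups$cancer_code[i] &
                       manifest$tissue_type == groups$tissue_type[i]]
  })
  empty <- lengths(groups$samples) == 0L
  if (any(empty)) {
    stop("cancer code(s) lacking a tissue type: ",
         paste(groups$label[empty], collapse = ", "))
  }
  groups
}

#' Per-group Q1/Q3 quartile profiles
#'
#' Computes, for every probe and every (cancer, tissue) sample group, the
#' 25th (Q1) and 75th (Q3) percentile of the non-missing beta values plus
#' the non-missing count.
#'
#' @param m Beta matrix (probes x samples).
#' @param manifest Sample manifest covering the matrix columns.
#' @param config A [filter_config()].
#' @return A `quartile_profile`: list with probe x group matrices `q1`,
#'   `q3`, `n`, the group table `groups`, and `config`.
#' @export
group_quartiles <- function(m, manifest, config = filter_config()) {
  groups <- manifest_groups(manifest, m)
  type <- quantile_type(config)
  ng <- nrow(groups)
  q1 <- q3 <- nn <- matrix(NA_real_, nrow(m), ng,
                           dimnames = list(rownames(m), groups$label))
  for (g in seq_len(ng)) {
    sub <- m[, groups$samples[[g]], drop = FALSE]
    nn[, g] <- rowSums(!is.na(sub))
    ok <- nn[, g] >= 1L
    if (any(ok)) {
      qs <- apply(sub[ok, , drop = FALSE], 1L, function(x) {
        stats::quantile(x, probs = c(0.25, 0.75), na.rm = TRUE,
                        type = type, names = FALSE)
      })
      q1[ok, g] <- qs[1L, ]
      q3[ok, g] <- qs[2L, ]
    }
  }
  structure(list(q1 = q1, q3 = q3, n = nn, groups = groups, config = config),
            class = "quartile_profile")
}

# Vectorized rule evaluation for one target cancer. Returns a character
# vector over probes. Strict inequalities throughout: a quartile exactly at
# a threshold never fires a rule.
classify_target <- function(profile, target_cancer, config) {
  groups <- profile$groups
  hyper <- config$hyper_threshold
  hypo <- config$hypo_threshold
  lab <- function(cancer, tissue) paste(cancer, tissue, sep = "|")
  others <- setdiff(unique(groups$cancer_code), target_cancer)
  oT <- lab(others, "primary_tumor")
  oN <- lab(others, "normal_tissue")
  tT <- lab(target_cancer, "primary_tumor")
  tN <- lab(target_cancer, "normal_tissue")

  q1 <- profile$q1; q3 <- profile$q3
  callable <- rowSums(profile$n < config$min_group_size) == 0L
  all_lt <- function(qm, cols, thr) {
    if (length(cols) == 0L) return(rep(TRUE, nrow(qm)))
    rowSums(qm[, cols, drop = FALSE] < thr) == length(cols)
  }
  all_gt <- function(qm, cols, thr) {
    if (length(cols) == 0L) return(rep(TRUE, nrow(qm)))
    rowSums(qm[, cols, drop = FALSE] > thr) == length(cols)
  }

  others_low <- all_lt(q3, oT, hypo) & all_lt(q3, oN, hypo)
  others_high <- all_gt(q1, oT, hyper) & all_gt(q1, oN, hyper)

  ch <- q1[, tT] > hyper & q3[, tN] < hypo & others_low
  cl <- q3[, tT] < hypo & q1[, tN] > hyper & others_high
  th <- q1[, tT] > hyper & q1[, tN] > hyper & others_low
  tl <- q3[, tT] < hypo & q3[, tN] < hypo & others_high

  out <- rep("none", nrow(q1))
  out[tl] <- "tissue_hypo"
  out[th] <- "tissue_hyper"
  out[cl] <- "cancer_hypo"
  out[ch] <- "cancer_hyper"
  out[!callable] <- "none"
  out[is.na(out)] <- "none"
  names(out) <- rownames(q1)
  out
}

#' Classify one probe against one target cancer
#'
#' Applies the four quartile rules with precedence
#' `cancer_hyper > cancer_hypo > tissue_hyper > tissue_hypo`. With T = tumor,
#' N = normal, t = target cancer, o = every other cancer, and thresholds
#' (H, L) = (`hyper_threshold`, `hypo_threshold`):
#' \itemize{
#'   \item cancer_hyper: Q1(T,t) > H, Q3(N,t) < L, and Q3 < L for T and N of
#'     every other cancer — only the target's tumors are methylated.
#'   \item cancer_hypo: Q3(T,t) < L, Q1(N,t) > H, and Q1 > H elsewhere —
#'     only the target's tumors are unmethylated.
#'   \item tissue_hyper: Q1 > H for both tissues of the target, Q3 < L
#'     elsewhere.
#'   \item tissue_hypo: Q3 < L for both tissues of the target, Q1 > H
#'     elsewhere.
#' }
#' A probe with any group below `min_group_size` is uncallable (`"none"`).
#'
#' @param profile A [group_quartiles()] result.
#' @param probe_id Probe to classify.
#' @param target_cancer Cancer code treated as the target.
#' @param config A [filter_config()]; defaults to the profile's.
#' @return One of `"cancer_hyper"`, `"cancer_hypo"`, `"tissue_hyper"`,
#'   `"tissue_hypo"`, `"none"`.
#' @export
classify_probe <- function(profile, probe_id, target_cancer,
                           config = profile$config) {
  if (!probe_id %in% rownames(profile$q1)) stop("unknown probe: ", probe_id)
  if (!target_cancer %in% profile$groups$cancer_code) {
    stop("unknown target cancer: ", target_cancer)
  }
  unname(classify_target(profile, target_cancer, config)[probe_id])
}

#' Run the quartile filter over a cohort
#'
#' Classifies every probe against every cancer as target. A probe's winning
#' call is the first non-`none` (target, class) pair in manifest cancer
#' order; all satisfied pairs are kept in long format.
#'
#' @param m Beta matrix (probes x samples).
#' @param manifest Sample manifest; needs >= 2 cancer codes, each with both
#'   tissue types.
#' @param config A [filter_config()].
#' @return A `call_table`: list with `calls` (probe_id, call_class,
#'   target_cancer; one row per probe), `long` (all satisfied pairs),
#'   `tally` (class x cancer counts), `profile`, and `config`.
#' @export
run_filter <- function(m, manifest, config = filter_config()) {
  profile <- group_quartiles(m, manifest, config)
  cancers <- unique(profile$groups$cancer_code)
  if (length(cancers) < 2L) {
    stop("need >= 2 cancer codes: the rules quantify over other cancers")
  }
  if (length(cancers) > config$max_cancers) {
    stop("manifest has ", length(cancers), " cancer codes; config caps at ",
         config$max_cancers)
  }
  per_target <- vapply(cancers, function(t) classify_target(profile, t, config),
                       character(nrow(m)))
  if (nrow(m) == 1L) per_target <- matrix(per_target, nrow = 1L,
                                          dimnames = list(rownames(m), cancers))
  hit <- per_target != "none"
  first <- apply(hit, 1L, function(h) if (any(h)) which(h)[1L] else NA_integer_)
  calls <- data.frame(
    probe_id = rownames(m),
    call_class = ifelse(is.na(first), "none",
                        per_target[cbind(seq_len(nrow(m)), first)]),
    target_cancer = ifelse(is.na(first), "", cancers[first]),
    stringsAsFactors = FALSE)
  idx <- which(hit, arr.ind = TRUE)
  long <- data.frame(probe_id = rownames(m)[idx[, 1L]],
                     call_class = per_target[idx],
                     target_cancer = cancers[idx[, 2L]],
                     stringsAsFactors = FALSE)
  long <- long[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rownames(long) <- NULL
  structure(list(calls = calls, long = long,
                 tally = tally_calls(calls, cancers),
                 profile = profile, config = config),
            class = "call_table")
}

#' Tally calls per class and cancer
#'
#' @param calls Data frame with `call_class` and `target_cancer` (the
#'   `calls` element of [run_filter()]), or a `call_table`.
#' @param cancer_codes Cancer codes to include as columns (zeros kept).
#' @return Integer matrix, four call classes x cancers.
#' @export
tally_calls <- function(calls, cancer_codes = NULL) {
  if (inherits(calls, "call_table")) calls <- calls$calls
  if (is.null(cancer_codes)) {
    cancer_codes <- sort(unique(calls$target_cancer[calls$target_cancer != ""]))
  }
  tal <- matrix(0L, length(CALL_CLASSES), length(cancer_codes),
                dimnames = list(CALL_CLASSES, cancer_codes))
  nz <- calls[calls$call_class != "none", , drop = FALSE]
  for (i in seq_len(nrow(nz))) {
    tal[nz$call_class[i], nz$target_cancer[i]] <-
      tal[nz$call_class[i], nz$target_cancer[i]] + 1L
  }
  tal
}

#' Export filter calls and tally as TSV
#'
#' `calls.tsv` carries one row per probe with its winning call and the
#' per-group Q1/Q3; `tally.tsv` mirrors the class x cancer tally with the
#' conventional long labels ("Cancer-specific hypermethylation", ...).
#'
#' @param result A [run_filter()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_call_table <- function(result, dir) {
  stopifnot(inherits(result, "call_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- result$profile
  qcols <- cbind(prof$q1, prof$q3)
  colnames(qcols) <- c(paste0("Q1|", colnames(prof$q1)),
                       paste0("Q3|", colnames(prof$q3)))
  calls <- cbind(result$calls,
                 as.data.frame(formatC(qcols, format = "g", digits = 17)))
  calls_path <- file.path(dir, "calls.tsv")
  utils::write.table(calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  long_path <- file.path(dir, "calls_long.tsv")
  utils::write.table(result$long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tal <- result$tally
  tal_df <- data.frame(Sites = CALL_LABELS[rownames(tal)],
                       as.data.frame(tal), check.names = FALSE)
  tally_path <- file.path(dir, "tally.tsv")
  utils::write.table(tal_df, tally_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(calls_path, long_path, tally_path))
}
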