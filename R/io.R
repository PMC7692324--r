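# Readers/writers for the TSV/CSV/GMT dialects the pipeline consumes.
# Matrix orientation is fixed throughout: probes (or genes) in rows,
# samples in columns.

TISSUE_TYPES <- c("primary_tumor", "normal_tissue")
REGION_CLASSES <- c("island", "shore", "shelf", "open_sea")

read_delim_matrix <- function(path, missing_token = "NA", id_name = "row") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >=1 sample column: ", path)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate ", id_name, " ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[raw == missing_token | raw == ""] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric value '", raw[bad[1L, 1L], bad[1L, 2L]], "' at probe ",
         ids[bad[1L, 1L]], ", sample ", samples[bad[1L, 2L]], " in ", path)
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read a beta-value matrix
#'
#' Reads a tab-delimited methylation matrix (first column probe ids, header
#' row sample ids) and validates that every non-missing beta value lies in
#' \eqn{[0, 1]}. A beta value is the fraction of methylated signal at a CpG:
#' 0 is fully unmethylated, 1 fully methylated.
#'
#' @param path Path to a TSV file.
#' @param missing_token String marking missing cells (default `"NA"`).
#' @return Numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path, missing_token = "NA") {
  m <- read_delim_matrix(path, missing_token, id_name = "probe")
  validate_beta_values(m, context = path)
  m
}

validate_beta_values <- function(m, context = "beta matrix") {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("beta value out of [0,1] in ", context, ": probe ", rownames(m)[i],
         ", sample ", colnames(m)[j], ", value ", m[i, j])
  }
  invisible(m)
}

#' Read an FPKM expression matrix
#'
#' Same dialect as [read_beta_matrix()] but values are non-negative FPKM
#' (fragments per kilobase of transcript per million mapped reads).
#'
#' @inheritParams read_beta_matrix
#' @return Numeric matrix, features (genes/transcripts) in rows.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  m <- read_delim_matrix(path, missing_token, id_name = "feature")
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("negative expression value in ", path, ": feature ", rownames(m)[i],
         ", sample ", colnames(m)[j], ", value ", m[i, j])
  }
  m
}

#' Write a beta or expression matrix as TSV
#'
#' Values are written with 17 significant digits so that
#' `read_beta_matrix(write_beta_matrix(m))` round-trips bit-identically.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param missing_token Token written for missing cells.
#' @param id_name Header label for the id column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, missing_token = "NA", id_name = "probe_id") {
  ch <- array(formatC(m, format = "g", digits = 17), dim = dim(m))
  ch[is.na(m)] <- missing_token
  lines <- c(paste(c(id_name, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(ch, 1L, paste, collapse = "\t"), sep = "\t"))
  if (nrow(m) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample manifest
#'
#' TSV with columns `sample_id`, `cancer_code`, `tissue_type`, where
#' `tissue_type` is `primary_tumor` or `normal_tissue`.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame with validated columns.
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  validate_manifest(df)
}

validate_manifest <- function(df) {
  need <- c("sample_id", "cancer_code", "tissue_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$tissue_type), TISSUE_TYPES)
  if (length(bad) > 0L) {
    stop("unknown tissue_type value(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(TISSUE_TYPES, collapse = " or "), ")")
  }
  df
}

#' Write a sample manifest
#' @param manifest Manifest data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_manifest <- function(manifest, path) {
  utils::write.table(validate_manifest(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge per-sample beta matrices under one manifest
#'
#' TCGA-style downloads deliver one file per sample (or small batches); this
#' merges them into one probe-by-sample matrix. By default the probe
#' *intersection* is kept, so every downstream group is complete; set
#' `how = "union"` to keep all probes with missing values where a file lacks
#' them. Column order follows manifest order.
#'
#' @param paths Character vector of beta TSV files.
#' @param manifest Sample manifest (data frame or path).
#' @param how `"intersect"` (default) or `"union"`.
#' @param missing_token Missing-value token in the input files.
#' @return Merged beta matrix.
#' @export
merge_beta_matrices <- function(paths, manifest, how = c("intersect", "union"),
                                missing_token = "NA") {
  how <- match.arg(how)
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest)) {
    manifest <- read_sample_manifest(manifest)
  }
  manifest <- validate_manifest(manifest)
  mats <- lapply(paths, read_beta_matrix, missing_token = missing_token)
  all_samples <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_samples)) {
    stop("sample id(s) appear in more than one file: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  }
  unknown <- setdiff(all_samples, manifest$sample_id)
  if (length(unknown) > 0L) {
    stop("sample(s) present in files but absent from manifest: ",
         paste(unknown, collapse = ", "))
  }
  probes <- Reduce(if (how == "intersect") intersect else union,
                   lapply(mats, rownames))
  if (length(probes) == 0L) stop("empty probe ", how, " across input files")
  if (how == "union") probes <- sort(probes)
  out <- matrix(NA_real_, nrow = length(probes), ncol = length(all_samples),
                dimnames = list(probes, all_samples))
  for (m in mats) {
    shared <- intersect(probes, rownames(m))
    out[shared, colnames(m)] <- m[shared, , drop = FALSE]
  }
  keep <- manifest$sample_id[manifest$sample_id %in% all_samples]
  out[, keep, drop = FALSE]
}
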