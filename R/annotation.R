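# Probe annotation (450K-manifest dialect), GMT gene sets, and
# annotation-driven probe subsetting.

GENE_REGIONS <- c("promoter_associated", "body", "other")

#' Construct a probe annotation table
#'
#' Normalized annotation used throughout the package: one row per probe,
#' genes and gene regions as semicolon-joined strings, and one of four
#' CpG-density classes (`island`, `shore`, `shelf`, `open_sea`).
#'
#' @param probe_id Character vector of unique probe ids.
#' @param gene_symbols Semicolon-joined gene symbols per probe (may be `""`).
#' @param region_class One of `island`, `shore`, `shelf`, `open_sea` per probe.
#' @param gene_region Semicolon-joined subset of `promoter_associated`,
#'   `body`, `other` per probe (may be `""`).
#' @return Data frame with the four columns above.
#' @export
probe_annotation <- function(probe_id, gene_symbols = "", region_class = "open_sea",
                             gene_region = "") {
  n <- length(probe_id)
  if (anyDuplicated(probe_id)) {
    stop("duplicate probe_id in annotation: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  }
  df <- data.frame(probe_id = as.character(probe_id),
                   gene_symbols = rep_len(as.character(gene_symbols), n),
                   region_class = rep_len(as.character(region_class), n),
                   gene_region = rep_len(as.character(gene_region), n))
  bad <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown region_class value(s): ", paste(bad, collapse = ", "))
  }
  regs <- setdiff(unique(unlist(split_multi(df$gene_region))), GENE_REGIONS)
  if (length(regs) > 0L) {
    stop("unknown gene_region value(s): ", paste(regs, collapse = ", "))
  }
  df
}

split_multi <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)

#' Read a 450K-style probe annotation CSV
#'
#' Expects the Illumina manifest columns `IlmnID`, `UCSC_RefGene_Name`,
#' `UCSC_RefGene_Group` and `Relation_to_UCSC_CpG_Island`. Island relations
#' collapse to `island` / `shore` / `shelf` / `open_sea`; RefGene groups
#' `TSS200`, `TSS1500` and `5'UTR` map to `promoter_associated`, `Body` to
#' `body`, anything else to `other`.
#'
#' @param path Path to the annotation CSV.
#' @return Normalized annotation data frame (see [probe_annotation()]).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  need <- c("IlmnID", "UCSC_RefGene_Name", "UCSC_RefGene_Group",
            "Relation_to_UCSC_CpG_Island")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))

  region <- vapply(df$Relation_to_UCSC_CpG_Island, function(r) {
    r <- toupper(trimws(r))
    if (r == "ISLAND") "island"
    else if (r %in% c("N_SHORE", "S_SHORE")) "shore"
    else if (r %in% c("N_SHELF", "S_SHELF")) "shelf"
    else "open_sea"
  }, character(1L), USE.NAMES = FALSE)

  genes <- vapply(split_multi(df$UCSC_RefGene_Name), function(g) {
    g <- g[g != ""]
    paste(g[!duplicated(toupper(g))], collapse = ";")
  }, character(1L))

  gene_region <- vapply(split_multi(df$UCSC_RefGene_Group), function(g) {
    g <- toupper(g[g != ""])
    out <- ifelse(g %in% c("TSS200", "TSS1500", "5'UTR"), "promoter_associated",
                  ifelse(g == "BODY", "body", "other"))
    paste(unique(out), collapse = ";")
  }, character(1L))

  probe_annotation(df$IlmnID, genes, region, gene_region)
}

#' Write a probe annotation table in the 450K CSV dialect
#' @param annotation Annotation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  region_out <- c(island = "Island", shore = "N_Shore", shelf = "N_Shelf",
                  open_sea = "")[annotation$region_class]
  group_out <- vapply(split_multi(annotation$gene_region), function(g) {
    paste(c(promoter_associated = "TSS200", body = "Body",
            other = "3'UTR")[g], collapse = ";")
  }, character(1L))
  out <- data.frame(IlmnID = annotation$probe_id,
                    UCSC_RefGene_Name = annotation$gene_symbols,
                    UCSC_RefGene_Group = group_out,
                    Relation_to_UCSC_CpG_Island = region_out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more gene symbols, all
#' tab-separated. Genes are deduplicated case-insensitively (first spelling
#' kept).
#'
#' @param path Path to a GMT file.
#' @return Named list; each element is `list(name, description, genes)`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has ", length(f), " field(s); need name, ",
           "description and >=1 gene")
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(toupper(genes))]
    if (length(genes) == 0L) stop("GMT line ", i, " has no genes")
    sets[[i]] <- list(name = f[[1L]], description = f[[2L]], genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Subset a beta matrix by gene membership and probe region
#'
#' Keeps probes annotated to at least one gene of `gene_set`
#' (case-insensitive symbol match; multi-gene annotations are
#' semicolon-split) and, optionally, lying in the given CpG-density classes
#' and/or promoter-associated gene regions. Probe order is preserved and no
#' probe is duplicated.
#'
#' @param m Beta matrix (probes x samples).
#' @param annotation Probe annotation data frame.
#' @param gene_set Character vector of gene symbols, or a single element of
#'   [read_gene_sets()] output, or `NULL` to keep all annotated genes.
#' @param region_filter Subset of `c("island","shore","shelf","open_sea")`,
#'   or `NULL` for no region restriction.
#' @param promoter_only If `TRUE`, keep only probes whose gene region
#'   includes `promoter_associated`.
#' @return The row-subset beta matrix (possibly 0-row, with a warning).
#' @export
subset_probes <- function(m, annotation, gene_set = NULL, region_filter = NULL,
                          promoter_only = FALSE) {
  if (is.list(gene_set) && !is.null(gene_set$genes)) gene_set <- gene_set$genes
  ann <- annotation[match(rownames(m), annotation$probe_id), , drop = FALSE]
  gene_lists <- split_multi(ann$gene_symbols)
  keep <- lengths(gene_lists) > 0L & !is.na(ann$probe_id)
  if (!is.null(gene_set)) {
    wanted <- unique(toupper(gene_set))
    keep <- keep & vapply(gene_lists, function(g) any(toupper(g) %in% wanted),
                          logical(1L))
  }
  if (!is.null(region_filter)) {
    bad <- setdiff(region_filter, REGION_CLASSES)
    if (length(bad) > 0L) stop("unknown region_filter value(s): ",
                               paste(bad, collapse = ", "))
    keep <- keep & ann$region_class %in% region_filter
  }
  if (isTRUE(promoter_only)) {
    keep <- keep & vapply(split_multi(ann$gene_region),
                          function(g) "promoter_associated" %in% g, logical(1L))
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no probes match the gene set / region filter")
  m[keep, , drop = FALSE]
}
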