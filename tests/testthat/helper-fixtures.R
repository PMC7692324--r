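# Small in-code fixtures shared across test files.

make_manifest <- function(cancers = c("BRCA", "COAD"), n_tumor = 3L,
                          n_normal = 3L) {
  do.call(rbind, lapply(cancers, function(cc) {
    data.frame(
      sample_id = c(sprintf("%s_T%d", cc, seq_len(n_tumor)),
                    sprintf("%s_N%d", cc, seq_len(n_normal))),
      cancer_code = cc,
      tissue_type = rep(c("primary_tumor", "normal_tissue"),
                        c(n_tumor, n_normal)),
      stringsAsFactors = FALSE)
  }))
}

# Beta matrix with one row per probe, built from per-group constants:
# groups follow the manifest's (cancer, tissue) blocks.
make_group_matrix <- function(manifest, probe_values) {
  groups <- paste(manifest$cancer_code, manifest$tissue_type, sep = "|")
  m <- t(vapply(probe_values, function(pv) unname(pv[groups]),
                numeric(nrow(manifest))))
  rownames(m) <- names(probe_values)
  colnames(m) <- manifest$sample_id
  m
}

write_beta_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

write_manifest_tsv <- function(manifest, path = tempfile(fileext = ".tsv")) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
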