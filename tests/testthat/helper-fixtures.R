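# In-code fixtures shared across the suite.

std_design <- function(replicates = 3L, seed = 1L) {
  titration_design(replicates = replicates, seed = seed)
}

# Hand-built ground truth with full control over every field; mirrors the
# schema produced by generate_truth().
make_truth <- function(gene_id, species, expressed_same = TRUE,
                       relative_abundance = 1,
                       ortholog_partner = NA_character_,
                       cross_class = "none", cross_prob = NA_real_,
                       cross_abundance = NA_real_) {
  df <- data.frame(gene_id = gene_id, species = species,
                   expressed_same = expressed_same,
                   relative_abundance = relative_abundance,
                   ortholog_partner = ortholog_partner,
                   cross_class = cross_class, cross_prob = cross_prob,
                   cross_abundance = cross_abundance,
                   stringsAsFactors = FALSE)
  class(df) <- c("synthetic_truth", "data.frame")
  df
}

# Microarray detection table from a named list mapping level keys
# ("h0_m100", ...) to feature x replicate p-value matrices. Levels not
# supplied are filled with p = 0.5 (never detected).
make_ptable <- function(feature_ids, per_level, design = std_design(),
                        platform_species = "human", fill = 0.5) {
  labels <- unlist(lapply(design$mixture_levels, function(h) {
    vapply(seq_len(design$replicates),
           function(r) sprintf("h%d_m%d_r%d", round(100 * h),
                               round(100 * (1 - h)), r), "")
  }))
  values <- matrix(fill, nrow = length(feature_ids), ncol = length(labels),
                   dimnames = list(feature_ids, labels))
  for (key in names(per_level)) {
    block <- per_level[[key]]
    cols <- sprintf("%s_r%d", key, seq_len(design$replicates))
    values[rownames(block), cols] <- block
  }
  detection_table("microarray", platform_species, values, design)
}

write_tsv_fixture <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
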