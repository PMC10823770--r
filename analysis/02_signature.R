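#!/usr/bin/env Rscript
# Build the cell-type signature matrix from the sorted-cell reference
# profiles: intersect genes with the bulk matrix, select markers enriched
# > 1.5-fold against every other cell type (up to 200 per type), and stack
# the marker rows.

suppressPackageStartupMessages(library(decontox))

ref_raw <- read_expression("results/reference_profiles.tsv")
bulk <- read_expression("results/bulk_expression.tsv")

# one profile column per type already (single sorted replicate per type)
labels <- stats::setNames(colnames(ref_raw), colnames(ref_raw))
ref <- collapse_replicates(ref_raw, labels)
both <- intersect_genes(ref, bulk)

markers <- select_markers(both$ref, fc_threshold = 1.5, max_genes = 200)
X <- build_signature(both$ref, markers)
write_expression(X, "results/signature_matrix.tsv")

marker_tab <- do.call(rbind, lapply(names(markers), function(ct) {
  data.frame(cell_type = ct, markers[[ct]])
}))
utils::write.csv(marker_tab, "results/marker_genes.csv", row.names = FALSE)

cat(sprintf("signature: %d marker genes x %d cell types\n", nrow(X), ncol(X)))
cat("markers per type:",
    paste(sprintf("%s=%d", names(markers), vapply(markers, nrow, 0L)), collapse = ", "),
    "\n")
cat(sprintf("median enrichment ratio: %.2f\n", stats::median(marker_tab$ratio)))
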