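#!/usr/bin/env Rscript
# Generate the synthetic toxicogenomics study: sorted-cell reference
# profiles, a 16-compound / 4-time-point liver mixture study with matched
# vehicle controls and 4 planted trafficking clusters, and a gene-set
# collection with one planted discriminative set.

suppressPackageStartupMessages(library(decontox))

seed <- 2026
dir.create("results", showWarnings = FALSE)

study <- simulate_study(seed = seed)
sets <- simulate_gene_sets(study, n_sets = 200, set_size = 25,
                           n_discriminative = 1, target_cluster = 1,
                           seed = seed + 1)

write_expression(study$reference$reference, "results/reference_profiles.tsv")
write_expression(study$expression, "results/bulk_expression.tsv")
write_sample_metadata(study$meta, "results/sample_metadata.csv")
write_gmt(sets, "results/gene_sets.gmt")
jsonlite::write_json(list(true_cluster = as.list(study$truth$true_cluster),
                          planted_sets = attr(sets, "planted"),
                          seed = seed),
                     "results/simulation_truth.json", auto_unbox = TRUE)

cat(sprintf("study: %d genes x %d samples (%d compounds, %d controls/time)\n",
            nrow(study$expression), ncol(study$expression),
            length(unique(study$meta$compound[!study$meta$is_control])),
            sum(study$meta$is_control & study$meta$time_h == 3)))
cat(sprintf("planted clusters: %s\n",
            paste(table(study$truth$true_cluster), collapse = "/")))
cat(sprintf("gene sets: %d (%d planted discriminative)\n",
            length(sets), length(attr(sets, "planted"))))
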