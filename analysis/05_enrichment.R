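#!/usr/bin/env Rscript
# Characterize the trafficking clusters: ssGSEA scores of every sample
# against the gene-set collection, then cluster-discriminative terms by
# Mann-Whitney tests with Bonferroni correction. The planted set should
# surface as the top term of its target cluster.

suppressPackageStartupMessages(library(decontox))

bulk <- read_expression("results/bulk_expression.tsv")
meta <- read_sample_metadata("results/sample_metadata.csv")
sets <- read_gmt("results/gene_sets.gmt")
clusters <- utils::read.csv("results/compound_clusters.csv")
truth <- jsonlite::read_json("results/simulation_truth.json")

assignment <- stats::setNames(clusters$immune_cluster, clusters$compound)

# score treated samples at the target cluster's peak-effect time (3 h)
keep <- meta$sample_id[!meta$is_control & meta$time_h == 3]
tab <- score_table(bulk[, keep], sets)
utils::write.csv(data.frame(sample_id = rownames(tab), round(tab, 5),
                            check.names = FALSE),
                 "results/ssgsea_scores_3h.csv", row.names = FALSE)

res <- discriminative_terms(tab, assignment, meta)
utils::write.csv(res, "results/discriminative_terms.csv", row.names = FALSE)

planted <- unlist(truth$planted_sets)
top_by_cluster <- do.call(rbind, lapply(split(res, res$cluster), utils::head, 1))
cat("top discriminative term per cluster:\n")
print(top_by_cluster, row.names = FALSE)
hit <- res[res$set_name %in% planted, ]
hit <- hit[which.min(hit$adjusted_p), ]
cat(sprintf("planted set '%s': best adjusted p = %.3g in cluster %d (rank %d)\n",
            hit$set_name, hit$adjusted_p, hit$cluster,
            which(res$set_name[res$cluster == hit$cluster] == hit$set_name)))
cat(sprintf("terms with adjusted p < 0.05: %d of %d contrasts\n",
            sum(res$adjusted_p < 0.05), nrow(res)))
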