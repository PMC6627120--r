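#!/usr/bin/env Rscript
# Genus-level co-occurrence networks from Pearson correlations of CLR
# abundances at cutoff 0.28: one network over all biological samples and
# one per community type.

suppressMessages(library(milkbiome))

tb <- read_count_table("results/cohort/counts_filtered.tsv",
                       roles = "results/cohort/metadata.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
types <- read.delim("results/community_types.tsv")

net_all <- build_network(tb, tax, mra_threshold = 0.005, r_cutoff = 0.28)
cat(sprintf("all samples: %d nodes, %d edges (%d positive, %d negative)\n",
            nrow(net_all$nodes), nrow(net_all$edges),
            sum(net_all$edges$r > 0), sum(net_all$edges$r < 0)))
ss <- edge_r(net_all, "Streptococcus", "Staphylococcus")
cat(sprintf("Streptococcus-Staphylococcus: r = %s\n",
            ifelse(is.na(ss), "below cutoff", sprintf("%.2f", ss))))
write.table(net_all$edges, "results/network_all_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (k in sort(unique(types$ch_label))) {
  ids <- types$sample_id[types$ch_label == k]
  if (length(ids) < 3) next
  net_k <- build_network(tb, tax, mra_threshold = 0.005, r_cutoff = 0.28,
                         subset = ids)
  cat(sprintf("community type %d (n = %d): %d nodes, %d edges\n",
              k, length(ids), nrow(net_k$nodes), nrow(net_k$edges)))
  write.table(net_k$edges, sprintf("results/network_cluster%d_edges.tsv", k),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
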