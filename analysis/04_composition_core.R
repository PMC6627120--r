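#!/usr/bin/env Rscript
# Compositional profile of the cleaned, depth-filtered cohort: mean
# relative abundances at genus level and the prevalence-threshold core
# bacteriome (features present in at least 80% of biological samples).

suppressMessages(library(milkbiome))

tb <- read_count_table("results/cohort/counts_filtered.tsv",
                       roles = "results/cohort/metadata.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")

genus <- collapse_to_rank(tb, tax, "genus")
mra <- sort(mean_relative_abundance(to_relative(genus)), decreasing = TRUE)
write.table(data.frame(genus = names(mra), mra = mra),
            "results/genus_mra.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("genera with mean relative abundance > 0.5%:\n")
top <- mra[mra > 0.005]
for (i in seq_along(top))
  cat(sprintf("  %-28s %5.1f%%\n", names(top)[i], 100 * top[i]))

core <- core_features(tb, threshold = 0.8, tax = tax)
cat(sprintf("core bacteriome at 80%% prevalence: %d OTUs from %d taxa\n",
            length(core$core_features), length(core$core_taxa)))
cat("  taxa:", paste(core$core_taxa, collapse = ", "), "\n")
write.table(data.frame(feature = names(core$core_features),
                       prevalence = core$core_features),
            "results/core_bacteriome.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
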