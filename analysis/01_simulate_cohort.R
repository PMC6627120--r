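#!/usr/bin/env Rscript
# Simulate the study cohort: three milk community types (Staphylococcus-
# dominant / mixed / Streptococcus-dominant, 40 samples each), a shared
# reagent-contamination background, four M. smegmatis-like spiked NTCs,
# a handful of under-sequenced samples, and duplicate library preps.
# Artifacts land under results/cohort/ as plain TSV + JSON.

suppressMessages({library(milkbiome); library(jsonlite)})
set.seed(101)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

sp <- cohort_spec(n_samples = c(40, 40, 40), otus_per_genus = 2,
                  n_low_depth = 5, n_ntc = 4)
co <- generate_cohort(sp, seed = 101)

# duplicate library preparations for three extracts (cf. the 11 repeats
# sequenced in duplicate in the study design)
tb <- co$table
for (s in c("S005", "S045", "S085")) {
  tb <- generate_replicate_pair(tb, s, seed = 500 + match(s, sample_ids(tb)))
}

write_count_table(tb, "results/cohort/counts.tsv")

md <- co$metadata
reps <- data.frame(sample_id = setdiff(sample_ids(tb), md$sample_id),
                   role = "replicate", cluster = NA, site = NA,
                   delivery_mode = NA, stringsAsFactors = FALSE)
md <- rbind(md, reps)
md$replicate_of <- tb$replicate_of[md$sample_id]
writeLines(c(paste(c("#SampleID", names(md)[-1]), collapse = "\t"),
             apply(md, 1, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t"))),
           "results/cohort/metadata.tsv")

tax <- co$taxonomy
lineage <- apply(tax[, -1], 1, function(r) {
  paste0(c("k__", "p__", "c__", "o__", "f__", "g__"),
         ifelse(is.na(r), "", r), collapse = ";")
})
writeLines(paste(tax$feature_id, lineage, sep = "\t"),
           "results/cohort/taxonomy.tsv")

write_json(list(true_cluster = as.list(co$truth$true_cluster),
                contaminant_features = co$truth$contaminant_features,
                spike_feature = sp$spike_feature),
           "results/cohort/ground_truth.json", auto_unbox = TRUE)

cat(sprintf("cohort: %d features x %d samples (%d biological, %d NTC, %d replicates)\n",
            length(feature_ids(tb)), length(sample_ids(tb)),
            sum(tb$roles == "biological"), sum(tb$roles == "ntc_spiked"),
            sum(tb$roles == "replicate")))
cat(sprintf("read depth: median %d (range %d-%d); %d samples below 1000 reads\n",
            round(median(sample_depths(tb))), min(sample_depths(tb)),
            max(sample_depths(tb)),
            sum(sample_depths(tb)[tb$roles == "biological"] < 1000)))
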