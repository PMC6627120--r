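#!/usr/bin/env Rscript
# Remove under-sequenced samples (strictly below 1000 reads, where milk
# rarefaction curves plateau), tabulate alpha diversity, and test its
# difference between community types by one-way ANOVA.

suppressMessages(library(milkbiome))

tb <- read_count_table("results/cohort/counts_clean.tsv",
                       roles = "results/cohort/metadata.tsv")
truth <- jsonlite::read_json("results/cohort/ground_truth.json", simplifyVector = TRUE)

res <- filter_min_depth(tb, 1000)
cat(sprintf("depth filter: removed %d of %d samples (<1000 reads): %s\n",
            length(res$removed), length(sample_ids(tb)),
            paste(res$removed, collapse = ", ")))
tb <- res$table
write_count_table(tb, "results/cohort/counts_filtered.tsv")

ad <- alpha_diversity(tb)
write.table(ad, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Shannon: median %.2f (IQR %.2f-%.2f); Chao1 median %.1f\n",
            median(ad$shannon), quantile(ad$shannon, 0.25),
            quantile(ad$shannon, 0.75), median(ad$chao1)))

bio <- ad$sample_id[ad$role == "biological"]
grp <- unlist(truth$true_cluster)[bio]
for (metric in c("shannon", "chao1")) {
  vals <- ad[[metric]][match(bio, ad$sample_id)]
  fit <- alpha_anova(vals, grp)
  cat(sprintf("ANOVA of %s between community types: F(%d, %d) = %.2f, p = %.3g\n",
              metric, fit$df_between, fit$df_within, fit$f, fit$p))
}

rc <- rarefaction_curve(subset_samples(tb, bio[1:12]),
                        depths = c(100, 250, 500, 1000, 2000, 4000),
                        metric = "shannon", n_iter = 10, seed = 103)
write.table(rc, "results/rarefaction_shannon.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
plateau <- with(rc[!rc$skipped, ], tapply(mean, depth, mean, na.rm = TRUE))
cat("mean Shannon by rarefaction depth:\n")
print(round(plateau, 3))
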