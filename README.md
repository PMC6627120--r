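# milkbiome

Compositional analysis of human breast milk (HBM) 16S rRNA bacteriome
profiles from OTU count tables.

Low-biomass samples such as breast milk are dominated by two analytical
problems: reagent ("kitome") contamination that can swamp the biological
signal, and the compositional nature of amplicon counts, which makes naive
correlations and distances misleading. This package implements, as a tested
and reusable pipeline, the analysis stack used to characterise the HBM
bacteriome of a birth-cohort study population:

* **Spiked-NTC decontamination** — no-template extraction controls spiked
  with DNA of a known taxon (e.g. *Mycobacterium smegmatis*) are sequenced
  at sample-like depth; every non-spike feature seen in them is catalogued
  as background, and its mean NTC read count is subtracted from each
  biological sample, floored at zero. Features absent from the controls are
  never touched, bounding over-compensation.
* **Compositional profiling** — relative abundances, mean relative
  abundance (MRA) summaries, per-sample "other" grouping for plotting, and
  the prevalence-threshold **core bacteriome** (features present in ≥ 80 %
  of samples, inclusive).
* **Alpha diversity** — Shannon–Weaver index
  H = −Σ p_i log p_i and bias-corrected Chao1 richness
  S_chao1 = S_obs + F₁(F₁−1) / (2(F₂+1)), rarefaction curves by
  hypergeometric subsampling, and the strict < 1000-read depth filter.
* **Community typing** — Bray–Curtis dissimilarity
  d_jk = Σ|p_ij − p_ik| / Σ(p_ij + p_ik), complete-linkage hierarchical
  clustering cut at height 0.8, with the number of community types selected
  by the Calinski–Harabasz index CH(k) = [B/(k−1)] / [W/(n−k)] (computed on
  PCoA coordinates) and validated by mean silhouette width.
* **Compositional geometry** — Bayesian-multiplicative zero replacement,
  centered log-ratio (CLR) transform, Aitchison distances, and
  lambda-scaled log-ratio biplots whose row and column markers have equal
  total spread.
* **Co-occurrence networks** — genus-level Pearson correlations of CLR
  abundances, thresholded at |r| > 0.28, for all samples and per community
  type.
* **Inference** — single-factor permutation PERMANOVA
  (pseudo-F = [SS_A/(a−1)] / [SS_W/(N−a)], p = (1 + #{F_perm ≥ F_obs})/(B+1)),
  Benjamini–Hochberg FDR across covariate × taxonomy-level scans, one-way
  ANOVA of alpha diversity, and replicate-reproducibility R².

A Dirichlet-multinomial **cohort simulator** reproduces the statistical
structure these analyses assume — three community types
(*Staphylococcus*-dominant, mixed, *Streptococcus*-dominant), a shared
reagent background appearing in both samples and spiked NTCs, and duplicate
library preparations — so the whole pipeline is testable without sequence
data, with known ground truth.

## Worked example

```r
library(milkbiome)

sp     <- cohort_spec(n_samples = c(15, 15, 15), n_ntc = 4)
cohort <- generate_cohort(sp, seed = 42)
cohort$table
#> count_table: 18 features x 49 samples (45 biological, 4 spiked-NTC, 0 replicate)
#>   read depth: median 7546, range 1856-28137

catalog <- identify_background(cohort$table, sp$spike_feature)
catalog
#> background_catalog: 4 features from 4 spiked NTCs
#>      OTU_Ralstonia   OTU_Sphingomonas OTU_Bradyrhizobium  OTU_Cutibacterium
#>             125.75              75.50              54.50              52.25
cleaned <- subtract_background(cohort$table, catalog)

genus <- collapse_to_rank(cleaned, cohort$taxonomy, "genus")
comp  <- abundance_filter(to_relative(genus), 0.005, mode = "dataset_mra")
d     <- bray_curtis(comp)
types <- hierarchical_cluster(d, cut_height = 0.8)
sel   <- select_k(d, types, 2:6)
sel
#> k_selection: selected k = 3
#>  k        ch silhouette
#>  2  82.57659  0.6371199
#>  3 198.69614  0.7994406
#>  4 139.65502  0.6675524
#>  5 107.78496  0.4891380
#>  6  89.16993  0.4521696

permanova(d, cohort$truth$true_cluster, B = 999, seed = 1)
#> PERMANOVA: pseudo-F(2, 42) = 636.6, p = 0.001 (999 permutations)
#>   SS between 4.453 | within 0.1469 | total 4.6 | R2 = 0.968
```

The spiked controls catalogue the four planted reagent contaminants with
their per-NTC mean read counts; after subtraction and genus-level
collapsing, Calinski–Harabasz selection recovers the three generating
community types (CH peaks at k = 3 with mean silhouette 0.80), and
PERMANOVA confirms that community type explains essentially all
between-sample Bray–Curtis structure (R² = 0.97, smallest attainable p at
999 permutations).

## Analysis workflow

The `analysis/` directory is a numbered workflow over the package —
simulate a cohort, decontaminate, depth-filter and tabulate diversity,
profile composition and the core bacteriome, type communities, build
networks, and scan covariates by PERMANOVA:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_decontaminate.R
# ... through analysis/07_associations.R
```

Each script prints a short narrative of what it found and writes its
tables under `results/`.

## Vignette

`vignettes/milk-bacteriome-workflow.Rmd` documents the models, the
parameter choices and their defaults, what the simulator does and does not
emulate, and the package's resolutions of the places where the original
analysis description is ambiguous.
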