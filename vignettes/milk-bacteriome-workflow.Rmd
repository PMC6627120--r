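---
title: "Models and methods of the milk bacteriome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the milk bacteriome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkbiome)
```

This vignette is the package's own account of the science it implements:
the models behind each stage, the tunable parameters and their defaults,
what the cohort simulator does and does not emulate, and the choices made
where the underlying analysis description was genuinely open.

## The problem

Human breast milk is a low-biomass specimen. Two consequences dominate
its 16S analysis. First, DNA in extraction kits and reagents (the
"kitome") is sequenced alongside the real community and can contribute a
non-trivial share of reads, so contamination must be measured and removed
rather than assumed away. Second, amplicon counts are compositional: only
the relative sizes of the parts are informative, library size is an
artefact, and ordinary covariances and Euclidean distances on raw
proportions can be misleading. The pipeline treats both problems
explicitly: a spiked-control subtraction step for the first, and
log-ratio (CLR/Aitchison) geometry alongside Bray–Curtis ecology for the
second.

## Spiked-NTC decontamination

The experimental design sequesters the kitome in *spiked no-template
controls*: extraction blanks spiked with DNA of a taxon known to be
absent from milk (a *Mycobacterium smegmatis*-like spike), at a 16S
concentration similar to real samples, so that reagent contaminants are
sequenced at sample-like depth rather than being amplified into noise.

The correction has two halves:

* `identify_background()` removes the spike from the spiked-NTC columns
  and catalogues every remaining feature with a positive count in any
  control as *background*, recording its arithmetic mean read count
  across all spiked-NTC columns. Zeros count in the denominator: a
  feature seen at 8 reads in one of two controls has mean 4.
* `subtract_background()` removes that mean from every biological
  column, flooring at zero. Features never seen in the controls are
  untouched — removal is bounded feature-by-feature by what the controls
  actually contained, which is the guard against over-compensation.

Three places were open and are settled as follows:

* **Rounding.** Whether the mean is rounded before subtraction is not
  determined by the design; the default rounds half-up
  (`rounding = "half_up"`), with truncation (`"floor"`) and real-valued
  subtraction followed by flooring (`"none"`) behind the flag. On
  realistic depths the three differ by at most one read per feature.
* **Run structure.** When each sequencing run has its own spiked NTCs,
  per-run means are arguably the better estimate of that run's reagent
  load. `identify_background(..., runs = )` computes both; subtraction
  uses the run-matched means when run labels are supplied and the pooled
  means otherwise. Pooled is the default because the catalog is then a
  single object with a single interpretation.
* **Matching.** The default matches catalog to table features by exact
  feature ID, the table-level analogue of 100%-identity full-length
  alignment of representative sequences. When representative sequences
  are available, `match_background_sequences()` re-keys the catalog by
  exact string equality of sequences, the bit-reproducible form of that
  alignment.

The subtraction estimates the *expected* contaminant reads; the realized
contaminant draw in any one sample differs by multinomial noise, so the
correction reduces, but cannot eliminate, contamination error. The
package's simulations quantify this: across contamination fractions
0.01–0.2 the mean absolute error of post-subtraction compositions against
the contamination-free truth is smaller than the pre-subtraction error in
every simulated cell.

## Depth filtering, diversity, core

Samples below 1000 reads are removed (`filter_min_depth()`), the depth at
which milk Shannon rarefaction curves plateau; the bound is strict
(`< 1000`), so a 1000-read sample survives. Alpha diversity uses the
Shannon–Weaver index (natural log by default — the log base is exposed
rather than guessed, since ecosystems differ; `base = 2` gives bits) and
Chao1 richness in its bias-corrected form
$S_{chao1} = S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which is defined even with
no doubletons; the classic $F_1^2/(2F_2)$ variant sits behind
`bias_corrected = FALSE`. Rarefaction subsamples reads without
replacement (multivariate hypergeometric), seeded, so rarefied counts sum
exactly to the requested depth.

The core bacteriome is the set of features with a positive count in at
least 80% of biological samples; the threshold is inclusive, and
prevalence is computed after decontamination and after the depth filter
(computing it before the filter would let unusable libraries vote on
membership).

## Community typing

Samples are clustered on genus-level Bray–Curtis dissimilarities of
relative abundances, restricted to genera above 0.5% mean relative
abundance (the `dataset_mra` filter, which fixes one feature set across
samples — a per-sample filter would give different features per column
and break the distance computation; per-sample "other" grouping exists
separately for barplots). Complete linkage is used throughout: its merge
heights are monotone, and a fixed cut at height 0.8 defines the community
types, with clusters smaller than `min_size = 5` set aside, mirroring the
practice of excluding tiny residual clusters from group comparisons.

The number of types is chosen by the Calinski–Harabasz index,
$CH(k) = [B(k)/(k-1)]/[W(k)/(n-k)]$. CH is defined on coordinates, not
distances, and the choice of space matters: here it is computed on all
positive-eigenvalue principal-coordinate (PCoA) axes of the Bray–Curtis
matrix, which is faithful to the distance structure without inventing a
feature space. Mean silhouette width, computed directly on the
dissimilarities, is reported alongside as validation. Ties in the CH
argmax break toward smaller k (parsimony). Both the fixed-cut labels and
the CH-selected labels are reported side by side; on simulated
three-type cohorts the 0.8 cut can merge the mixed type into a neighbour
(their complete-linkage height falls below 0.8) while CH selection
recovers k = 3 — which is why both code paths exist.

PCoA itself is classical scaling: Gower double-centering of $-d^2/2$ and
eigendecomposition. Bray–Curtis is not Euclidean, so negative eigenvalues
occur; they are reported and their axes dropped (variance explained is
quoted relative to the positive-eigenvalue total).

## Compositional geometry

Log-ratio methods need strictly positive compositions, so zeros are
replaced first. `zero_replace()` implements Bayesian-multiplicative
replacement with a Dirichlet prior of strength $\alpha$ per feature
(default 0.5, Jeffreys-like; the literature offers several prior
variants, and the parameter is exposed rather than fixed): a zero cell of
sample $j$ becomes $\delta_{ij} = \alpha_i/(n_j + \sum_k \alpha_k)$ and
the nonzero cells are shrunk multiplicatively so the column stays on the
simplex. Multiplicative adjustment preserves the ratios among observed
parts exactly — the property the subsequent transforms rely on.

The CLR transform, Aitchison distance (Euclidean on CLR; a true metric,
perturbation-invariant) and the log-ratio biplot follow. The biplot is
the SVD of the doubly centered CLR matrix in column-principal form
($\gamma = 0$), with lambda-scaling: row markers are multiplied and
column markers divided by
$\lambda = (\sum\lVert col\rVert^2 / \sum\lVert row\rVert^2)^{1/4}$,
which equalizes the total spread of sample and taxon markers without
changing the inner products that reconstruct the data.

## Co-occurrence networks

Networks are built at genus level: collapse, MRA-filter at 0.5%,
zero-replace, CLR, Pearson correlations across samples, and a hard edge
threshold $|r| > 0.28$. Correlating CLR coordinates rather than raw
proportions is a deliberate choice: proportions force spurious negative
correlation (the parts must sum to one), and CLR largely removes that
artefact. A raw-proportion mode remains behind `use_clr = FALSE` for
comparison. When networks are built per community type, the MRA filter is
recomputed within each subset, so each network reflects its own
abundance structure.

```{r network-example}
co <- generate_block_cohort(n_samples = 60, seed = 1)
net <- build_network(co$table, co$taxonomy, r_cutoff = 0.28)
net
```

## Inference

`permanova()` implements single-factor permutational multivariate
analysis of variance on any dissimilarity:
$SS_T = \frac{1}{N}\sum_{j<k} d_{jk}^2$,
$SS_W = \sum_g \frac{1}{n_g}\sum_{j<k \in g} d_{jk}^2$,
pseudo-$F = [SS_A/(a-1)]/[SS_W/(N-a)]$, with the p-value from unrestricted
random label permutations, the identity permutation always counted:
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(B+1)$, so $p \in [1/(B+1), 1]$ and
is deterministic given the seed. The default $B = 999$. On Euclidean
distances the decomposition coincides with coordinate-space ANOVA, and
the implementation is cross-checked against `vegan::adonis2` in the test
suite. Both Bray–Curtis and Aitchison distances are supported in the
covariate scan (`permanova_scan()`) — the two are genuinely different
lenses (ecological vs log-ratio geometry) and neither is privileged;
multi-factor sequential models are out of the tested core, since
sequential term addition is order-dependent.

The scan runs every covariate at every requested taxonomy level and
corrects the whole family with Benjamini–Hochberg; alpha-diversity group
differences use one-way ANOVA (for a single factor, the Type II test
coincides with the classical decomposition); replicate reproducibility is
the $R^2$ of regressing a duplicate library's per-OTU counts on its
partner's.

## The cohort simulator

`generate_cohort()` draws, per biological sample of community type $c$:
a composition $p \sim \mathrm{Dirichlet}(\pi_c \cdot \theta)$ around the
type's expected profile $\pi_c$ with concentration $\theta$, a library
size from a log-normal, biological reads
$\mathrm{Multinomial}(n_{bio}, p)$, and contaminant reads
$\mathrm{Multinomial}(n \cdot f, \beta)$ from a shared background
composition $\beta$. Spiked-NTC columns contain spike reads plus a
background draw only. The defaults are the study conditions the analyses
assume:

* three genus profiles — *Staphylococcus*-dominant (0.75), mixed
  (*Staphylococcus* 0.40 / *Streptococcus* 0.40), and
  *Streptococcus*-dominant (0.75) — over the core milk genera
  (*Streptococcus*, *Staphylococcus*, *Rothia*, *Corynebacterium*,
  *Veillonella*, *Gemella*, *Acinetobacter*, *Micrococcus*, an unassigned
  Enterobacteriaceae member) plus minor genera; 40 samples per type;
  concentration $\theta = 200$;
* log-normal library sizes with median ≈ 8000 reads
  (`depth_meanlog = log(8000)`, `depth_sdlog = 0.55`), the depth scale of
  milk amplicon libraries, with `n_low_depth` samples forced below 1000
  reads to exercise the depth filter;
* contaminant fraction $f = 0.03$ over a four-genus kitome background
  (*Ralstonia*, *Sphingomonas*, *Bradyrhizobium*, *Cutibacterium* —
  water- and skin-associated genera typical of reagent contamination).
  The true contamination load of milk-study NTCs is not knowable from
  the sequenced output alone; 3% is a realistic reagent share for
  low-biomass work and is a free parameter, not a claim about any
  particular study;
* spiked NTCs drawn at sample-like total depth (that is what spiking at
  sample-like 16S concentration achieves), with the same background
  fraction, so NTC background counts estimate per-sample contaminant
  counts without systematic bias.

`GroundTruth$true_composition` records the *realized* proportions of the
biological (non-contaminant) reads actually drawn — not the Dirichlet
expectation — so that at contamination 0 the observed table equals the
truth exactly and recovery errors measure decontamination alone, not
multinomial noise.

One OTU per genus is the default; `otus_per_genus > 1` fans each genus
into OTUs with cohort-level Dirichlet split weights, separating OTU-level
from genus-level code paths (core bacteriome vs genus collapsing).
`generate_replicate_pair()` emulates duplicate library preparation by
re-drawing a multinomial sample from a column's observed proportions.
`generate_block_cohort()` is a separate logistic-normal generator with a
planted latent factor: oral genera (*Streptococcus*, *Rothia*,
*Veillonella*, *Gemella*) load positively, skin genera (*Staphylococcus*,
*Corynebacterium*) negatively, producing the within-block positive /
across-block negative correlation structure that co-occurrence networks
should recover.

What the simulator does **not** emulate: sequence-level error (chimeras,
PCR substitution), taxonomy misassignment, the long tail of hundreds of
rare OTUs in real tables, overdispersion beyond Dirichlet-multinomial,
batch effects other than the run structure of the controls, and
covariate-driven composition shifts (the generated covariates are null by
construction). Passing simulation tests therefore demonstrates that the
estimators and the correction behave as designed under their assumed
model — not that any particular real cohort satisfies those assumptions.

## Simulation scales and numerical choices

The validation suite uses problem sizes chosen to make the Monte Carlo
error of each check small relative to its margin: 100 random inputs per
formula-equivalence check at $10^{-9}$ tolerance; 20 seeds × 4
contamination fractions (60-sample cohorts, 4 NTCs) for decontamination
recovery; 20 seeds of the 120-sample three-type cohort for community-type
recovery (adjusted Rand index against generating labels); 1000
structureless 20-sample replicates at $B = 199$ for PERMANOVA type-I
error and 100 replicates at $n = 30$ per group for power, with group 2
shifted by one pooled SD per CLR coordinate (the conventional
unit-effect-size simulation design); 20 seeds for network sign recovery;
10 duplicate pairs at depth $10^5$ for replicate $R^2$.
`scripts/acceptance.R` re-runs the same computations from scratch under a
caller-supplied seed.

Numerical conventions worth knowing: count validation tolerates only
whole numbers; zero-total samples are an error everywhere (they carry no
compositional information); eigenvalues within machine tolerance of zero
are treated as zero in PCoA; the CH argmax breaks ties toward smaller k;
`half_up` rounding is `floor(x + 0.5)`; all stochastic functions take an
explicit seed and restore the caller's RNG state.

## Known limitations

* Decontamination subtracts an expected count; it cannot undo
  sample-specific contamination bursts, and it assumes the spike taxon is
  truly absent from biological samples.
* The fixed 0.8 cut and CH selection can disagree; the package reports
  both rather than reconciling them.
* Single-factor PERMANOVA only is validated; sequential multi-factor
  models inherit term-order dependence and are intentionally outside the
  tested surface.
* Bray–Curtis violates the triangle inequality; nothing here relies on
  it, but consumers of the distance matrices should not either.
* The network threshold (|r| > 0.28) is a hard cutoff with no edge-level
  inference; edges near the threshold are unstable under resampling.
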