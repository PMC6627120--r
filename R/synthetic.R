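#' Default genus-level community profiles of the three milk community types
#'
#' Expected genus compositions for the three community types observed in
#' human breast milk: a Staphylococcus-dominant type, a mixed
#' Staphylococcus/Streptococcus type, and a Streptococcus-dominant type.
#' The remaining mass is spread over the other core milk genera
#' (Rothia, Corynebacterium, Veillonella, Gemella, Acinetobacter,
#' Micrococcus, an unassigned Enterobacteriaceae member) plus a few minor
#' genera seen in milk (Pseudomonas, Enhydrobacter, Lactobacillus,
#' Bifidobacterium).
#'
#' @return list of three named proportion vectors, each summing to 1.
#' @export
default_cluster_profiles <- function() {
  minor <- c(Rothia = 0.06, Corynebacterium = 0.03, Veillonella = 0.03,
             Gemella = 0.02, Acinetobacter = 0.02, Micrococcus = 0.01,
             `Enterobacteriaceae_unassigned` = 0.01, Pseudomonas = 0.005,
             Enhydrobacter = 0.005, Lactobacillus = 0.005, Bifidobacterium = 0.005)
  fill <- function(staph, strep) {
    v <- c(Staphylococcus = staph, Streptococcus = strep, minor)
    v / sum(v)
  }
  list(
    staphylococcus_dominant = fill(0.75, 0.05),
    mixed                   = fill(0.40, 0.40),
    streptococcus_dominant  = fill(0.05, 0.75)
  )
}

#' Specification of a synthetic milk bacteriome cohort
#'
#' Captures everything the generator needs: per-cluster sample sizes and
#' expected genus compositions, a Dirichlet concentration controlling
#' within-cluster overdispersion, a log-normal library-size distribution,
#' a reagent-contamination background shared between biological samples and
#' no-template controls, and a spike taxon (Mycobacterium, mimicking an
#' M. smegmatis spike) for the spiked NTCs.
#'
#' @param n_samples integer vector, samples per cluster.
#' @param cluster_profiles list of named genus-proportion vectors (sum 1),
#'   one per cluster.
#' @param concentration Dirichlet concentration scalar (or per-cluster
#'   vector); larger means tighter clusters.
#' @param depth_meanlog,depth_sdlog log-normal library-size parameters;
#'   defaults give a median depth near 8000 reads.
#' @param contamination_fraction expected fraction of each library's reads
#'   contributed by the reagent background.
#' @param background named proportion vector over contaminant features.
#' @param spike_feature feature ID of the spike taxon in NTCs.
#' @param n_ntc number of spiked no-template controls.
#' @param otus_per_genus integer: 1 keeps one OTU per genus; larger values
#'   fan each genus into several OTUs with Dirichlet-split weights so that
#'   OTU-level and genus-level code paths differ.
#' @param n_low_depth number of biological samples forced below 1000 reads,
#'   to exercise the minimum-depth filter.
#' @param seed integer seed stored with the spec; `generate_cohort()` may
#'   override it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = c(40, 40, 40),
                        cluster_profiles = default_cluster_profiles(),
                        concentration = 200,
                        depth_meanlog = log(8000),
                        depth_sdlog = 0.55,
                        contamination_fraction = 0.03,
                        background = c(Ralstonia = 0.4, Sphingomonas = 0.25,
                                       Bradyrhizobium = 0.2, Cutibacterium = 0.15),
                        spike_feature = "OTU_Mycobacterium_spike",
                        n_ntc = 4,
                        otus_per_genus = 1,
                        n_low_depth = 0,
                        seed = 1L) {
  if (length(n_samples) != length(cluster_profiles))
    stop("n_samples and cluster_profiles must have one entry per cluster")
  if (any(n_samples < 0) || n_ntc < 0) stop("sample counts must be >= 0")
  for (p in cluster_profiles) {
    if (length(p) == 0 || any(p < 0)) stop("cluster profile must be non-empty and non-negative")
    if (abs(sum(p) - 1) > 1e-12) stop("cluster profile must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-12 || any(background < 0))
    stop("background must be a proportion vector summing to 1")
  if (contamination_fraction < 0 || contamination_fraction >= 1)
    stop("contamination_fraction must be in [0, 1)")
  if (concentration <= 0) stop("concentration must be positive")
  if (otus_per_genus < 1) stop("otus_per_genus must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 cluster_profiles = cluster_profiles,
                 concentration = rep(concentration, length.out = length(n_samples)),
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 contamination_fraction = contamination_fraction,
                 background = background,
                 spike_feature = spike_feature,
                 n_ntc = as.integer(n_ntc),
                 otus_per_genus = as.integer(otus_per_genus),
                 n_low_depth = as.integer(n_low_depth),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Biological sample counts are drawn as
#' multinomial(depth, Dirichlet(cluster profile x concentration)), with an
#' added multinomial draw of contaminant reads from the shared background.
#' Spiked-NTC columns contain spike reads plus background reads only —
#' never reads from biological genera — mirroring a no-template extraction
#' control spiked with a known taxon at sample-like concentration.
#' Deterministic given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return list with elements:
#'   \describe{
#'     \item{table}{[count_table()] of OTU counts (biological + NTC columns)}
#'     \item{taxonomy}{`taxonomy_map` covering every feature}
#'     \item{metadata}{data.frame of sample_id, role, cluster and two
#'       unstructured covariates (site, delivery_mode)}
#'     \item{truth}{list: `true_cluster` (named labels),
#'       `true_composition` (feature x sample realized contamination-free
#'       proportions), `contaminant_features`, `contaminant_reads`
#'       (feature x sample matrix actually added)}
#'   }
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  genera <- unique(unlist(lapply(spec$cluster_profiles, names)))
  k <- length(spec$n_samples)

  # fan genera out into OTUs with cohort-level Dirichlet split weights
  if (spec$otus_per_genus > 1) {
    splits <- lapply(genera, function(g)
      as.numeric(rdirichlet(1, rep(2, spec$otus_per_genus))))
    names(splits) <- genera
    bio_features <- unlist(lapply(genera, function(g)
      paste0("OTU_", g, "_", seq_len(spec$otus_per_genus))))
    feat_genus <- rep(genera, each = spec$otus_per_genus)
  } else {
    splits <- NULL
    bio_features <- paste0("OTU_", genera)
    feat_genus <- genera
  }
  contam_features <- paste0("OTU_", names(spec$background))
  features <- c(bio_features, contam_features, spec$spike_feature)

  expand_profile <- function(p) {
    full <- stats::setNames(numeric(length(genera)), genera)
    full[names(p)] <- p
    if (is.null(splits)) return(stats::setNames(as.numeric(full), bio_features))
    stats::setNames(unlist(lapply(genera, function(g) full[g] * splits[[g]])),
                    bio_features)
  }

  n_bio <- sum(spec$n_samples)
  bio_ids <- sprintf("S%03d", seq_len(n_bio))
  ntc_ids <- if (spec$n_ntc > 0) sprintf("NTC%02d", seq_len(spec$n_ntc)) else character(0)
  clusters <- rep(seq_len(k), spec$n_samples)

  counts <- matrix(0, nrow = length(features), ncol = n_bio + spec$n_ntc,
                   dimnames = list(features, c(bio_ids, ntc_ids)))
  true_comp <- matrix(0, nrow = length(features), ncol = n_bio,
                      dimnames = list(features, bio_ids))
  contam_reads <- matrix(0, nrow = length(features), ncol = n_bio + spec$n_ntc,
                         dimnames = list(features, c(bio_ids, ntc_ids)))

  depths <- pmax(round(stats::rlnorm(n_bio, spec$depth_meanlog, spec$depth_sdlog)), 10)
  if (spec$n_low_depth > 0) {
    low <- sample(n_bio, min(spec$n_low_depth, n_bio))
    depths[low] <- sample(50:900, length(low), replace = TRUE)
  }

  for (j in seq_len(n_bio)) {
    prof <- expand_profile(spec$cluster_profiles[[clusters[j]]])
    conc <- spec$concentration[clusters[j]]
    p <- as.numeric(rdirichlet(1, pmax(prof * conc, 1e-8)))
    n_cont <- round(depths[j] * spec$contamination_fraction)
    n_bio_reads <- depths[j] - n_cont
    x_bio <- as.numeric(stats::rmultinom(1, n_bio_reads, p))
    counts[bio_features, j] <- x_bio
    true_comp[bio_features, j] <- x_bio / sum(x_bio)
    if (n_cont > 0) {
      x_cont <- as.numeric(stats::rmultinom(1, n_cont, spec$background))
      counts[contam_features, j] <- x_cont
      contam_reads[contam_features, j] <- x_cont
    }
  }

  for (j in seq_len(spec$n_ntc)) {
    col <- n_bio + j
    ntc_depth <- pmax(round(stats::rlnorm(1, spec$depth_meanlog, spec$depth_sdlog)), 10)
    n_cont <- round(ntc_depth * max(spec$contamination_fraction, 0))
    counts[spec$spike_feature, col] <- ntc_depth - n_cont
    if (n_cont > 0) {
      x_cont <- as.numeric(stats::rmultinom(1, n_cont, spec$background))
      counts[contam_features, col] <- x_cont
      contam_reads[contam_features, col] <- x_cont
    }
  }

  roles <- c(rep("biological", n_bio), rep("ntc_spiked", spec$n_ntc))
  tb <- count_table(counts, roles = roles)

  tax <- synth_taxonomy(bio_features, feat_genus, contam_features,
                        names(spec$background), spec$spike_feature)

  metadata <- data.frame(
    sample_id = c(bio_ids, ntc_ids),
    role = roles,
    cluster = c(paste0("cluster", clusters), rep(NA_character_, spec$n_ntc)),
    site = c(sample(c("siteA", "siteB"), n_bio, replace = TRUE),
             rep(NA_character_, spec$n_ntc)),
    delivery_mode = c(sample(c("vaginal", "caesarean"), n_bio, replace = TRUE,
                             prob = c(0.81, 0.19)),
                      rep(NA_character_, spec$n_ntc)),
    stringsAsFactors = FALSE
  )

  truth <- list(
    true_cluster = stats::setNames(paste0("cluster", clusters), bio_ids),
    true_composition = true_comp,
    contaminant_features = contam_features,
    contaminant_reads = contam_reads
  )
  list(table = tb, taxonomy = tax, metadata = metadata, truth = truth)
}

# Plausible lineages for the simulated genera; milk taxa get their real
# phylum-level placement, contaminants get theirs, the spike is Mycobacterium.
synth_taxonomy <- function(bio_features, feat_genus, contam_features,
                           contam_genera, spike_feature) {
  phylum_of <- c(Staphylococcus = "Firmicutes", Streptococcus = "Firmicutes",
                 Veillonella = "Firmicutes", Gemella = "Firmicutes",
                 Lactobacillus = "Firmicutes",
                 Rothia = "Actinobacteria", Corynebacterium = "Actinobacteria",
                 Micrococcus = "Actinobacteria", Bifidobacterium = "Actinobacteria",
                 Cutibacterium = "Actinobacteria",
                 Acinetobacter = "Proteobacteria", Pseudomonas = "Proteobacteria",
                 Enhydrobacter = "Proteobacteria",
                 Enterobacteriaceae_unassigned = "Proteobacteria",
                 Ralstonia = "Proteobacteria", Sphingomonas = "Proteobacteria",
                 Bradyrhizobium = "Proteobacteria")
  lineage_of <- function(genus) {
    ph <- phylum_of[genus]
    if (is.na(ph)) ph <- "Firmicutes"
    if (genus == "Enterobacteriaceae_unassigned") {
      sprintf("k__Bacteria;p__%s;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__", ph)
    } else {
      sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s", ph, genus)
    }
  }
  ids <- c(bio_features, contam_features, spike_feature)
  gen <- c(feat_genus, contam_genera, "Mycobacterium")
  lines <- paste(ids, vapply(gen, lineage_of, character(1)), sep = "\t")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  read_taxonomy(tmp)
}

#' Append a replicate library preparation of an existing sample
#'
#' Draws a fresh multinomial sample of `depth` reads from the observed
#' proportion vector of `sample`, emulating a duplicate library prep and
#' sequencing run of the same DNA extract, and appends it as a column with
#' role `replicate`.
#'
#' @param table a `count_table`.
#' @param sample sample ID to replicate.
#' @param depth read depth of the replicate library; defaults to the
#'   original sample's depth.
#' @param seed integer seed.
#' @return a `count_table` with one extra column named `<sample>_rep`.
#' @export
generate_replicate_pair <- function(table, sample, depth = NULL, seed = 1L) {
  if (!sample %in% sample_ids(table)) stop("unknown sample ID: ", sample)
  x <- table$counts[, sample]
  if (sum(x) == 0) stop("sample has zero reads: ", sample)
  if (is.null(depth)) depth <- sum(x)
  rep_counts <- with_seed(seed, as.numeric(stats::rmultinom(1, depth, x / sum(x))))
  new_id <- paste0(sample, "_rep")
  counts <- cbind(table$counts, rep_counts)
  colnames(counts)[ncol(counts)] <- new_id
  count_table(counts,
              roles = c(table$roles, stats::setNames("replicate", new_id)),
              replicate_of = c(table$replicate_of, stats::setNames(sample, new_id)))
}

#' Generate a cohort with planted genus co-variation blocks
#'
#' A logistic-normal community model in which the oral genera
#' (Streptococcus, Rothia, Veillonella, Gemella) load positively and the
#' skin genera (Staphylococcus, Corynebacterium) negatively on one latent
#' factor, so that within-block abundances co-vary positively while
#' Streptococcus and Staphylococcus anti-correlate — the sign structure
#' co-occurrence networks should recover.
#'
#' @param n_samples number of biological samples.
#' @param loading latent-factor loading magnitude (log scale).
#' @param noise_sd per-genus log-normal noise SD.
#' @param depth_meanlog,depth_sdlog log-normal library-size parameters.
#' @param seed integer seed.
#' @return list with `table` (count_table), `taxonomy` (taxonomy_map),
#'   `blocks` (list of oral/skin genus names).
#' @export
generate_block_cohort <- function(n_samples = 60, loading = 0.8, noise_sd = 0.4,
                                  depth_meanlog = log(8000), depth_sdlog = 0.4,
                                  seed = 1L) {
  oral <- c("Streptococcus", "Rothia", "Veillonella", "Gemella")
  skin <- c("Staphylococcus", "Corynebacterium")
  others <- c("Acinetobacter", "Micrococcus", "Pseudomonas", "Enhydrobacter")
  genera <- c(oral, skin, others)
  base <- c(Streptococcus = 0.35, Rothia = 0.08, Veillonella = 0.06,
            Gemella = 0.04, Staphylococcus = 0.25, Corynebacterium = 0.07,
            Acinetobacter = 0.05, Micrococcus = 0.03, Pseudomonas = 0.04,
            Enhydrobacter = 0.03)[genera]
  lambda <- stats::setNames(rep(0, length(genera)), genera)
  lambda[oral] <- loading
  lambda[skin] <- -loading

  with_seed(seed, {
    f <- stats::rnorm(n_samples)
    depths <- pmax(round(stats::rlnorm(n_samples, depth_meanlog, depth_sdlog)), 100)
    counts <- sapply(seq_len(n_samples), function(j) {
      eta <- log(base) + lambda * f[j] + stats::rnorm(length(genera), sd = noise_sd)
      p <- exp(eta) / sum(exp(eta))
      as.numeric(stats::rmultinom(1, depths[j], p))
    })
    dimnames(counts) <- list(paste0("OTU_", genera),
                             sprintf("S%03d", seq_len(n_samples)))
    tb <- count_table(counts)
    tax <- synth_taxonomy(rownames(counts), genera, character(0), character(0),
                          "OTU_placeholder_spike")
    tax <- tax[tax$feature_id != "OTU_placeholder_spike", , drop = FALSE]
    list(table = tb, taxonomy = tax, blocks = list(oral = oral, skin = skin))
  })
}
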