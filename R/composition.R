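#' Transform read counts to relative abundances
#'
#' Divides each column by its total, turning the count table into
#' compositional data (each sample a point on the simplex).
#'
#' @param table a `count_table`.
#' @return an object of class `composition_table`: list with `proportions`
#'   (feature x sample, columns sum to 1) and the source table's `roles`.
#' @export
to_relative <- function(table) {
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(sample_ids(table)[tot == 0], collapse = ", "))
  structure(list(proportions = sweep(table$counts, 2, tot, "/"),
                 roles = table$roles),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table: %d features x %d samples\n",
              nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}

#' Mean relative abundance per feature
#'
#' Arithmetic mean across biological samples of each feature's
#' within-sample proportion (MRA), the abundance summary used to rank taxa
#' and to gate clustering and network inputs.
#'
#' @param comp a `composition_table`.
#' @param biological_only if `TRUE` (default) only columns flagged
#'   biological enter the mean.
#' @return named numeric vector, one MRA per feature.
#' @export
mean_relative_abundance <- function(comp, biological_only = TRUE) {
  p <- comp$proportions
  if (biological_only && !is.null(comp$roles)) {
    keep <- comp$roles == "biological"
    if (!any(keep)) stop("no biological samples")
    p <- p[, keep, drop = FALSE]
  }
  rowMeans(p)
}

#' Filter a composition by abundance
#'
#' Two modes matching two distinct uses:
#' \describe{
#'   \item{`per_sample_other`}{for plotting: in each column, entries below
#'     `threshold` are moved into a single `"other"` row, so column sums
#'     are preserved exactly.}
#'   \item{`dataset_mra`}{for clustering/network inputs: rows whose mean
#'     relative abundance is <= `threshold` are dropped; remaining columns
#'     are NOT renormalized, so the retained feature set is fixed across
#'     samples.}
#' }
#'
#' @param comp a `composition_table`.
#' @param threshold abundance fraction in (0, 1); entries/rows must exceed
#'   it strictly to survive. `0` in `dataset_mra` mode is allowed and is
#'   the identity.
#' @param mode `"per_sample_other"` or `"dataset_mra"`.
#' @return a `composition_table`.
#' @export
abundance_filter <- function(comp, threshold = 0.005,
                             mode = c("dataset_mra", "per_sample_other")) {
  mode <- match.arg(mode)
  p <- comp$proportions
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  if (mode == "per_sample_other") {
    low <- p < threshold
    other <- colSums(p * low)
    kept <- p * !low
    out <- rbind(kept[rowSums(!low) > 0, , drop = FALSE], other = other)
  } else {
    mra <- rowMeans(p)
    keep <- mra > threshold
    if (!any(keep)) stop("abundance filter removed every feature")
    out <- p[keep, , drop = FALSE]
  }
  structure(list(proportions = out, roles = comp$roles),
            class = "composition_table")
}

#' Core bacteriome by prevalence threshold
#'
#' The core is the set of features present (count > 0) in at least
#' `threshold` of the biological samples — an inclusive bound, so a
#' feature seen in exactly 80% of samples belongs to an 80% core.
#'
#' @param table a `count_table` (typically post-decontamination, post
#'   depth filter).
#' @param threshold prevalence fraction in (0, 1].
#' @param tax optional `taxonomy_map`; if given, the genus labels of core
#'   features are reported.
#' @return an object of class `core_report`: list with `threshold`,
#'   `prevalence` (named, all features), `core_features` (named prevalence
#'   of features meeting the threshold), and `core_taxa` (character,
#'   possibly empty).
#' @export
core_features <- function(table, threshold = 0.8, tax = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  bio <- biological_samples(table)
  if (length(bio) == 0) stop("no biological samples")
  m <- table$counts[, bio, drop = FALSE]
  prevalence <- rowMeans(m > 0)
  core <- prevalence[prevalence >= threshold]
  core_taxa <- character(0)
  if (!is.null(tax) && length(core) > 0) {
    g <- tax$genus[match(names(core), tax$feature_id)]
    f <- tax$family[match(names(core), tax$feature_id)]
    lab <- ifelse(is.na(g), ifelse(is.na(f), "unassigned", paste0(f, ";g__")), g)
    core_taxa <- sort(unique(lab))
  }
  structure(list(threshold = threshold, prevalence = prevalence,
                 core_features = core, core_taxa = core_taxa),
            class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("core_report: %d features at prevalence >= %g\n",
              length(x$core_features), x$threshold))
  if (length(x$core_taxa) > 0)
    cat("  taxa:", paste(x$core_taxa, collapse = ", "), "\n")
  invisible(x)
}
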