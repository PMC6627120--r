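#' Catalogue reagent background features from spiked no-template controls
#'
#' Spiked NTCs contain only the spike taxon plus whatever the reagents and
#' buffers contributed, sequenced at sample-like depth. After setting the
#' spike aside, every feature observed in any spiked-NTC column is treated
#' as reagent background, and its mean read count is taken across all
#' spiked-NTC columns (zeros included in the denominator).
#'
#' @param table a `count_table` with at least one `ntc_spiked` column.
#' @param spike_feature feature ID of the spike taxon.
#' @param runs optional named vector mapping sample IDs to sequencing-run
#'   labels. When given, per-run mean read counts are also computed (one
#'   set per run that contains a spiked NTC), so subtraction can use the
#'   run each sample was sequenced in; the pooled means remain the
#'   default.
#' @return an object of class `background_catalog`: list with
#'   `background_features`, `mean_reads` (named, keyed exactly by
#'   `background_features`), `n_ntc_used`, and (when `runs` is supplied)
#'   `run_means`, a list of per-run mean-read vectors.
#' @export
identify_background <- function(table, spike_feature, runs = NULL) {
  ntc <- sample_ids(table)[table$roles == "ntc_spiked"]
  if (length(ntc) == 0) stop("no spiked-NTC columns in table")
  if (!spike_feature %in% feature_ids(table))
    stop("spike feature absent from table: ", spike_feature)
  m <- table$counts[, ntc, drop = FALSE]
  m <- m[rownames(m) != spike_feature, , drop = FALSE]
  present <- rownames(m)[rowSums(m > 0) > 0]
  means <- rowMeans(m[present, , drop = FALSE])
  run_means <- NULL
  if (!is.null(runs)) {
    ntc_runs <- runs[ntc]
    if (anyNA(ntc_runs)) stop("every spiked NTC needs a run label")
    run_means <- lapply(split(ntc, ntc_runs), function(cols)
      rowMeans(m[present, cols, drop = FALSE]))
  }
  structure(list(background_features = present,
                 mean_reads = means,
                 n_ntc_used = length(ntc),
                 run_means = run_means),
            class = "background_catalog")
}

#' Re-key a background catalog by exact sequence identity
#'
#' Sequence-level matching mode: when representative sequences are
#' available for both the catalogued background features and the table's
#' features, the catalog is re-keyed onto the table's feature IDs whose
#' representative sequence is identical (full length, exact string
#' equality — the bit-reproducible form of 100%-identity alignment).
#' Background features whose sequence matches nothing in the table are
#' dropped with a warning.
#'
#' @param catalog a `background_catalog`.
#' @param catalog_seqs named character vector: catalog feature ID ->
#'   representative sequence (e.g. from a FASTA read with
#'   `Biostrings::readDNAStringSet`).
#' @param table_seqs named character vector: table feature ID ->
#'   representative sequence.
#' @return the catalog with `background_features`/`mean_reads` keyed by
#'   the matched table feature IDs.
#' @export
match_background_sequences <- function(catalog, catalog_seqs, table_seqs) {
  stopifnot(inherits(catalog, "background_catalog"))
  seqs <- toupper(catalog_seqs[catalog$background_features])
  hit <- match(seqs, toupper(table_seqs))
  unmatched <- catalog$background_features[is.na(hit)]
  if (length(unmatched) > 0)
    warning("no identical representative sequence in table for: ",
            paste(unmatched, collapse = ", "))
  keep <- !is.na(hit)
  new_ids <- names(table_seqs)[hit[keep]]
  catalog$mean_reads <- stats::setNames(catalog$mean_reads[keep], new_ids)
  catalog$background_features <- new_ids
  if (!is.null(catalog$run_means))
    catalog$run_means <- lapply(catalog$run_means, function(v)
      stats::setNames(v[keep], new_ids))
  catalog
}

#' @export
print.background_catalog <- function(x, ...) {
  cat(sprintf("background_catalog: %d features from %d spiked NTCs\n",
              length(x$background_features), x$n_ntc_used))
  if (length(x$mean_reads) > 0)
    print(utils::head(sort(x$mean_reads, decreasing = TRUE), 10))
  invisible(x)
}

#' Subtract catalogued background reads from biological samples
#'
#' For every background feature, the NTC mean read count is removed from
#' each biological column, floored at zero. Features never seen in the
#' NTCs are untouched — this is the guard against over-compensation:
#' removal is bounded by what the controls actually contained, feature by
#' feature. NTC columns are consumed and dropped from the output.
#'
#' @param table a `count_table`.
#' @param catalog a `background_catalog` from [identify_background()].
#' @param rounding how the (real-valued) NTC mean is turned into a read
#'   count before subtraction: `"half_up"` (default) rounds .5 up,
#'   `"floor"` truncates, `"none"` subtracts the real mean and floors the
#'   result to the next lower integer.
#' @param runs optional named vector mapping sample IDs to sequencing-run
#'   labels; requires a catalog built with the same `runs`. Samples whose
#'   run has its own spiked NTCs get that run's means; others fall back
#'   to the pooled means.
#' @return a `count_table` of the cleaned biological (and replicate)
#'   columns.
#' @export
subtract_background <- function(table, catalog,
                                rounding = c("half_up", "floor", "none"),
                                runs = NULL) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(catalog, "background_catalog"))
  if (!is.null(runs) && is.null(catalog$run_means))
    stop("runs supplied but the catalog has no per-run means; rebuild it with identify_background(..., runs = )")
  keep <- sample_ids(table)[table$roles != "ntc_spiked"]
  if (length(keep) == 0) stop("no non-NTC columns to clean")
  m <- table$counts[, keep, drop = FALSE]

  feats <- catalog$background_features
  missing <- setdiff(feats, rownames(m))
  if (length(missing) > 0) {
    warning("catalog features absent from table, skipped: ",
            paste(missing, collapse = ", "))
    feats <- setdiff(feats, missing)
  }
  if (length(feats) > 0) {
    quantize <- function(v) switch(rounding,
                                   half_up = round_half_up(v),
                                   floor = floor(v),
                                   none = v)
    for (j in seq_along(keep)) {
      means <- catalog$mean_reads
      if (!is.null(runs)) {
        r <- runs[keep[j]]
        if (!is.na(r) && r %in% names(catalog$run_means))
          means <- catalog$run_means[[r]]
      }
      cleaned <- m[feats, j] - quantize(means[feats])
      if (rounding == "none") cleaned <- floor(cleaned)
      m[feats, j] <- pmax(cleaned, 0)
    }
  }
  count_table(m, roles = table$roles[keep],
              replicate_of = table$replicate_of[keep])
}
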