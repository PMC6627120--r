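#' Pearson correlation matrix over genera
#'
#' Product-moment correlation for every pair of rows of a genus x sample
#' value matrix (typically CLR coordinates). Genera with zero variance
#' across samples get `NA` correlations and a warning naming them.
#'
#' @param values genus x sample numeric matrix, >= 3 samples.
#' @return genus x genus correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 3) stop("need >= 3 samples")
  v <- apply(values, 1, stats::var)
  flat <- rownames(values)[v == 0]
  if (length(flat) > 0)
    warning("zero-variance genera, correlations undefined: ",
            paste(flat, collapse = ", "))
  r <- suppressWarnings(stats::cor(t(values)))
  diag(r) <- 1
  r
}

#' Genus-level co-occurrence network from thresholded Pearson correlations
#'
#' Pipeline: collapse the count table to genus level, keep genera with
#' mean relative abundance above `mra_threshold`, replace zeros and take
#' CLR coordinates, compute Pearson correlations across samples, and keep
#' every genus pair with |r| strictly above `r_cutoff` as a signed edge.
#' Node sizes are the genus MRAs. A `subset` of sample IDs builds the
#' network on those samples only (e.g. per community type), with the MRA
#' filter recomputed within the subset.
#'
#' @param table a `count_table` (biological samples are used).
#' @param tax a `taxonomy_map`.
#' @param mra_threshold mean-relative-abundance gate (default 0.005, i.e.
#'   genera above 0.5%).
#' @param r_cutoff absolute-correlation cutoff in [0, 1) (default 0.28).
#' @param subset optional character vector of sample IDs.
#' @param use_clr correlate CLR coordinates (default) or raw proportions.
#' @param alpha zero-replacement prior strength.
#' @return an object of class `cooccurrence_network`: list with `nodes`
#'   (data.frame genus, mra), `edges` (data.frame from, to, r), `r_cutoff`,
#'   `n_samples`.
#' @export
build_network <- function(table, tax, mra_threshold = 0.005, r_cutoff = 0.28,
                          subset = NULL, use_clr = TRUE, alpha = 0.5) {
  if (r_cutoff < 0 || r_cutoff >= 1) stop("r_cutoff must be in [0, 1)")
  bio <- biological_samples(table)
  if (!is.null(subset)) bio <- intersect(subset, bio)
  if (length(bio) < 3) stop("need >= 3 samples in subset")
  tb <- subset_samples(table, bio)
  gt <- collapse_to_rank(tb, tax, "genus")

  comp <- to_relative(gt)
  mra <- mean_relative_abundance(comp)
  keep <- names(mra)[mra > mra_threshold]
  if (length(keep) < 2) stop("fewer than 2 genera pass the abundance filter")
  gt <- count_table(gt$counts[keep, , drop = FALSE], roles = gt$roles,
                    replicate_of = gt$replicate_of)

  vals <- if (use_clr) {
    clr(zero_replace(gt, alpha = alpha))
  } else {
    to_relative(gt)$proportions
  }
  r <- pearson_correlation_matrix(vals)

  pairs <- which(upper.tri(r) & abs(r) > r_cutoff & !is.na(r), arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[pairs[, 1]],
                      to = colnames(r)[pairs[, 2]],
                      r = r[pairs],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(genus = keep, mra = unname(mra[keep]),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 r_cutoff = r_cutoff,
                 n_samples = length(bio)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|r| > %g, n = %d samples)\n",
              nrow(x$nodes), nrow(x$edges), x$r_cutoff, x$n_samples))
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}

#' Look up the signed correlation of a genus pair in a network
#'
#' @param net a `cooccurrence_network`.
#' @param a,b genus names.
#' @return the edge's r, or `NA` if the pair is not connected.
#' @export
edge_r <- function(net, a, b) {
  hit <- (net$edges$from == a & net$edges$to == b) |
         (net$edges$from == b & net$edges$to == a)
  if (!any(hit)) return(NA_real_)
  net$edges$r[which(hit)[1]]
}
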