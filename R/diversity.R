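#' Shannon-Weaver diversity of a count vector
#'
#' H = -sum_i p_i log(p_i) over features with positive count, with
#' p_i = x_i / sum(x). Natural log by default; `base = 2` gives bits.
#' Invariant under rescaling of the counts.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @param base logarithm base.
#' @return Shannon index (scalar).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero count vector")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 estimated species richness
#'
#' Bias-corrected by default: S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)),
#' where F1 and F2 are the numbers of singleton and doubleton features.
#' The classic estimator S_obs + F1^2 / (2 F2) is available behind
#' `bias_corrected = FALSE` (undefined when F2 = 0; falls back to the
#' bias-corrected form there, as is conventional).
#'
#' @param counts non-negative integer vector with positive sum.
#' @param bias_corrected logical.
#' @return estimated richness (scalar, >= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero count vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Observed richness
#' @param counts non-negative numeric vector.
#' @return number of features with positive count.
#' @export
observed_features <- function(counts) sum(counts > 0)

#' Per-sample alpha diversity table
#'
#' @param table a `count_table`.
#' @param base log base for Shannon.
#' @return data.frame: sample_id, role, depth, observed, shannon, chao1.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- table$counts
  data.frame(
    sample_id = colnames(m),
    role = unname(table$roles),
    depth = unname(colSums(m)),
    observed = apply(m, 2, observed_features),
    shannon = apply(m, 2, shannon, base = base),
    chao1 = apply(m, 2, chao1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# one multivariate-hypergeometric subsample of d reads without replacement
subsample_counts <- function(x, d) {
  stopifnot(d <= sum(x))
  pool <- rep.int(seq_along(x), x)
  tabulate(sample(pool, d), nbins = length(x))
}

#' Rarefaction curves of a diversity metric
#'
#' For each sample and each depth d not exceeding the sample's read count,
#' draws `n_iter` subsamples of d reads without replacement (multivariate
#' hypergeometric), computes the metric, and records mean and SD. Depths
#' larger than a sample's depth are skipped and flagged.
#'
#' @param table a `count_table`.
#' @param depths increasing positive integers.
#' @param metric `"shannon"`, `"chao1"` or `"observed"`.
#' @param n_iter subsamples per (sample, depth).
#' @param seed integer seed.
#' @param base log base when `metric = "shannon"`.
#' @return an object of class `rarefaction_curve`: data.frame with
#'   sample_id, depth, mean, sd, skipped; attributes `metric`, `n_iter`,
#'   `seed`.
#' @export
rarefaction_curve <- function(table, depths, metric = c("shannon", "chao1", "observed"),
                              n_iter = 10, seed = 1L, base = exp(1)) {
  metric <- match.arg(metric)
  if (length(depths) == 0) stop("empty depth list")
  if (any(depths <= 0)) stop("depths must be positive")
  if (n_iter < 1) stop("n_iter must be >= 1")
  fun <- switch(metric,
                shannon = function(v) shannon(v, base = base),
                chao1 = chao1,
                observed = observed_features)
  res <- with_seed(seed, {
    rows <- list()
    for (s in sample_ids(table)) {
      x <- table$counts[, s]
      nx <- sum(x)
      for (d in depths) {
        if (d > nx) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, depth = d, mean = NA_real_, sd = NA_real_,
            skipped = TRUE, stringsAsFactors = FALSE)
          next
        }
        vals <- vapply(seq_len(n_iter), function(i) fun(subsample_counts(x, d)),
                       numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, depth = d, mean = mean(vals),
          sd = if (n_iter > 1) stats::sd(vals) else 0,
          skipped = FALSE, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  structure(res, metric = metric, n_iter = n_iter, seed = seed,
            class = c("rarefaction_curve", "data.frame"))
}

#' Remove samples below a minimum read depth
#'
#' The filter is strict: a sample is removed when its read count is
#' strictly below `min_reads`, so a sample at exactly the threshold is
#' kept. Only biological (and replicate) columns are filtered; NTC columns
#' pass through untouched.
#'
#' @param table a `count_table`.
#' @param min_reads minimum depth (default 1000 reads, where milk
#'   rarefaction curves plateau).
#' @return list: `table` (filtered `count_table`), `removed` (character
#'   vector of dropped sample IDs).
#' @export
filter_min_depth <- function(table, min_reads = 1000) {
  if (min_reads < 0) stop("min_reads must be >= 0")
  depth <- colSums(table$counts)
  bio_like <- table$roles != "ntc_spiked"
  drop <- depth < min_reads & bio_like
  if (any(bio_like) && all(drop[bio_like]))
    stop("depth filter removed every biological sample")
  keep <- sample_ids(table)[!drop]
  list(table = subset_samples(table, keep),
       removed = sample_ids(table)[drop])
}
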