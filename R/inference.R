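#' Single-factor PERMANOVA on a distance matrix
#'
#' Partitions squared inter-sample dissimilarities into between- and
#' within-group components:
#' SS_T = (1/N) sum_{j<k} d_jk^2,
#' SS_W = sum_g (1/n_g) sum_{j<k in g} d_jk^2,
#' SS_A = SS_T - SS_W,
#' pseudo-F = (SS_A / (a-1)) / (SS_W / (N-a)).
#' The p-value is permutational: group labels are shuffled `B` times and
#' p = (1 + #{F_perm >= F_obs}) / (B + 1), so the identity permutation is
#' always counted and p can never be 0.
#'
#' @param d a `dist` (or symmetric matrix) over samples.
#' @param groups factor/character of group labels, aligned with the
#'   samples of `d` (names are matched to distance labels when present).
#' @param B number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `permanova_result`: list with `ss_between`,
#'   `ss_within`, `ss_total`, `df_between`, `df_within`, `f`, `p`,
#'   `n_permutations`, `seed`, `n`, `groups` (group sizes).
#' @export
permanova <- function(d, groups, B = 999, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(groups)) && !is.null(labs)) groups <- groups[labs]
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must label every sample in d")
  if (anyNA(groups)) stop("NA group labels")
  a <- length(unique(groups))
  if (a < 2) stop("need >= 2 groups")
  if (a >= n) stop("need >= 2 samples in some group")
  if (B < 1) stop("B must be >= 1")

  d2 <- as.matrix(d)^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_for <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ssa <- ss_total - ssw
    if (ssw <= 0) return(Inf)
    (ssa / (a - 1)) / (ssw / (n - a))
  }

  f_obs <- f_for(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(B), function(b) f_for(sample(groups)) >= f_obs,
               logical(1)))
  })
  p <- (1 + exceed) / (B + 1)

  ss_within <- ss_within_for(groups)
  structure(list(ss_between = ss_total - ss_within,
                 ss_within = ss_within, ss_total = ss_total,
                 df_between = a - 1, df_within = n - a,
                 f = f_obs, p = p, n_permutations = B, seed = seed,
                 n = n, groups = table(groups)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$f, x$p, x$n_permutations))
  cat(sprintf("  SS between %.4g | within %.4g | total %.4g | R2 = %.3f\n",
              x$ss_between, x$ss_within, x$ss_total, x$ss_between / x$ss_total))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} p_(j) m / j, capped at 1,
#' mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-way ANOVA of alpha diversity between groups
#'
#' Classical F = MS_between / MS_within; with a single factor this
#' coincides with a Type II test.
#'
#' @param values numeric vector (e.g. a column of [alpha_diversity()]).
#' @param groups group labels aligned with `values`.
#' @return list: `f`, `p`, `df_between`, `df_within`.
#' @export
alpha_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}

#' Replicate reproducibility R-squared
#'
#' Regresses the replicate library's per-OTU read counts on the original
#' sample's and returns the coefficient of determination — the
#' reproducibility summary for duplicate library preparations of one DNA
#' extract.
#'
#' @param table a `count_table` containing both columns.
#' @param sample original sample ID.
#' @param replicate replicate sample ID; defaults to the column flagged
#'   `replicate-of: sample`.
#' @return R-squared (scalar).
#' @export
replicate_r2 <- function(table, sample, replicate = NULL) {
  if (is.null(replicate)) {
    hit <- which(table$replicate_of == sample)
    if (length(hit) == 0) stop("no replicate column flagged for sample ", sample)
    replicate <- sample_ids(table)[hit[1]]
  }
  ids <- sample_ids(table)
  if (!sample %in% ids || !replicate %in% ids) stop("sample column missing")
  x <- table$counts[, sample]
  y <- table$counts[, replicate]
  if (length(x) < 2) stop("need >= 2 features")
  if (stats::var(x) == 0) stop("zero-variance predictor sample")
  summary(stats::lm(y ~ x))$r.squared
}

#' PERMANOVA scan of covariates across taxonomy ranks
#'
#' Runs a single-factor PERMANOVA of each covariate at each taxonomic
#' rank (collapsing the table, transforming, computing the chosen
#' distance) and applies Benjamini-Hochberg correction across the whole
#' scan. Samples with a missing covariate value are dropped for that
#' covariate.
#'
#' @param table a `count_table` (biological samples are used).
#' @param tax a `taxonomy_map`.
#' @param metadata data.frame with `sample_id` and covariate columns.
#' @param covariates character vector of metadata column names.
#' @param ranks taxonomy ranks to scan (default phylum, order, family,
#'   genus).
#' @param distance `"bray"` (Bray-Curtis on proportions) or `"aitchison"`
#'   (Euclidean on CLR after zero replacement).
#' @param B permutations per test.
#' @param seed integer seed.
#' @param alpha zero-replacement prior strength (aitchison only).
#' @return an `fdr_report`: data.frame with covariate, rank, f, p, q and
#'   `significant` at q < 0.05.
#' @export
permanova_scan <- function(table, tax, metadata, covariates,
                           ranks = c("phylum", "order", "family", "genus"),
                           distance = c("bray", "aitchison"),
                           B = 999, seed = 1L, alpha = 0.5) {
  distance <- match.arg(distance)
  bio <- biological_samples(table)
  tb <- subset_samples(table, bio)
  rows <- list()
  for (rk in ranks) {
    ct <- collapse_to_rank(tb, tax, rk)
    d <- if (distance == "bray") {
      bray_curtis(to_relative(ct))
    } else {
      aitchison_dist(zero_replace(ct, alpha = alpha))
    }
    dm <- as.matrix(d)
    for (cv in covariates) {
      vals <- stats::setNames(metadata[[cv]], metadata$sample_id)[bio]
      keep <- !is.na(vals)
      if (length(unique(vals[keep])) < 2 || sum(keep) < 4) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, rank = rk, f = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      sub <- stats::as.dist(dm[keep, keep])
      res <- permanova(sub, vals[keep], B = B, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, rank = rk, f = res$f, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < 0.05
  structure(out, class = c("fdr_report", "data.frame"))
}
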