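#' Bayesian-multiplicative zero replacement
#'
#' Count zeros are replaced by small pseudo-proportions derived from a
#' Dirichlet prior with strength `alpha` per feature, and the nonzero
#' parts of each sample are shrunk multiplicatively so the column still
#' sums to 1. For sample j with total n_j, a zero cell of feature i
#' becomes delta_ij = alpha_i / (n_j + sum(alpha)), and every nonzero
#' cell becomes (x_ij / n_j) * (1 - sum of that column's deltas).
#' Multiplicative adjustment preserves the ratios between nonzero parts
#' exactly, the property log-ratio methods require.
#'
#' @param table a `count_table` (columns must have positive totals).
#' @param alpha prior strength, scalar or per-feature vector; default 0.5
#'   (Jeffreys-like).
#' @return an object of class `zero_replaced_composition`: list with
#'   `proportions` (strictly positive, unit-sum columns), `alpha`,
#'   `replaced` (logical mask of adjusted cells), `roles`.
#' @export
zero_replace <- function(table, alpha = 0.5) {
  m <- table$counts
  if (any(alpha <= 0)) stop("alpha must be > 0")
  alpha <- rep(alpha, length.out = nrow(m))
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ", paste(colnames(m)[tot == 0], collapse = ", "))
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    zero <- x == 0
    delta <- alpha / (tot[j] + sum(alpha))
    out[zero, j] <- delta[zero]
    out[!zero, j] <- (x[!zero] / tot[j]) * (1 - sum(delta[zero]))
  }
  structure(list(proportions = out, alpha = alpha, replaced = m == 0,
                 roles = table$roles),
            class = c("zero_replaced_composition", "composition_table"))
}

#' Centered log-ratio transform
#'
#' clr(x)_i = ln(x_i) - mean_i ln(x_i), applied per sample (column).
#' Coordinates sum to zero within each sample and are invariant to
#' rescaling of the composition.
#'
#' @param comp a strictly positive `composition_table` (use
#'   [zero_replace()] first if the data contain zeros) or a bare matrix.
#' @return feature x sample matrix of CLR coordinates.
#' @export
clr <- function(comp) {
  p <- if (inherits(comp, "composition_table")) comp$proportions else as.matrix(comp)
  if (any(p <= 0))
    stop("composition contains zeros; apply zero_replace() before clr()")
  lg <- log(p)
  sweep(lg, 2, colMeans(lg))
}

#' Aitchison distance between two compositions
#'
#' The Euclidean norm of the difference of the CLR vectors — a true metric
#' on the interior of the simplex, invariant under perturbation.
#'
#' @param comp_a,comp_b strictly positive proportion vectors over the same
#'   features.
#' @return distance (scalar).
#' @export
aitchison_distance <- function(comp_a, comp_b) {
  if (length(comp_a) != length(comp_b)) stop("mismatched feature sets")
  if (!is.null(names(comp_a)) && !is.null(names(comp_b)) &&
      !identical(names(comp_a), names(comp_b)))
    stop("mismatched feature sets")
  if (any(comp_a <= 0) || any(comp_b <= 0)) stop("compositions must be strictly positive")
  ca <- log(comp_a) - mean(log(comp_a))
  cb <- log(comp_b) - mean(log(comp_b))
  sqrt(sum((ca - cb)^2))
}

#' Aitchison distance matrix over samples
#'
#' @param comp a strictly positive `composition_table` (e.g. from
#'   [zero_replace()]).
#' @return a `dist` with attribute `metric = "aitchison"`.
#' @export
aitchison_dist <- function(comp) {
  z <- clr(comp)
  d <- stats::dist(t(z))
  attr(d, "metric") <- "aitchison"
  d
}

#' Lambda-scaled log-ratio biplot
#'
#' SVD of the double-centered CLR matrix (CLR centers each sample; the
#' biplot additionally centers each feature across samples). With the
#' column-principal form (gamma = 0), row (sample) markers are U scaled by
#' lambda and column (taxon) markers are V S divided by lambda, so inner
#' products reconstruct the centered CLR matrix regardless of lambda.
#' Under the `spread_balance` rule lambda is set to
#' (sum ||col||^2 / sum ||row||^2)^(1/4), which equalizes the total spread
#' of sample and taxon markers.
#'
#' @param comp a strictly positive `composition_table`, e.g. from
#'   [zero_replace()].
#' @param n_axes number of biplot axes (default 2).
#' @param lambda_rule `"spread_balance"` or a fixed positive number.
#' @param gamma row/column principal exponent in [0, 1]; 0 (default) is
#'   column-principal.
#' @return an object of class `biplot_model`: list with `rows` (sample
#'   markers), `cols` (taxon markers), `singular_values`, `lambda`,
#'   `variance_explained`.
#' @export
logratio_biplot <- function(comp, n_axes = 2, lambda_rule = "spread_balance",
                            gamma = 0) {
  z <- clr(comp)                      # features x samples
  x <- t(z)                           # samples x features
  x <- sweep(x, 2, colMeans(x))       # center each taxon across samples
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 samples and >= 2 features")
  sv <- svd(x)
  r <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_axes > r) stop(sprintf("n_axes = %d exceeds rank %d", n_axes, r))
  idx <- seq_len(n_axes)
  rows <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx]^gamma, n_axes)
  cols <- sv$v[, idx, drop = FALSE] %*% diag(sv$d[idx]^(1 - gamma), n_axes)
  lambda <- if (identical(lambda_rule, "spread_balance")) {
    (sum(cols^2) / sum(rows^2))^(1 / 4)
  } else {
    stopifnot(is.numeric(lambda_rule), lambda_rule > 0)
    as.numeric(lambda_rule)
  }
  rows <- rows * lambda
  cols <- cols / lambda
  dimnames(rows) <- list(rownames(x), paste0("axis", idx))
  dimnames(cols) <- list(colnames(x), paste0("axis", idx))
  structure(list(rows = rows, cols = cols,
                 singular_values = sv$d[seq_len(r)],
                 lambda = lambda,
                 variance_explained = sv$d[idx]^2 / sum(sv$d^2)),
            class = "biplot_model")
}
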