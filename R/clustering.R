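#' Bray-Curtis dissimilarity between samples
#'
#' d_jk = sum_i |p_ij - p_ik| / sum_i (p_ij + p_ik); on compositions this
#' lies in [0, 1]. It is a dissimilarity, not a metric — the triangle
#' inequality is not guaranteed and nothing downstream relies on it.
#'
#' @param comp a `composition_table` (or bare feature x sample matrix).
#' @return a `dist` over samples with attribute `metric = "bray"`.
#' @export
bray_curtis <- function(comp) {
  p <- if (inherits(comp, "composition_table")) comp$proportions else as.matrix(comp)
  d <- vegan::vegdist(t(p), method = "bray")
  attr(d, "metric") <- "bray"
  d
}

#' Complete-linkage hierarchical community typing
#'
#' Agglomerates samples under complete linkage (cluster distance = maximum
#' pairwise dissimilarity, so merge heights are monotone non-decreasing)
#' and assigns community-type labels by cutting all merges above
#' `cut_height`. Clusters smaller than `min_size` are set aside (label
#' `NA`): with a fixed cut the tree typically yields a few large community
#' types plus singleton-ish clusters that are excluded from downstream
#' group comparisons.
#'
#' @param d a `dist` (e.g. from [bray_curtis()]).
#' @param cut_height height at which the tree is cut (default 0.8).
#' @param min_size minimum cluster size retained (default 5); smaller
#'   clusters get label `NA`.
#' @return an object of class `cluster_model`: list with `hclust` (the
#'   tree), `cut_height`, `labels` (named integer, `NA` for set-aside
#'   samples), `all_labels` (before the size rule), `small_clusters`.
#' @export
hierarchical_cluster <- function(d, cut_height = 0.8, min_size = 5) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m)))) stop("distance matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  if (attr(d, "Size") < 2) stop("need >= 2 samples")
  hc <- stats::hclust(d, method = "complete")
  all_labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(all_labels)
  small <- as.integer(names(sizes)[sizes < min_size])
  labels <- all_labels
  labels[labels %in% small] <- NA_integer_
  # relabel retained clusters 1..K by decreasing size
  kept <- sort(table(labels), decreasing = TRUE)
  remap <- stats::setNames(seq_along(kept), names(kept))
  labels <- unname(remap[as.character(labels)])
  names(labels) <- names(all_labels)
  structure(list(hclust = hc, cut_height = cut_height,
                 labels = labels, all_labels = all_labels,
                 small_clusters = small),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$labels)))
  cat(sprintf("cluster_model: cut height %g -> %d retained cluster(s), %d sample(s) set aside\n",
              x$cut_height, k, sum(is.na(x$labels))))
  invisible(x)
}

# Calinski-Harabasz index on coordinates: [B/(k-1)] / [W/(n-k)]
calinski_harabasz <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- length(unique(labels))
  if (k < 2 || k > n - 1) return(NA_real_)
  grand <- colMeans(coords)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    cg <- coords[labels == g, , drop = FALSE]
    cen <- colMeans(cg)
    w <- w + sum(sweep(cg, 2, cen)^2)
    b <- b + nrow(cg) * sum((cen - grand)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Choose the number of community types
#'
#' For each k in `k_range`, labels come from cutting the complete-linkage
#' tree into k groups; the Calinski-Harabasz index CH(k) is computed on
#' the positive-eigenvalue PCoA coordinates of the dissimilarity (faithful
#' to the distance structure without inventing a feature space), and the
#' mean silhouette width is computed directly on the dissimilarity.
#' `selected_k` maximizes CH; ties break toward smaller k (parsimony).
#' The silhouette profile is reported alongside as validation.
#'
#' @param d a `dist`.
#' @param model a `cluster_model` from [hierarchical_cluster()] on the
#'   same samples (its tree supplies the per-k labels).
#' @param k_range integer vector within [2, n-1].
#' @return an object of class `k_selection`: list with `scores`
#'   (data.frame k, ch, silhouette), `selected_k`, `labels_at_selected`,
#'   `degenerate` flag (all points identical).
#' @export
select_k <- function(d, model, k_range = 2:10) {
  n <- attr(d, "Size")
  if (any(k_range < 2 | k_range > n - 1)) stop("k_range must lie in [2, n-1]")
  coords <- pcoa(d, n_axes = n - 1)
  degenerate <- ncol(coords$coordinates) == 0 || max(d) == 0
  dm <- as.matrix(d)
  scores <- data.frame(k = integer(0), ch = numeric(0), silhouette = numeric(0))
  for (k in k_range) {
    lab <- stats::cutree(model$hclust, k = k)
    ch <- if (degenerate) 0 else calinski_harabasz(coords$coordinates, lab)
    sil <- mean(cluster::silhouette(lab, dmatrix = dm)[, "sil_width"])
    scores <- rbind(scores, data.frame(k = k, ch = ch, silhouette = sil))
  }
  sel <- if (all(!is.finite(scores$ch))) NA_integer_ else
    scores$k[which.max(scores$ch)]  # which.max takes the first (smallest k) tie
  labels_at_selected <- if (!is.na(sel)) stats::cutree(model$hclust, k = sel) else NULL
  structure(list(scores = scores, selected_k = sel,
                 labels_at_selected = labels_at_selected,
                 degenerate = degenerate),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: selected k = %s%s\n", x$selected_k,
              if (x$degenerate) " (degenerate input)" else ""))
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Principal coordinate analysis
#'
#' Classical scaling: Gower double-centering of -d^2/2, eigendecomposition,
#' coordinates = eigenvectors scaled by the square root of their (positive)
#' eigenvalues, axes ordered by eigenvalue. Axes with negative eigenvalues
#' (possible for non-Euclidean dissimilarities like Bray-Curtis) are
#' dropped and their eigenvalues reported.
#'
#' @param d a `dist`.
#' @param n_axes maximum number of axes returned.
#' @return list: `coordinates` (samples x axes), `eigenvalues` (all,
#'   including negatives), `negative_eigenvalues`, `variance_explained`
#'   (per returned axis, relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2) {
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- attr(d, "Size")
  # negative eigenvalues are expected for non-Euclidean input; cmdscale
  # warns about them and returns only the positive-eigenvalue axes
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_keep <- min(n_axes, ncol(fit$points))
  coords <- fit$points[, seq_len(n_keep), drop = FALSE]
  if (n_keep > 0) colnames(coords) <- paste0("PCo", seq_len(n_keep))
  pos_total <- sum(eig[eig > 0])
  neg_tol <- sqrt(.Machine$double.eps) * max(abs(eig), 1)
  list(coordinates = coords,
       eigenvalues = eig,
       negative_eigenvalues = eig[eig < -neg_tol],
       variance_explained = if (n_keep > 0) eig[seq_len(n_keep)] / pos_total else numeric(0))
}
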