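test_that("bray-curtis matches its defining formula", {
  comp <- structure(list(proportions = cbind(S1 = c(0.6, 0.4), S2 = c(0.4, 0.6),
                                             S3 = c(1, 0), S4 = c(0, 1),
                                             S5 = c(0.6, 0.4))),
                    class = "composition_table")
  d <- as.matrix(bray_curtis(comp))
  expect_equal(d["S1", "S5"], 0)          # identical columns
  expect_equal(d["S3", "S4"], 1)          # disjoint support
  expect_equal(d["S1", "S2"], 0.2)        # 0.4 / 2

  set.seed(1)
  for (i in 1:20) {
    a <- random_composition(6); b <- random_composition(6)
    m <- as.matrix(bray_curtis(cbind(a, b)))
    expect_equal(m[1, 2], o_bray(a, b), tolerance = 1e-12)
    expect_gte(m[1, 2], 0); expect_lte(m[1, 2], 1)
  }
})

test_that("two-point clustering splits exactly at the cut height", {
  dm <- matrix(c(0, 0.9, 0.9, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m1 <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.8, min_size = 1)
  expect_equal(length(unique(m1$all_labels)), 2)
  m2 <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.95, min_size = 1)
  expect_equal(length(unique(m2$all_labels)), 1)
})

test_that("complete linkage merges at the maximum pairwise distance", {
  dm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm["A", "B"] <- dm["B", "A"] <- 0.1
  dm["A", "C"] <- dm["C", "A"] <- 0.9
  dm["B", "C"] <- dm["C", "B"] <- 0.9
  model <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.5, min_size = 1)
  expect_equal(model$hclust$height, c(0.1, 0.9))
  expect_equal(unname(model$all_labels["A"]), unname(model$all_labels["B"]))
  expect_false(unname(model$all_labels["A"]) == unname(model$all_labels["C"]))
})

test_that("hclust agrees with a brute-force complete-linkage oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- 8
    dm <- matrix(0, n, n)
    dm[upper.tri(dm)] <- runif(n * (n - 1) / 2)
    dm <- dm + t(dm)
    dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
    oracle <- o_complete_linkage(dm)
    model <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.5, min_size = 1)
    expect_equal(sort(model$hclust$height), sort(oracle$heights), tolerance = 1e-12)
    for (h in c(0.2, 0.5, 0.8)) {
      got <- canonical_partition(stats::cutree(model$hclust, h = h))
      want <- canonical_partition(oracle$partition_at(h))
      expect_equal(got, unname(want))
    }
  }
})

test_that("cut extremes give n singletons and one cluster", {
  set.seed(3)
  dm <- as.matrix(dist(matrix(rnorm(12), 6)))
  model <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.5, min_size = 1)
  expect_equal(length(unique(stats::cutree(model$hclust, h = 0))), 6)
  expect_equal(length(unique(stats::cutree(model$hclust,
                                           h = max(model$hclust$height)))), 1)
})

test_that("small clusters are set aside as NA labels", {
  # 6 tight points + 1 outlier; min_size 2 discards the singleton cluster
  coords <- c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 10)
  dm <- as.matrix(dist(coords))
  dimnames(dm) <- list(paste0("s", 1:7), paste0("s", 1:7))
  model <- hierarchical_cluster(stats::as.dist(dm), cut_height = 1, min_size = 2)
  expect_true(is.na(model$labels["s7"]))
  expect_equal(unname(model$labels[1:6]), rep(1L, 6))
})

test_that("select_k prefers two well-separated blobs with silhouette near 1", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(20, 0, 0.01), 10),
               matrix(rnorm(20, 5, 0.01), 10))
  d <- dist(pts)
  model <- hierarchical_cluster(d, cut_height = 1, min_size = 1)
  sel <- select_k(d, model, 2:5)
  expect_equal(sel$selected_k, 2)
  expect_gt(sel$scores$silhouette[sel$scores$k == 2], 0.95)
})

test_that("identical points are flagged degenerate", {
  dm <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  model <- hierarchical_cluster(stats::as.dist(dm), cut_height = 0.5, min_size = 1)
  sel <- select_k(stats::as.dist(dm), model, 2:3)
  expect_true(sel$degenerate)
  expect_true(all(sel$scores$ch == 0))
})

test_that("pcoa embeds euclidean distances exactly", {
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  fit <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(fit$coordinates)), as.matrix(d), tolerance = 1e-9)
  # axes orthogonal
  cross <- crossprod(fit$coordinates)
  expect_lt(abs(cross[1, 2]), 1e-8)
  expect_length(fit$negative_eigenvalues, 0)
})

test_that("pcoa reports negative eigenvalues for non-euclidean input", {
  set.seed(6)
  comp <- matrix(rgamma(60, 1), 6, 10)
  comp <- sweep(comp, 2, colSums(comp), "/")
  d <- bray_curtis(comp)
  fit <- pcoa(d, n_axes = 3)
  expect_true(length(fit$negative_eigenvalues) > 0)
  expect_true(all(diff(fit$variance_explained) <= 1e-12))
})

test_that("community typing recovers the three milk profiles", {
  sp <- cohort_spec(n_samples = c(20, 20, 20))
  co <- generate_cohort(sp, seed = 11)
  clean <- subtract_background(co$table,
                               identify_background(co$table, sp$spike_feature))
  g <- collapse_to_rank(clean, co$taxonomy, "genus")
  d <- bray_curtis(abundance_filter(to_relative(g), 0.005, "dataset_mra"))
  model <- hierarchical_cluster(d, cut_height = 0.8, min_size = 5)
  sel <- select_k(d, model, 2:8)
  expect_equal(sel$selected_k, 3)
  ari <- mclust::adjustedRandIndex(sel$labels_at_selected,
                                   co$truth$true_cluster[biological_samples(clean)])
  expect_gt(ari, 0.9)
})
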