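test_that("permanova separates perfectly split groups", {
  # two groups of 2: zero within-group, positive between-group distance
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 0
  dm[3, 4] <- dm[4, 3] <- 0
  dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(stats::as.dist(dm), c("a", "a", "b", "b"), B = 99, seed = 1)
  expect_equal(res$ss_within, 0)
  expect_true(is.infinite(res$f))
  # only 3 distinct splits into 2+2 exist; identity is counted
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
})

test_that("permanova SS decomposition matches the hand formula and adds up", {
  set.seed(2)
  for (i in 1:10) {
    pts <- matrix(rnorm(24), 12, 2)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(paste0("s", 1:12), paste0("s", 1:12))
    g <- rep(c("x", "y", "z"), each = 4)
    res <- permanova(stats::as.dist(dm), g, B = 9, seed = 3)
    want <- o_permanova_ss(dm, g)
    expect_equal(res$ss_total, want$ss_t, tolerance = 1e-9)
    expect_equal(res$ss_within, want$ss_w, tolerance = 1e-9)
    expect_equal(res$ss_between + res$ss_within, res$ss_total, tolerance = 1e-9)
  }
})

test_that("on euclidean distances the SS decomposition equals coordinate ANOVA", {
  set.seed(3)
  pts <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  dm <- as.matrix(dist(pts))
  res <- permanova(stats::as.dist(dm), g, B = 9, seed = 1)
  # centered-coordinate sums of squares, per axis, summed
  ss_t <- sum(sweep(pts, 2, colMeans(pts))^2)
  ss_w <- 0
  for (lev in unique(g)) {
    sub <- pts[g == lev, , drop = FALSE]
    ss_w <- ss_w + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  expect_equal(res$ss_total, ss_t, tolerance = 1e-9)
  expect_equal(res$ss_within, ss_w, tolerance = 1e-9)
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
  set.seed(4)
  m <- matrix(rgamma(80, 1), 8, 10)
  comp <- sweep(m, 2, colSums(m), "/")
  colnames(comp) <- paste0("S", 1:10)
  d <- bray_curtis(comp)
  g <- rep(c("a", "b"), 5)
  res <- permanova(d, g, B = 999, seed = 5)
  ad <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(res$f, ad$F[1], tolerance = 1e-9)
  expect_equal(res$ss_between / res$ss_total, ad$R2[1], tolerance = 1e-9)
  expect_equal(res$ss_total, ad$SumOfSqs[nrow(ad)], tolerance = 1e-9)  # Total row
})

test_that("permanova p-values are seed-deterministic, bounded, label-invariant", {
  set.seed(6)
  dm <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(dm) <- list(paste0("s", 1:10), paste0("s", 1:10))
  g <- rep(c("a", "b"), each = 5)
  r1 <- permanova(stats::as.dist(dm), g, B = 99, seed = 7)
  r2 <- permanova(stats::as.dist(dm), g, B = 99, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 100)
  expect_lte(r1$p, 1)
  # renaming the groups changes nothing
  g2 <- unname(c(a = "group2", b = "group1")[g])
  r3 <- permanova(stats::as.dist(dm), g2, B = 99, seed = 7)
  expect_equal(r1$f, r3$f)
  expect_equal(r1$p, r3$p)
})

test_that("degenerate groupings are refused", {
  dm <- as.matrix(dist(1:4)); dimnames(dm) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(permanova(stats::as.dist(dm), rep("a", 4), B = 9), ">= 2 groups")
  expect_error(permanova(stats::as.dist(dm), c("a", "b", "c", "d"), B = 9),
               ">= 2 samples")
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:30) {
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, o_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # order-preserving
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("alpha-diversity ANOVA matches the sum-of-squares oracle", {
  vals <- c(1.2, 1.4, 1.1, 2.8, 3.0, 2.9, 2.0, 2.2, 1.9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- alpha_anova(vals, g)
  want <- o_anova(vals, g)
  expect_equal(res$f, want$f, tolerance = 1e-9)
  expect_equal(res$p, want$p, tolerance = 1e-9)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # strongly separated means are detected
  expect_lt(alpha_anova(c(rnorm(10), rnorm(10) + 50), rep(c("x", "y"), each = 10))$p,
            0.001)
  expect_error(alpha_anova(1:4, c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("replicate R2 hits 1 for identical or proportional duplicates", {
  counts <- cbind(S1 = c(100, 50, 25, 5), S1_dup = c(100, 50, 25, 5),
                  S1_double = 2 * c(100, 50, 25, 5))
  tb <- make_table(counts, roles = c("biological", "replicate", "replicate"),
                   replicate_of = c(NA, "S1", "S1"))
  # lm warns about the (intentionally) perfect fit
  expect_equal(suppressWarnings(replicate_r2(tb, "S1", "S1_dup")), 1)
  expect_equal(suppressWarnings(replicate_r2(tb, "S1", "S1_double")), 1)
  # default replicate lookup uses the role flag
  expect_equal(suppressWarnings(replicate_r2(tb, "S1")), 1)
})

test_that("deep multinomial duplicates reproduce with R2 above 0.97", {
  profile <- c(4900, 1800, 600, 300, 300, 200, 200, 100, 100, 500) * 10
  tb <- make_table(cbind(S1 = profile))
  pair <- generate_replicate_pair(tb, "S1", depth = 1e5, seed = 8)
  expect_gt(replicate_r2(pair, "S1"), 0.97)
})

test_that("the covariate scan is stable under metadata row order", {
  sp <- cohort_spec(n_samples = c(8, 8, 8), n_ntc = 2)
  co <- generate_cohort(sp, seed = 9)
  md <- co$metadata
  scan1 <- permanova_scan(co$table, co$taxonomy, md,
                          covariates = c("cluster", "site"),
                          ranks = c("phylum", "genus"), B = 99, seed = 10)
  scan2 <- permanova_scan(co$table, co$taxonomy, md[rev(seq_len(nrow(md))), ],
                          covariates = c("cluster", "site"),
                          ranks = c("phylum", "genus"), B = 99, seed = 10)
  expect_equal(scan1$p, scan2$p)
  expect_equal(scan1$q, bh_adjust(scan1$p))
  expect_identical(scan1$significant, scan1$q < 0.05 & !is.na(scan1$q))
  # the true cluster structure shows up at genus level
  expect_lt(scan1$p[scan1$covariate == "cluster" & scan1$rank == "genus"], 0.05)
})
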