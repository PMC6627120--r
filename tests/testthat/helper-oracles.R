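# Brute-force reference implementations of the defining formulas, kept
# deliberately naive and independent of the package's code paths.

o_shannon <- function(x, base = exp(1)) {
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

o_chao1 <- function(x, bias_corrected = TRUE) {
  s <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected || f2 == 0) s + f1 * (f1 - 1) / (2 * (f2 + 1))
  else s + f1^2 / (2 * f2)
}

o_bray <- function(a, b) sum(abs(a - b)) / sum(a + b)

o_clr <- function(x) log(x) - mean(log(x))

# pairwise log-ratio form of the Aitchison distance
o_aitchison <- function(x, y) {
  D <- length(x)
  s <- 0
  for (i in seq_len(D)) for (j in seq_len(D)) {
    s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
  }
  sqrt(s / (2 * D))
}

o_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

# BH step-up by hand: q_(i) = min_{j>=i} p_(j) m / j, back in input order
o_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# one-way ANOVA from sums of squares
o_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_b <- 0
  ss_w <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - grand)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df_b <- length(unique(groups)) - 1
  df_w <- length(values) - length(unique(groups))
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# brute-force complete-linkage agglomeration: returns merge heights and a
# function giving the partition after merging everything at height <= h
o_complete_linkage <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  states <- list(clusters)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, best_h)
    states[[length(states) + 1]] <- clusters
  }
  partition_at <- function(h) {
    k <- sum(heights <= h)          # merges performed at or below h
    state <- states[[k + 1]]
    lab <- integer(n)
    for (i in seq_along(state)) lab[state[[i]]] <- i
    lab
  }
  list(heights = heights, partition_at = partition_at)
}

# canonical form of a partition for label-free comparison
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# permanova SS decomposition by hand from the squared distance matrix
o_permanova_ss <- function(dm, groups) {
  n <- nrow(dm)
  d2 <- dm^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  list(ss_t = ss_t, ss_w = ss_w, ss_a = ss_t - ss_w)
}
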