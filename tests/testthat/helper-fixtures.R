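# Shared fixtures: every table is generated in code at test time.

# benchmark-scale metacommunity SAD: sdlog = 1 at S = 200 matches the
# dominance profile (top-1 ~5%, top-10 ~26%) of the full-scale pool
# (S = 2000, sdlog = 2)
bench_sad <- list(meanlog = 0, sdlog = 1)

bench_meta <- function(seed, S = 200)
  make_metacommunity(S, sad_params = bench_sad, seed = seed)

bench_design <- function(seed, regime = "neutral", m = 0.1, ...)
  simulation_design(N_T = 1000, depth = 1000, m = m, regime = regime,
                    seed = seed, ...)

# small multinomial table with a lognormal pool, no group structure
random_table <- function(n = 12, S = 30, depth = 150, seed = 1,
                         sdlog = 1) {
  set.seed(seed)
  p <- sort(stats::rlnorm(S, 0, sdlog), decreasing = TRUE)
  p <- p / sum(p)
  m <- t(vapply(seq_len(n), function(i) stats::rmultinom(1, depth, p)[, 1],
                integer(S)))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(S)))
  community_table(m, quiet = TRUE)
}

toy_2x2 <- function() {
  community_table(matrix(c(5L, 0L, 1L, 3L), 2, 2, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("t1", "t2"))),
                  quiet = TRUE)
}

# independent naive IndVal implementation used as an oracle
oracle_indval <- function(m, groups) {
  groups <- factor(groups)
  S <- ncol(m)
  out <- matrix(0, nlevels(groups), S)
  for (j in seq_len(S)) {
    means <- sapply(levels(groups), function(g) mean(m[groups == g, j]))
    for (k in seq_len(nlevels(groups))) {
      g <- levels(groups)[k]
      A <- if (sum(means) == 0) 0 else means[k] / sum(means)
      B <- mean(m[groups == g, j] > 0)
      out[k, j] <- A * B
    }
  }
  out
}

# independent one-factor pseudo-F from a distance matrix (Anderson's
# direct formula: total and within-group sums of squared distances)
oracle_pseudo_f <- function(d, groups) {
  dmat <- as.matrix(d)
  n <- nrow(dmat)
  sst <- sum(dmat[lower.tri(dmat)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ssa <- sst - ssw
  a <- length(unique(groups))
  (ssa / (a - 1)) / (ssw / (n - a))
}
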