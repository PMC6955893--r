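# shared internal helpers

# Permutation p-value with additive smoothing; never 0.  Ties between the
# null statistic and the observed one count as "at least as extreme", with a
# small tolerance so floating-point jitter cannot flip a tie.
perm_pvalue <- function(null, obs, tol = 1e-12) {
  (1 + sum(null >= obs - tol)) / (1 + length(null))
}

# Deterministic substream seed derived from a master seed and an index.
# Keeps every derived seed a valid positive 32-bit integer, so sample i
# gets the same stream regardless of how many samples precede it.
derive_seed <- function(master, i) {
  x <- (as.numeric(master) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + as.numeric(i) * 16807) %% 2147483647
  as.integer(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# Weighted sampling without replacement (exponential-keys method):
# returns `size` distinct indices with inclusion driven by `prob`.
sample_weighted_norep <- function(n, size, prob) {
  if (size == 0L) return(integer(0))
  keys <- stats::rexp(n) / prob
  keys[prob <= 0] <- Inf
  order(keys)[seq_len(size)]
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(p_hat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All n! permutations of 1..n, one per row.
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutation only supported for n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
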