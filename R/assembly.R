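#' One abundance-based null assembly of a community table
#'
#' Builds a randomised table in which every sample keeps its observed
#' richness and total abundance, but taxon identities are reassigned from
#' the regional pool: the occurring taxa of each null sample are chosen
#' without replacement with probability proportional to their regional
#' occurrence frequency (each receiving one guaranteed individual), and
#' the remaining individuals are then assigned multinomially in
#' proportion to regional relative abundance among the chosen taxa.
#' Uses the current RNG state.
#'
#' @param x community table (rarefied; equal sample depths).
#' @param reference optional community table supplying the regional pool
#'   (occurrence frequencies and relative abundances); defaults to `x`
#'   itself.  Useful for evaluating a stratum or a simulated table
#'   against an externally defined pool.
#' @return an integer matrix with the same dimensions and dimnames.
#' @export
null_assemble <- function(x, reference = NULL) {
  m <- counts_matrix(x)
  ref <- if (is.null(reference)) m else counts_matrix(reference)
  if (ncol(ref) != ncol(m))
    stop("reference must cover the same taxa as the table")
  occ <- colMeans(ref > 0)
  ab <- colSums(ref) / sum(ref)
  rich <- rowSums(m > 0)
  tot <- rowSums(m)
  pool <- sum(occ > 0)
  if (any(rich > pool))
    stop("sample richness exceeds the regional taxon pool")
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    idx <- sample_weighted_norep(ncol(m), rich[i], occ)
    counts <- rep(1L, rich[i])
    rem <- tot[i] - rich[i]
    if (rem > 0)
      counts <- counts + stats::rmultinom(1, rem, ab[idx])[, 1]
    out[i, idx] <- counts
  }
  out
}

#' Abundance-based beta-diversity null deviation
#'
#' For every pair of samples, the deviation is the observed Bray-Curtis
#' dissimilarity minus its expectation over `n_null` random assemblies
#' from [null_assemble()].  Deviations near zero are consistent with
#' random (neutral) assembly; strongly positive deviations indicate
#' niche structuring.  Group summaries (mean and sd of the deviations of
#' within-group pairs) are returned when `groups` is given, together with
#' a Kruskal-Wallis comparison of the within-group deviations.
#'
#' @param x community table with equal sample depths (rarefied).
#' @param groups optional factor of sample groups for the summaries.
#' @param n_null number of null assemblies (>= 100 recommended; the
#'   study protocol uses 1000).
#' @param seed RNG seed.
#' @param reference optional pool table, see [null_assemble()].
#' @return list of class `beta_null_result`: `pairs` (data.frame with
#'   `sample_i`, `sample_j`, `observed_bc`, `null_mean_bc`, `null_sd_bc`,
#'   `deviation`), `summary` (per-group mean/sd), `n_null`, and, with
#'   two or more groups, attribute `kruskal_p`.
#' @export
beta_null_deviation <- function(x, groups = NULL, n_null = 1000,
                                seed = NULL, reference = NULL) {
  m <- counts_matrix(x)
  if (nrow(m) < 2) stop("need at least two samples")
  if (length(unique(rowSums(m))) != 1)
    warning("sample depths are unequal (expected for taxon strata of a ",
            "rarefied table; otherwise rarefy first)")
  if (n_null < 100)
    warning("n_null < 100 gives noisy null means")
  set_seed_if(seed)
  obs <- vegan::vegdist(m, method = "bray")
  np <- length(obs)
  mean_acc <- numeric(np)
  m2_acc <- numeric(np)
  for (r in seq_len(n_null)) {
    null_d <- as.vector(vegan::vegdist(null_assemble(x, reference),
                                       method = "bray"))
    delta <- null_d - mean_acc
    mean_acc <- mean_acc + delta / r
    m2_acc <- m2_acc + delta * (null_d - mean_acc)
  }
  null_sd <- sqrt(m2_acc / (n_null - 1))
  labs <- rownames(m)
  ij <- which(lower.tri(diag(nrow(m))), arr.ind = TRUE)
  pairs <- data.frame(sample_i = labs[ij[, 2]], sample_j = labs[ij[, 1]],
                      observed_bc = as.vector(obs),
                      null_mean_bc = mean_acc, null_sd_bc = null_sd,
                      deviation = as.vector(obs) - mean_acc,
                      stringsAsFactors = FALSE)
  if (is.null(groups)) {
    summ <- data.frame(group = "all", mean_deviation = mean(pairs$deviation),
                       sd_deviation = stats::sd(pairs$deviation),
                       n_pairs = np, stringsAsFactors = FALSE)
    kr <- NULL
  } else {
    groups <- factor(groups)
    gi <- groups[ij[, 2]]
    gj <- groups[ij[, 1]]
    within <- as.character(gi) == as.character(gj)
    wg <- droplevels(gi[within])
    dev_w <- pairs$deviation[within]
    summ <- data.frame(group = levels(wg),
                       mean_deviation = tapply(dev_w, wg, mean),
                       sd_deviation = tapply(dev_w, wg, stats::sd),
                       n_pairs = as.vector(table(wg)),
                       stringsAsFactors = FALSE, row.names = NULL)
    kr <- if (nlevels(wg) >= 2)
      stats::kruskal.test(dev_w, wg)$p.value else NULL
  }
  out <- list(pairs = pairs, summary = summ, n_null = n_null)
  attr(out, "kruskal_p") <- kr
  class(out) <- "beta_null_result"
  out
}

#' @export
print.beta_null_result <- function(x, ...) {
  cat(sprintf("beta-null deviation over %d pairs (%d null assemblies)\n",
              nrow(x$pairs), x$n_null))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sloan neutral prediction of occurrence frequency
#'
#' Under the Sloan et al. neutral community model the local relative
#' abundance of a taxon with metacommunity mean relative abundance p is
#' approximately Beta(N m p, N m (1 - p)), where N is the local community
#' size and m the immigration probability per death.  The predicted
#' occurrence frequency is the probability that this beta variable
#' exceeds the detection limit d: `1 - pbeta(d, N m p, N m (1 - p))`.
#' Strictly increasing in both p and m.
#'
#' @param p metacommunity mean relative abundance, in (0, 1); vectorised.
#' @param N local community size (by convention the rarefaction depth).
#' @param m migration rate, with `N * m > 0`.
#' @param d detection limit in (0, 1); default `1/N` (a single read).
#' @return predicted occurrence frequencies in \[0, 1\].
#' @export
sloan_predicted_frequency <- function(p, N, m, d = 1 / N) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (N * m <= 0) stop("N * m must be positive")
  if (d <= 0 || d >= 1) stop("detection limit d must be in (0, 1)")
  a <- N * m * p
  b <- N * m * (1 - p)
  if (any(a <= 0) || any(b <= 0)) stop("degenerate beta shapes")
  1 - stats::pbeta(d, a, b)
}

# core least-squares fit of m on (p_mean, freq_obs)
fit_sloan_core <- function(p_mean, freq_obs, N, d, conf = 0.95,
                           n_samples = NULL) {
  sse <- function(m) {
    pred <- sloan_predicted_frequency(p_mean, N, m, d)
    sum((freq_obs - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(1e-6, 1))
  m_hat <- opt$minimum
  pred <- sloan_predicted_frequency(p_mean, N, m_hat, d)
  ss_tot <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- 1 - opt$objective / ss_tot
  ci <- wilson_interval(pred, n_samples, conf = conf)
  list(m = m_hat, R2 = r2, pred = pred, ci_low = ci$low, ci_high = ci$high,
       at_bound = m_hat > 1 - 1e-4 || m_hat < 2e-6)
}

#' Fit the Sloan neutral community model
#'
#' Fits the single free migration parameter m by bounded one-dimensional
#' nonlinear least squares of observed occurrence frequencies against the
#' neutral prediction, using each taxon's mean relative abundance as its
#' metacommunity abundance.  A 95% Wilson score interval around the
#' predicted frequency (with the number of samples as trials) partitions
#' taxa into over-represented (observed frequency above the band),
#' under-represented (below), and neutrally distributed (within).
#'
#' @param x community table (ideally rarefied to even depth).
#' @param N local community size; default the median sample depth.
#' @param d detection limit; default `1/N`.
#' @param conf confidence level of the partition band.
#' @return object of class `neutral_fit`: list with `m`, `N`, `d`, `R2`,
#'   `at_bound` flag, and `taxa` (data.frame: `taxon_id`, `p_mean`,
#'   `freq_obs`, `freq_pred`, `ci_low`, `ci_high`, `partition`).
#' @export
fit_neutral_model <- function(x, N = NULL, d = NULL, conf = 0.95) {
  m <- counts_matrix(x)
  if (is.null(N)) N <- stats::median(rowSums(m))
  if (is.null(d)) d <- 1 / N
  rel <- sweep(m, 1, rowSums(m), "/")
  p_mean <- colMeans(rel)
  freq_obs <- colMeans(m > 0)
  keep <- p_mean > 0 & p_mean < 1
  if (all(freq_obs[keep] == 1))
    stop("degenerate fit: every taxon occurs in every sample")
  if (sum(freq_obs[keep] > 0 & freq_obs[keep] < 1) < 5)
    warning("fewer than 5 taxa with intermediate occurrence; ",
            "fit will be poorly constrained")
  fit <- fit_sloan_core(p_mean[keep], freq_obs[keep], N, d, conf = conf,
                        n_samples = nrow(m))
  partition <- rep("neutral", sum(keep))
  partition[freq_obs[keep] > fit$ci_high] <- "over"
  partition[freq_obs[keep] < fit$ci_low] <- "under"
  taxa <- data.frame(taxon_id = colnames(m)[keep],
                     p_mean = p_mean[keep], freq_obs = freq_obs[keep],
                     freq_pred = fit$pred, ci_low = fit$ci_low,
                     ci_high = fit$ci_high, partition = partition,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(m = fit$m, N = N, d = d, R2 = fit$R2,
                 at_bound = fit$at_bound, taxa = taxa),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: m = %.4f, N = %g, R2 = %.3f%s\n",
              x$m, x$N, x$R2,
              if (x$at_bound) " (optimizer at bound)" else ""))
  print(table(x$taxa$partition))
  invisible(x)
}

#' Cross-partition taxa by neutral prediction and niche class
#'
#' Crosses the neutral-model partition (over / neutral / under) with the
#' generalist/specialist classification computed on the same table, and
#' reports, per niche class, the ratio of non-neutrally to neutrally
#' distributed taxa both by richness (taxon counts) and by summed mean
#' relative abundance.
#'
#' @param fit a `neutral_fit`.
#' @param classification a `niche_classification` on the same table.
#' @return list: `counts` (partition x niche class), `rel_abund` (summed
#'   p_mean), `richness_ratio`, `abundance_ratio` (named by niche class;
#'   0 when no taxon of the class is non-neutral, `Inf` when none is
#'   neutral).
#' @export
partition_by_neutral_prediction <- function(fit, classification) {
  ft <- fit$taxa
  common <- intersect(ft$taxon_id, classification$taxon_id)
  if (length(common) == 0 ||
      length(setdiff(ft$taxon_id, classification$taxon_id)) > 0)
    stop("taxon ids of the neutral fit and classification do not match")
  cls <- classification$label[match(ft$taxon_id, classification$taxon_id)]
  part <- factor(ft$partition, levels = c("over", "neutral", "under"))
  cls <- factor(cls, levels = c("generalist", "specialist",
                                "non_significant"))
  counts <- table(partition = part, niche = cls)
  rel <- tapply(ft$p_mean, list(part, cls), sum, default = 0)
  non_neutral <- counts["over", ] + counts["under", ]
  ratio <- function(num, den) ifelse(num == 0 & den == 0, 0, num / den)
  richness_ratio <- ratio(non_neutral, counts["neutral", ])
  ab_non <- rel["over", ] + rel["under", ]
  abundance_ratio <- ratio(ab_non, rel["neutral", ])
  list(counts = counts, rel_abund = rel,
       richness_ratio = richness_ratio,
       abundance_ratio = abundance_ratio)
}
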