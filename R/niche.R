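#' Levins' niche breadth per taxon
#'
#' For taxon j with counts across samples, let q_ij be the proportion of
#' taxon j's total found in sample i.  Levins' breadth is the inverse
#' Simpson concentration `B_j = 1 / sum_i(q_ij^2)`, ranging from 1 (all
#' of the taxon in one sample; an extreme specialist) to the number of
#' samples (perfectly even occupancy; an extreme generalist).  B is
#' invariant to rescaling a taxon's counts by a positive constant.
#'
#' @param x community table (samples x taxa) or count matrix.
#' @return named numeric vector of breadths, one per taxon with positive
#'   total count; all-zero taxa are excluded with a warning.
#' @export
levins_breadth <- function(x) {
  m <- counts_matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("all-zero taxa excluded from niche breadth")
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  q <- sweep(m, 2, tot, "/")
  1 / colSums(q^2)
}

#' Classify habitat generalists and specialists
#'
#' Compares each taxon's Levins breadth to its null distribution over
#' randomised tables that preserve every sample total and every taxon
#' total exactly (vegan's fixed-fixed `quasiswap_count` algorithm, the
#' standard null for generalist/specialist screening of count tables).
#' A taxon is a generalist if its observed B exceeds the upper null
#' quantile, a specialist if it falls below the lower quantile, and
#' non-significant otherwise; boundary ties are non-significant
#' (conservative).  Intended to be run on a rarefied table so that equal
#' sample depths are not confounded with the fixed sample margins.
#'
#' @param x community table.
#' @param n_perm number of null tables (>= 100; the study protocol uses
#'   1000).
#' @param alpha two-sided significance level; quantiles at `alpha/2` and
#'   `1 - alpha/2`.
#' @param seed RNG seed.
#' @param batch null tables are simulated in batches of this size to
#'   bound memory at large table sizes.
#' @return data.frame of class `niche_classification`: `taxon_id`, `B`,
#'   `null_low`, `null_high`, `mean_rel_abund`, `label`.
#' @export
classify_generalists_specialists <- function(x, n_perm = 1000, alpha = 0.05,
                                             seed = NULL, batch = 200) {
  if (n_perm < 100) stop("need at least 100 permutations")
  m <- counts_matrix(x)
  if (sum(rowSums(m) > 0) < 2 || sum(colSums(m) > 0) < 2)
    stop("table too small for the swap null model (< 2x2 non-zero)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  B_obs <- levins_breadth(x)
  nm <- vegan::nullmodel(m, "quasiswap_count")
  null_B <- matrix(NA_real_, n_perm, ncol(m))
  done <- 0L
  b <- 0L
  rs <- rowSums(m); cs <- colSums(m)
  while (done < n_perm) {
    b <- b + 1L
    k <- min(batch, n_perm - done)
    sims <- stats::simulate(nm, nsim = k, seed = derive_seed(seed, b))
    for (j in seq_len(k)) {
      sim <- sims[, , j]
      # fixed-fixed invariant: every null table keeps both margins exactly
      stopifnot(all(rowSums(sim) == rs), all(colSums(sim) == cs))
      q <- sweep(sim, 2, cs, "/")
      null_B[done + j, ] <- 1 / colSums(q^2)
    }
    done <- done + k
  }
  qs <- apply(null_B, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  label <- rep("non_significant", ncol(m))
  label[B_obs > qs[2, ]] <- "generalist"
  label[B_obs < qs[1, ]] <- "specialist"
  rel <- sweep(m, 1, rowSums(m), "/")
  out <- data.frame(taxon_id = colnames(m), B = unname(B_obs),
                    null_low = qs[1, ], null_high = qs[2, ],
                    mean_rel_abund = colMeans(rel),
                    label = label, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("niche_classification", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}

#' Write a niche classification as TSV
#'
#' @param x a `niche_classification`.
#' @param path output file.
#' @export
write_niche_classification <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
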