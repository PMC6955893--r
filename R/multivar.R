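#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum_j min(x_j, y_j) / (sum_j x_j + sum_j y_j)`,
#' computed on counts via [vegan::vegdist()].
#'
#' @param x community table.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- counts_matrix(x)
  if (any(rowSums(m) == 0)) stop("all-zero samples have no Bray-Curtis")
  vegan::vegdist(m, method = "bray")
}

# Gower-centred inner-product matrix of a distance matrix
gower_centre <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  a <- -0.5 * d^2
  cen <- diag(n) - matrix(1 / n, n, n)
  cen %*% a %*% cen
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type-I) partitioning of a Gower-centred distance matrix
#' over the terms of a factorial design, with pseudo-F statistics and
#' permutation p-values obtained by freely permuting sample identities.
#' Supports crossed factors with interactions (e.g.
#' `~ environment * site`).  With `exact = TRUE` (n <= 8 samples) all
#' n! permutations are enumerated and the p-value is the exact fraction
#' of permutations (the identity included) whose pseudo-F is at least
#' the observed one, which for a single grouping factor equals
#' enumeration over the distinct label assignments.
#'
#' @param dm distance matrix (`dist`).
#' @param data data.frame of design factors, rows aligned with `dm`.
#' @param formula right-hand-side formula over columns of `data`; terms
#'   are partitioned in the order given.
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exact enumerate all permutations (requires n <= 8).
#' @param permutations optional integer matrix of permutations (one per
#'   row), overriding `n_perm`; rows must be permutations of `1:n`.
#' @return data.frame of class `permanova`: one row per term plus
#'   `Residual` and `Total`, with `Df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @export
permanova <- function(dm, data, formula = ~environment, n_perm = 999,
                      seed = NULL, exact = FALSE, permutations = NULL) {
  n <- attr(dm, "Size")
  if (nrow(data) != n) stop("data rows do not match distance matrix")
  default_rn <- all(rownames(data) == as.character(seq_len(n)))
  if (!is.null(labels(dm)) && !default_rn &&
      !all(labels(dm) == rownames(data)))
    stop("sample order of data and distance matrix differ")
  G <- gower_centre(dm)
  mm <- stats::model.matrix(formula, data)
  asg <- attr(mm, "assign")
  term_labels <- attr(stats::terms(formula, data = data), "term.labels")
  qr_full <- qr(mm)
  if (qr_full$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_full$pivot[(qr_full$rank + 1):ncol(mm)]]
    stop("singular design; aliased terms: ", paste(aliased, collapse = ", "))
  }
  K <- length(term_labels)
  hats <- vector("list", K + 1)
  hats[[1]] <- matrix(1 / n, n, n)  # intercept
  df <- integer(K)
  for (k in seq_len(K)) {
    hats[[k + 1]] <- hat_matrix(mm[, asg <= k, drop = FALSE])
    df[k] <- sum(asg == k)
  }
  projs <- lapply(seq_len(K), function(k) hats[[k + 1]] - hats[[k]])
  resid_proj <- diag(n) - hats[[K + 1]]
  df_res <- n - qr_full$rank
  ss_term <- function(Gp) vapply(projs, function(M) sum(M * Gp), 0)
  ss_obs <- ss_term(G)
  ss_res <- sum(resid_proj * G)
  ss_tot <- sum(diag(G))
  f_stat <- function(ss_t, ss_r) (ss_t / df) / (ss_r / df_res)
  f_obs <- f_stat(ss_obs, ss_res)
  if (is.null(permutations)) {
    if (exact) {
      if (n > 8) stop("exact enumeration requires n <= 8 samples")
      permutations <- all_permutations(n)
    } else {
      set_seed_if(seed)
      permutations <- t(replicate(n_perm, sample.int(n)))
    }
  }
  hits <- numeric(K)
  for (r in seq_len(nrow(permutations))) {
    pi <- permutations[r, ]
    Gp <- G[pi, pi]
    fp <- f_stat(ss_term(Gp), sum(resid_proj * Gp))
    hits <- hits + (fp >= f_obs - 1e-12)
  }
  p <- if (exact) hits / nrow(permutations) else
    (1 + hits) / (1 + nrow(permutations))
  out <- data.frame(
    term = c(term_labels, "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(ss_obs, ss_res, ss_tot),
    R2 = c(ss_obs, ss_res, ss_tot) / ss_tot,
    F = c(f_obs, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova", class(out))
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast `R = (mean between-group rank - mean within-group
#' rank) / (M / 2)` with `M = n (n - 1) / 2`, in \[-1, 1\]; p-value by
#' permutation of group labels (exact enumeration over all permutations
#' when `exact = TRUE` and n <= 8).
#'
#' @param dm distance matrix.
#' @param groups factor of group memberships.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exact enumerate all label permutations (n <= 8).
#' @return list of class `anosim_test`: `statistic`, `p`, `n_perm`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = NULL,
                        exact = FALSE) {
  groups <- factor(groups)
  n <- attr(dm, "Size")
  if (length(groups) != n) stop("groups must match distance matrix")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2))
    warning("groups of size 1 make within-group ranks undefined for them")
  r <- rank(as.vector(dm))
  M <- n * (n - 1) / 2
  ij <- which(lower.tri(diag(n)), arr.ind = TRUE)
  stat_for <- function(g) {
    within <- g[ij[, 1]] == g[ij[, 2]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  stat <- stat_for(groups)
  if (exact) {
    if (n > 8) stop("exact enumeration requires n <= 8 samples")
    perms <- all_permutations(n)
    null <- apply(perms, 1, function(pi) stat_for(groups[pi]))
    p <- mean(null >= stat - 1e-12)
    n_used <- nrow(perms)
  } else {
    set_seed_if(seed)
    null <- replicate(n_perm, stat_for(groups[sample.int(n)]))
    p <- perm_pvalue(null, stat)
    n_used <- n_perm
  }
  structure(list(statistic = stat, p = p, n_perm = n_used),
            class = "anosim_test")
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Iterative variance-inflation-factor screening
#'
#' Computes `VIF_i = 1 / (1 - R2_i)` from regressing each variable on all
#' others and repeatedly drops the variable with the largest VIF until
#' all VIFs are at or below the threshold.  Perfectly collinear
#' variables have infinite VIF and are dropped deterministically (ties
#' broken by variable name order).
#'
#' @param env data.frame or matrix of continuous variables (>= 2
#'   columns, each with positive variance).
#' @param threshold maximum acceptable VIF (default 5).
#' @return list: `retained` (names), `vif` (final VIFs), `dropped`
#'   (data.frame of dropped variables and the VIF at removal).
#' @export
vif_filter <- function(env, threshold = 5) {
  X <- as.data.frame(env)
  if (ncol(X) < 2) stop("need at least two variables")
  if (!all(vapply(X, is.numeric, TRUE))) stop("variables must be numeric")
  if (any(vapply(X, stats::var, 0) == 0))
    stop("constant variables: ",
         paste(names(X)[vapply(X, stats::var, 0) == 0], collapse = ", "))
  vif_of <- function(X) {
    vapply(seq_along(X), function(i) {
      # perfect fits are expected for exact duplicates; VIF becomes Inf
      r2 <- suppressWarnings(
        summary(stats::lm(X[[i]] ~ ., data = X[-i]))$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  dropped <- data.frame(variable = character(0), vif = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    v <- vif_of(X)
    names(v) <- names(X)
    if (max(v) <= threshold || ncol(X) <= 1) break
    cand <- which(v == max(v))
    drop <- names(X)[cand[order(names(X)[cand])[1]]]
    dropped <- rbind(dropped,
                     data.frame(variable = drop, vif = unname(v[drop]),
                                stringsAsFactors = FALSE))
    X[[drop]] <- NULL
  }
  list(retained = names(X), vif = v, dropped = dropped)
}

#' PCNM spatial eigenvectors
#'
#' Principal Coordinates of Neighbour Matrices: the Euclidean distance
#' matrix of the sample coordinates is truncated at the longest edge of
#' its minimum spanning tree (distances beyond it replaced by 4x the
#' threshold) and the positive-eigenvalue principal coordinates of the
#' truncated matrix are returned as spatial predictors.  Delegates to
#' [vegan::pcnm()].
#'
#' @param coords matrix or data.frame of planar coordinates (n x 2, or
#'   n x k), at least 3 distinct points.
#' @return matrix of spatial eigenvectors (columns `PCNM1`, ...), with
#'   attributes `values` (eigenvalues) and `threshold`.
#' @export
pcnm_vectors <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 3)
    stop("need at least 3 distinct coordinates")
  pc <- vegan::pcnm(stats::dist(coords))
  out <- as.matrix(pc$vectors)
  attr(out, "values") <- pc$values[pc$values > 0]
  attr(out, "threshold") <- pc$threshold
  out
}

#' db-RDA variation partitioning of a distance matrix
#'
#' Partitions the variation of a (Bray-Curtis) distance matrix between an
#' environmental and a spatial predictor set by partial distance-based
#' redundancy analysis: Ezekiel-adjusted R-squared of the environmental,
#' spatial and joint models give the pure fractions by subtraction
#' (pure env = adj(env+spat) - adj(spat)), the shared fraction as the
#' remainder (it may be negative), and permutation p-values for the
#' testable (pure and total) fractions.  Negative PCoA eigenvalues are
#' handled by square-root transformation of the dissimilarities when
#' present (`sqrt_dist = "auto"`).
#'
#' @param dm distance matrix.
#' @param env,spat data.frames/matrices of predictors, rows aligned with
#'   `dm`.
#' @param n_perm permutations for the fraction tests.
#' @param seed RNG seed.
#' @param sqrt_dist `"auto"` (default; correct only when negative
#'   eigenvalues are present), `"never"`, or `"always"`.
#' @return list of class `variation_partition`: `adjR2` (named:
#'   `pure_env`, `pure_spat`, `shared`, `total`, `residual`), `p`
#'   (named: `pure_env`, `pure_spat`, `total`), `sqrt_dist` flag.
#' @export
dbrda_varpart <- function(dm, env, spat, n_perm = 999, seed = NULL,
                          sqrt_dist = c("auto", "never", "always")) {
  sqrt_dist <- match.arg(sqrt_dist)
  n <- attr(dm, "Size")
  E <- as.matrix(as.data.frame(env))
  S <- as.matrix(as.data.frame(spat))
  if (nrow(E) != n || nrow(S) != n)
    stop("predictor rows do not match the distance matrix")
  if (ncol(E) + ncol(S) > n - 1)
    stop("more predictors than samples - 1")
  use_sqrt <- switch(sqrt_dist,
    never = FALSE,
    always = TRUE,
    auto = {
      eig <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))$eig
      neg <- any(eig < -sqrt(.Machine$double.eps) * max(abs(eig)))
      if (neg) message("negative PCoA eigenvalues: ",
                       "applying square-root correction to dissimilarities")
      neg
    })
  vp <- vegan::varpart(dm, E, S, sqrt.dist = use_sqrt)
  ind <- vp$part$indfract$Adj.R.squared
  names(ind) <- c("pure_env", "pure_spat", "shared", "residual")
  total <- sum(ind[c("pure_env", "pure_spat", "shared")])
  set_seed_if(seed)
  # a fully aliased conditional model (e.g. env identical to spat) has a
  # rank-zero constrained component; its fraction is untestable -> NA
  safe_p <- function(expr) tryCatch(
    stats::anova(expr, permutations = n_perm)$`Pr(>F)`[1],
    error = function(e) NA_real_)
  p_pure_env <- safe_p(vegan::dbrda(dm ~ E + Condition(S),
                                    sqrt.dist = use_sqrt))
  p_pure_spat <- safe_p(vegan::dbrda(dm ~ S + Condition(E),
                                     sqrt.dist = use_sqrt))
  p_total <- safe_p(vegan::dbrda(dm ~ E + S, sqrt.dist = use_sqrt))
  structure(list(
    adjR2 = c(ind[c("pure_env", "pure_spat", "shared")], total = total,
              residual = unname(ind["residual"])),
    p = c(pure_env = p_pure_env, pure_spat = p_pure_spat,
          total = p_total),
    sqrt_dist = use_sqrt), class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("db-RDA variation partitioning (adjusted R2):\n")
  print(round(x$adjR2, 4))
  cat("permutation p-values:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Forward selection of constraining variables for db-RDA
#'
#' Greedy addition of the candidate variable that most increases the
#' adjusted R-squared, with the double stopping rule: stop when the best
#' candidate's permutation p-value exceeds `alpha` or when the model's
#' adjusted R-squared would exceed that of the global (all-candidate)
#' model.  Delegates to [vegan::ordiR2step()] on db-RDA models.
#'
#' @param dm distance matrix.
#' @param candidates data.frame of candidate variables (pass them
#'   through [vif_filter()] first).
#' @param alpha inclusion threshold on the permutation p-value.
#' @param n_perm permutations per inclusion test.
#' @param seed RNG seed.
#' @return list: `selected` (character, possibly empty), `adj_r2` of the
#'   selected model, `global_adj_r2`, and the selection `trace`.
#' @export
forward_select <- function(dm, candidates, alpha = 0.05, n_perm = 199,
                           seed = NULL) {
  dat <- as.data.frame(candidates)
  m0 <- vegan::dbrda(dm ~ 1, data = dat)
  m1 <- vegan::dbrda(dm ~ ., data = dat)
  set_seed_if(seed)
  sel <- vegan::ordiR2step(m0, scope = stats::formula(m1), Pin = alpha,
                           R2scope = TRUE, trace = FALSE,
                           permutations = permute::how(nperm = n_perm))
  selected <- attr(stats::terms(sel), "term.labels")
  list(selected = selected,
       adj_r2 = vegan::RsquareAdj(sel)$adj.r.squared,
       global_adj_r2 = vegan::RsquareAdj(m1)$adj.r.squared,
       trace = sel$anova)
}
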