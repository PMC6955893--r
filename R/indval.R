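#' Dufrene-Legendre indicator values
#'
#' For taxon j and group k, specificity `A_jk` is the group's share of
#' the taxon's mean abundance (mean abundance of j in k divided by the
#' sum of its group means) and fidelity `B_fid_jk` is the fraction of
#' samples of k in which the taxon occurs.  The indicator value is their
#' product; each taxon is reported for its maximizing group.  (Fidelity
#' is written `B_fid` to avoid collision with Levins' breadth B.)
#'
#' @param x community table.
#' @param groups factor (or coercible) of group membership, one per
#'   sample; at least two groups with at least one sample each.
#' @return data.frame: `taxon_id`, `group` (maximizing group), `A`,
#'   `B_fid`, `indval`.  The full taxon x group indval matrix is attached
#'   as attribute `indval_matrix`.
#' @export
indval_scores <- function(x, groups) {
  m <- counts_matrix(if (inherits(x, "community_table")) x else
    community_table(x, quiet = TRUE))
  groups <- factor(groups)
  if (length(groups) != nrow(m))
    stop("groups must have one entry per sample")
  if (nlevels(groups) < 2) stop("need at least two groups")
  iv <- indval_matrix(m, groups)
  best <- apply(iv$indval, 2, which.max)
  j <- seq_len(ncol(m))
  out <- data.frame(taxon_id = colnames(m),
                    group = levels(groups)[best],
                    A = iv$A[cbind(best, j)],
                    B_fid = iv$B_fid[cbind(best, j)],
                    indval = iv$indval[cbind(best, j)],
                    stringsAsFactors = FALSE)
  attr(out, "indval_matrix") <- iv$indval
  out
}

# specificity, fidelity and indval matrices (groups x taxa)
indval_matrix <- function(m, groups) {
  ng <- as.vector(table(groups))
  gmean <- rowsum(m, groups) / ng
  A <- sweep(gmean, 2, colSums(gmean), "/")
  B_fid <- rowsum((m > 0) + 0, groups) / ng
  list(A = A, B_fid = B_fid, indval = A * B_fid)
}

#' Permutation significance of indicator values
#'
#' The null statistic for each taxon is its maximum-group indicator value
#' under permutation of the group labels across samples.  With
#' `exact = TRUE` (or automatically for two-group designs with at most
#' `exact_limit` distinct label assignments) the null is enumerated over
#' all distinct assignments and the p-value is the exact fraction of
#' assignments with a null value at least as large as the observed one.
#' Otherwise `p = (1 + #{null >= obs}) / (1 + n_perm)`, which is never 0.
#'
#' @param x community table.
#' @param groups group factor.
#' @param n_perm number of random permutations (>= 99).
#' @param seed RNG seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default `NULL` decides by `exact_limit`.
#' @param exact_limit maximum number of distinct assignments enumerated.
#' @return numeric vector of p-values, one per taxon.
#' @export
indval_significance <- function(x, groups, n_perm = 999, seed = NULL,
                                exact = NULL, exact_limit = 5000) {
  m <- counts_matrix(if (inherits(x, "community_table")) x else
    community_table(x, quiet = TRUE))
  groups <- factor(groups)
  n <- nrow(m)
  obs <- apply(indval_matrix(m, groups)$indval, 2, max)
  two_groups <- nlevels(groups) == 2
  n_assign <- if (two_groups) choose(n, sum(groups == levels(groups)[1])) else Inf
  if (is.null(exact)) exact <- two_groups && n_assign <= exact_limit
  if (exact) {
    if (!two_groups || n_assign > exact_limit)
      stop("exact enumeration only supported for two groups with <= ",
           exact_limit, " assignments")
    n1 <- sum(groups == levels(groups)[1])
    combos <- utils::combn(n, n1)
    hits <- numeric(ncol(m))
    for (a in seq_len(ncol(combos))) {
      g <- factor(rep(levels(groups)[2], n), levels = levels(groups))
      g[combos[, a]] <- levels(groups)[1]
      null <- apply(indval_matrix(m, g)$indval, 2, max)
      hits <- hits + (null >= obs - 1e-12)
    }
    p <- hits / ncol(combos)
  } else {
    if (n_perm < 99) stop("need at least 99 permutations")
    set_seed_if(seed)
    hits <- numeric(ncol(m))
    for (r in seq_len(n_perm)) {
      g <- groups[sample.int(n)]
      null <- apply(indval_matrix(m, g)$indval, 2, max)
      hits <- hits + (null >= obs - 1e-12)
    }
    p <- (1 + hits) / (1 + n_perm)
  }
  stats::setNames(p, colnames(m))
}

#' Select good indicator taxa
#'
#' Applies the study's gates: indicator value strictly greater than
#' `indval_min` and permutation p strictly below `p_max`.
#'
#' @param records data.frame from [indval_analysis()] (needs columns
#'   `indval` and `p`).
#' @param indval_min,p_max selection thresholds (defaults 0.75 and 0.01).
#' @return the filtered data.frame.
#' @export
select_indicators <- function(records, indval_min = 0.75, p_max = 0.01) {
  records[records$indval > indval_min & records$p < p_max, , drop = FALSE]
}

#' Indicator species analysis in one call
#'
#' Scores, permutation p-values and the selection flag, in the layout the
#' module writes to TSV.
#'
#' @inheritParams indval_significance
#' @param indval_min,p_max selection gates, see [select_indicators()].
#' @return data.frame: `taxon_id`, `group`, `A`, `B_fid`, `indval`, `p`,
#'   `selected`.
#' @export
indval_analysis <- function(x, groups, n_perm = 999, seed = NULL,
                            exact = NULL, indval_min = 0.75, p_max = 0.01) {
  rec <- indval_scores(x, groups)
  rec$p <- indval_significance(x, groups, n_perm = n_perm, seed = seed,
                               exact = exact)
  rec$selected <- rec$indval > indval_min & rec$p < p_max
  attr(rec, "indval_matrix") <- NULL
  rec
}
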