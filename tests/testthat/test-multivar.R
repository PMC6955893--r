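test_that("Bray-Curtis matches hand values and the defining formula", {
  m <- matrix(c(1L, 1L, 1L, 3L), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  expect_equal(as.vector(bray_curtis(community_table(m, quiet = TRUE))),
               1 / 3)
  same <- matrix(c(2L, 5L, 2L, 5L), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.vector(bray_curtis(community_table(same, quiet = TRUE))),
               0)
  disj <- matrix(c(3L, 0L, 0L, 4L), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.vector(bray_curtis(community_table(disj, quiet = TRUE))),
               1)
  # defining formula on a random pair
  tab <- random_table(n = 2, S = 20, seed = 13)
  x <- unclass(tab)[1, ]; y <- unclass(tab)[2, ]
  expect_equal(as.vector(bray_curtis(tab)),
               1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y)))
})

test_that("PERMANOVA agrees with vegan::adonis2 term by term", {
  sim <- simulate_niche_community(
    add_niche_traits(bench_meta(71), seed = 72),
    bench_design(73, regime = "niche"))
  dm <- bray_curtis(sim$table)
  md <- sim$metadata
  set.seed(1)
  pm <- t(replicate(199, sample(24)))
  mine <- permanova(dm, md, ~ environment * site, permutations = pm)
  ref <- vegan::adonis2(dm ~ environment * site, data = md,
                        permutations = pm, by = "terms")
  expect_equal(mine$SumOfSqs[1:5], ref$SumOfSqs, tolerance = 1e-10)
  expect_equal(mine$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
  expect_equal(mine$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$p[1:3], ref$`Pr(>F)`[1:3])
  # partition identity: term R2s plus residual sum to 1
  expect_equal(sum(mine$R2[1:4]), 1, tolerance = 1e-9)
})

test_that("PERMANOVA exact p equals enumeration over label assignments", {
  # two clearly separated 3-sample clusters
  set.seed(2)
  m <- rbind(matrix(rpois(3 * 10, 20), 3, 10),
             matrix(rpois(3 * 10, 20) + 60L, 3, 10))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:10))
  tab <- community_table(m, quiet = TRUE)
  dm <- bray_curtis(tab)
  md <- data.frame(g = factor(rep(c("A", "B"), each = 3)))
  res <- permanova(dm, md, ~ g, exact = TRUE)
  # oracle: pseudo-F over all 20 assignments via Anderson's formula
  combos <- utils::combn(6, 3)
  f_obs <- oracle_pseudo_f(dm, md$g)
  f_null <- vapply(seq_len(ncol(combos)), function(a)
    oracle_pseudo_f(dm, ifelse(seq_len(6) %in% combos[, a], "A", "B")), 0)
  p_oracle <- mean(f_null >= f_obs - 1e-12)
  expect_equal(res$F[1], f_obs, tolerance = 1e-10)
  expect_equal(res$p[1], p_oracle)
  # complete separation: minimal p is 2/20 because every partition
  # appears under both labelings among the 20 assignments
  expect_equal(res$p[1], 2 / 20)

  # singular designs are rejected with the aliased term named
  md2 <- data.frame(g = md$g, h = md$g)
  expect_error(permanova(dm, md2, ~ g + h), "aliased")
})

test_that("ANOSIM matches manual ranking and vegan", {
  set.seed(3)
  m <- rbind(matrix(rpois(3 * 8, 10), 3, 8),
             matrix(rpois(3 * 8, 10) + 40L, 3, 8))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:8))
  dm <- bray_curtis(community_table(m, quiet = TRUE))
  g <- factor(rep(c("A", "B"), each = 3))
  res <- anosim_test(dm, g, n_perm = 99, seed = 4)
  # complete separation: R = 1
  expect_equal(res$statistic, 1)
  # manual ranking oracle
  r <- rank(as.vector(dm))
  within <- as.vector(outer(g, g, "==")[lower.tri(diag(6))])
  r_manual <- (mean(r[!within]) - mean(r[within])) / (15 / 2)
  expect_equal(res$statistic, r_manual)
  expect_equal(res$statistic,
               as.numeric(vegan::anosim(dm, g, permutations = 9)$statistic))
  # null symmetry: irrelevant groups give R near 0
  tab <- random_table(n = 12, S = 20, seed = 5)
  dmr <- bray_curtis(tab)
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    g2 <- factor(sample(rep(c("A", "B"), each = 6)))
    anosim_test(dmr, g2, n_perm = 19, seed = s)$statistic
  }, 0)
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("VIF screening drops collinear variables like stepwise regression", {
  set.seed(6)
  n <- 40
  base <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  # identical twin: infinite VIF, one of the pair dropped
  dup <- cbind(base, a2 = base$a)
  out <- vif_filter(dup)
  expect_equal(sort(out$dropped$variable), "a")  # name-order tie-break
  expect_true(all(out$vif <= 5))
  # orthogonal variables all retained with VIF near 1
  out2 <- vif_filter(base)
  expect_equal(out2$retained, c("a", "b", "c"))
  expect_true(all(out2$vif < 1.5))
  # near-duplicate pair: stepwise oracle agrees
  nd <- cbind(base, d = base$a + rnorm(n, 0, 0.05), e = rnorm(n))
  out3 <- vif_filter(nd)
  r2 <- summary(stats::lm(nd[[1]] ~ ., data = nd[, -1]))$r.squared
  expect_gt(1 / (1 - r2), 5)       # 'a' truly exceeded the threshold
  expect_equal(length(out3$dropped$variable), 1)
  expect_true(out3$dropped$variable %in% c("a", "d"))
  expect_error(vif_filter(base[, 1, drop = FALSE]), "two variables")
  expect_error(vif_filter(data.frame(a = rnorm(5), k = rep(1, 5))),
               "constant")
})

test_that("PCNM eigenvectors are orthogonal, complete and rigid-motion invariant", {
  coords <- cbind(x = seq(0, 60, by = 10), y = 0)
  pc <- pcnm_vectors(coords)
  # orthogonality
  cp <- crossprod(pc)
  expect_lt(max(abs(cp[lower.tri(cp)])), 1e-9)
  # positive-eigenvalue count against an independent spectral oracle
  d <- as.matrix(stats::dist(coords))
  thr <- attr(pc, "threshold")
  dtr <- ifelse(d > thr, 4 * thr, d)
  diag(dtr) <- 0
  n <- nrow(dtr)
  G <- (diag(n) - 1 / n) %*% (-0.5 * dtr^2) %*% (diag(n) - 1 / n)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ncol(pc), sum(ev > 1e-8 * max(ev)))
  # translation and rotation leave the vectors unchanged up to sign
  th <- 0.7
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  coords2 <- sweep(as.matrix(coords) %*% rot, 2, c(100, -50), "+")
  pc2 <- pcnm_vectors(coords2)
  for (k in seq_len(ncol(pc)))
    expect_lt(min(max(abs(pc[, k] - pc2[, k])),
                  max(abs(pc[, k] + pc2[, k]))), 1e-6)
  expect_error(pcnm_vectors(matrix(1, 5, 2)), "distinct")
})

test_that("variation partitioning obeys its identities", {
  sim <- simulate_niche_community(
    add_niche_traits(bench_meta(81), sigma_background = 1, seed = 82),
    bench_design(83, regime = "niche"))
  dm <- bray_curtis(sim$table)
  env <- sim$metadata[, c("env", "EC")]
  set.seed(84)
  spat <- as.data.frame(pcnm_vectors(sim$metadata[, c("x", "y")]))
  vp <- dbrda_varpart(dm, env, spat, n_perm = 99, seed = 85)
  a <- vp$adjR2
  expect_equal(unname(a["pure_env"] + a["pure_spat"] + a["shared"]),
               unname(a["total"]), tolerance = 1e-9)
  expect_equal(unname(a["total"] + a["residual"]), 1, tolerance = 1e-9)
  # identical predictor sets: pure fractions vanish, shared = total
  vp2 <- dbrda_varpart(dm, env, env, n_perm = 99, seed = 86)
  expect_lt(abs(vp2$adjR2["pure_env"]), 0.02)
  expect_lt(abs(vp2$adjR2["pure_spat"]), 0.02)
  expect_equal(unname(vp2$adjR2["shared"]), unname(vp2$adjR2["total"]),
               tolerance = 0.03)
  # pure-noise spatial predictors explain ~nothing
  set.seed(87)
  noise <- data.frame(n1 = rnorm(24), n2 = rnorm(24))
  vp3 <- dbrda_varpart(dm, env, noise, n_perm = 99, seed = 88)
  expect_lt(vp3$adjR2["pure_spat"], 0.05)
})

test_that("db-RDA on one binary predictor reproduces the PERMANOVA partition", {
  sim <- simulate_niche_community(
    add_niche_traits(bench_meta(91), seed = 92),
    bench_design(93, regime = "niche"))
  dm <- bray_curtis(sim$table)
  bin <- data.frame(z = as.numeric(sim$metadata$environment ==
                                     "intertidal"))
  mod <- vegan::dbrda(dm ~ z, data = bin, sqrt.dist = FALSE)
  r2_dbrda <- mod$CCA$tot.chi / mod$tot.chi
  pv <- permanova(dm, bin, ~ z, n_perm = 49, seed = 94)
  expect_equal(r2_dbrda, pv$R2[1], tolerance = 1e-6)
})

test_that("forward selection finds planted predictors deterministically", {
  # response driven by two orthogonal gradients among pure noise; the
  # stronger gradient must enter first and the noise must stay out
  set.seed(98)
  n <- 40
  v1 <- rnorm(n); v2 <- rnorm(n)
  resp <- cbind(2 * v1 + 0.8 * v2 + rnorm(n, 0, 0.3),
                2 * v1 - 0.8 * v2 + rnorm(n, 0, 0.3))
  dm <- stats::dist(resp)
  cand <- data.frame(v1 = v1, v2 = v2, u1 = rnorm(n), u2 = rnorm(n))
  fs <- forward_select(dm, cand, seed = 99)
  expect_equal(fs$selected[1], "v1")
  # v2 may be blocked by the adjusted-R2 scope rule once the model is
  # near the global fit; the noise variables must never enter
  expect_false(any(c("u1", "u2") %in% fs$selected))
  expect_lte(fs$adj_r2, fs$global_adj_r2 + 1e-9)
  fs2 <- forward_select(dm, cand, seed = 99)
  expect_identical(fs$selected, fs2$selected)
})
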