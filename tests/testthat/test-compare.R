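test_that("Box-Cox MLE recovers known transforms", {
  set.seed(31)
  # log-normal data: lambda near 0
  x <- stats::rlnorm(1e4, 1, 0.6)
  expect_lt(abs(boxcox_fit(x)$lambda), 0.1)
  # already-normal positive data: lambda near 1
  y <- stats::rnorm(1e4, 50, 2)
  expect_lt(abs(boxcox_fit(y)$lambda - 1), 0.25)
})

test_that("Box-Cox agrees with an independent profile-likelihood grid", {
  skip_if_not_installed("MASS")
  set.seed(32)
  x <- stats::rgamma(2000, shape = 2, rate = 0.5)
  fit <- boxcox_fit(x)
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-1, 2, 0.01), plotit = FALSE)
  expect_lt(abs(fit$lambda - bc$x[which.max(bc$y)]), 0.02)
})

test_that("Box-Cox handles shifts and degenerate input", {
  x <- c(-3, -1, 0, 2, 5)
  fit <- boxcox_fit(x)
  expect_gt(fit$shift, 3)
  expect_true(all(x + fit$shift > 0))
  cst <- boxcox_fit(rep(4, 10))
  expect_true(cst$constant)
  expect_equal(cst$transformed, rep(4, 10))
  # cover: the transform domain must include the case value
  fit2 <- boxcox_fit(c(1, 2, 3), cover = -5)
  expect_gt(fit2$shift, 5)
})

test_that("z-score definition and degenerate flags", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(zscore(mean(v), v)$z, 0)
  expect_equal(zscore(mean(v) + 2 * stats::sd(v), v)$z, 2)
  r <- zscore(7, rep(7, 10))
  expect_equal(r$z, 0)
  expect_equal(r$flag, "by_construction")
  r2 <- zscore(8, rep(7, 10))
  expect_equal(r2$z, Inf)
  expect_equal(r2$flag, "degenerate_sd")
})

test_that("empirical p counts extremes in the deviation direction", {
  set.seed(5)
  v <- stats::rnorm(50000)
  # case at the control median: p about 0.5
  expect_lt(abs(empirical_pvalue(stats::median(v), v)$p - 0.5), 0.02)
  # exactly 3 controls more extreme out of 5e4
  v3 <- c(stats::runif(49997, 0, 1), 2, 3, 4)
  expect_equal(empirical_pvalue(1.5, v3)$p, 3 / 50000)
  # beyond all controls: reported as the resolution bound 1/K
  r <- empirical_pvalue(10, v3)
  expect_equal(r$p, 1 / 50000)
  expect_true(r$bound)
  # left tail counts low values
  expect_equal(empirical_pvalue(-0.5, c(-1, 0, 1, 2))$p, 1 / 4)
  # two-tailed counts absolute deviations
  vv <- c(-2, -1, 0, 1, 2)
  expect_equal(empirical_pvalue(1.5, vv, tail = "two")$p, 2 / 5)
  # degenerate: case equal to a constant control distribution
  rc <- empirical_pvalue(3, rep(3, 10))
  expect_equal(rc$p, 1)
  expect_equal(rc$flag, "by_construction")
})

test_that("p and transformed z are invariant under positive rescaling", {
  set.seed(8)
  v <- stats::rgamma(500, 3, 1)
  case <- 9
  r1 <- brainwcn:::bc_z_p(case, v, "one")
  r2 <- brainwcn:::bc_z_p(case * 100, v * 100, "one")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, r2$z, tolerance = 1e-5)
  # the empirical p is monotone-invariant outright
  r3 <- brainwcn:::bc_z_p(case^3, v^3, "one")
  expect_equal(r1$p, r3$p)
})

test_that("subsampling is deterministic and degenerates correctly", {
  cc <- small_cohort()
  s1 <- subsample_profiles(cc$control, M_sub = 30, K = 3, seed = 5)
  s2 <- subsample_profiles(cc$control, M_sub = 30, K = 3, seed = 5)
  expect_identical(s1$profiles, s2$profiles)
  s3 <- subsample_profiles(cc$control, M_sub = 30, K = 3, seed = 6)
  expect_false(identical(s1$profiles, s3$profiles))

  # full-size subsampling without replacement reproduces the full network
  n_ctrl <- nrow(cc$control$values)
  s4 <- subsample_profiles(cc$control, M_sub = n_ctrl, K = 2, seed = 5,
                           replace = FALSE)
  full <- centrality_profile(suppressWarnings(build_network(cc$control)))
  expect_equal(s4$profiles[1, , ], unclass(full), ignore_attr = TRUE)
  expect_equal(s4$profiles[2, , ], unclass(full), ignore_attr = TRUE)
})

test_that("whole-network stats average nodes within each repetition", {
  cc <- small_cohort()
  sub <- subsample_profiles(cc$control, M_sub = 30, K = 4, seed = 9)
  w <- whole_network_stats(sub$profiles)
  expect_equal(dim(w), c(4L, 12L))
  expect_equal(unname(w[2, "clustering"]),
               mean(sub$profiles[2, , "clustering"], na.rm = TRUE))
  # single profile: column means
  prof <- centrality_profile(suppressWarnings(build_network(cc$control)))
  w1 <- whole_network_stats(prof)
  expect_equal(unname(w1[1, "strength"]),
               mean(prof[, "strength"], na.rm = TRUE))
  # degree column is constant across repetitions (fixed link density)
  expect_equal(stats::sd(w[, "degree"]), 0)
})

test_that("single-node statistics equal a per-node loop recomputation", {
  cc <- small_cohort()
  sub <- subsample_profiles(cc$control, M_sub = 30, K = 10, seed = 13)
  case_prof <- centrality_profile(suppressWarnings(
    build_network(cc$case)))
  res <- single_node_stats(case_prof, sub, tail = "one")
  ids <- rownames(case_prof)
  for (i in c(1, 7, 20)) for (m in c("strength", "clustering")) {
    v <- sub$profiles[, i, m]
    cv <- case_prof[i, m]
    if (is.na(cv) || mean(is.na(v)) > 0.5) {
      expect_true(res$excluded[i, m])
      next
    }
    v <- v[!is.na(v)]
    fit <- boxcox_fit(v, cover = cv)
    z_exp <- zscore(brainwcn:::boxcox_apply(cv, fit), fit$transformed)$z
    p_exp <- empirical_pvalue(cv, v)$p
    expect_equal(res$z[i, m], z_exp, info = paste(i, m))
    expect_equal(res$p[i, m], p_exp, info = paste(i, m))
  }
  expect_error(single_node_stats(case_prof[-1, ], sub), "node sets")
})

test_that("comparison results are deterministic given seed and config", {
  cc <- small_cohort()
  c1 <- compare_groups(cc$case, cc$control, K = 8, seed = 3)
  c2 <- compare_groups(cc$case, cc$control, K = 8, seed = 3)
  expect_identical(c1$whole, c2$whole)
  expect_identical(c1$nodes$z, c2$nodes$z)
})

test_that("node rankings follow |z| with deterministic tie-breaks", {
  z <- matrix(0, 4, 12, dimnames = list(c("b", "a", "d", "c"),
                                        MEASURE_NAMES))
  z[, "clustering"] <- c(-3, 1, 3, -0.5)
  ns <- list(z = z, p = z * 0 + 0.5, p_bound = z == Inf,
             excluded = z == Inf)
  rk <- rank_nodes(ns, "clustering", k = 3)
  expect_equal(rk$feature_id, c("b", "d", "a"))
  expect_equal(rk$z, c(-3, 3, 1))   # sign retained
  expect_equal(rk$rank, 1:3)
  # all-zero column: ranked by feature id
  rk0 <- rank_nodes(ns, "degree", k = 10)
  expect_equal(rk0$feature_id, c("a", "b", "c", "d"))  # truncated to n
  # metadata annotation mirrors the feature table
  md <- parse_feature_name(c("lh_cuneus_volume"))
  z2 <- matrix(1, 1, 12, dimnames = list("lh_cuneus_volume",
                                         MEASURE_NAMES))
  rk2 <- rank_nodes(list(z = z2), "ipr", k = 1, metadata = md)
  expect_equal(rk2$hemisphere, "left")
  expect_equal(rk2$region, "cuneus")
  expect_equal(rk2$feature_measure, "volume")
})

test_that("centrality cluster map is a valid clustered correlation", {
  cc <- small_cohort()
  prof <- centrality_profile(suppressWarnings(build_network(cc$control)))
  cm <- centrality_cluster_map(prof, k = 4)
  expect_equal(dim(cm$correlation), c(12L, 12L))
  expect_true(isSymmetric(cm$correlation))
  expect_equal(unname(diag(cm$correlation)), rep(1, 12))
  expect_equal(length(unique(cm$labels)), 4L)
  # a duplicated measure pair is perfectly correlated, hence co-clustered
  dup <- cbind(prof, unclass(prof)[, "strength", drop = FALSE])
  colnames(dup)[13] <- "strength"
  r <- stats::cor(dup[, c(2, 13)], method = "spearman",
                  use = "pairwise.complete.obs")
  expect_equal(r[1, 2], 1)
  expect_equal(cm$labels[["degree"]], cm$labels[["strength"]])
})

test_that("comparison output files are written and reloadable", {
  cc <- small_cohort()
  cmp <- compare_groups(cc$case, cc$control, K = 6, seed = 3)
  d <- withr::local_tempdir()
  paths <- write_comparison(cmp, d)
  expect_true(all(file.exists(paths)))
  whole <- utils::read.csv(file.path(d, "whole_network.csv"))
  expect_equal(whole$measure, MEASURE_NAMES)
  expect_equal(whole$z[whole$measure == "degree"], 0)
  meta <- jsonlite::read_json(file.path(d, "run_metadata.json"))
  expect_equal(meta$K, 6)
  expect_equal(meta$mode, "single_case")
})
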