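rand_table <- function(nsub = 12, nfeat = 8, seed = 7) {
  set.seed(seed)
  matrix(stats::rnorm(nsub * nfeat), nsub,
         dimnames = list(paste0("s", seq_len(nsub)),
                         paste0("f", seq_len(nfeat))))
}

test_that("Spearman matrix equals the rank-then-Pearson oracle", {
  x <- rand_table()
  x[1:3, 2] <- x[4, 2]  # introduce ties
  got <- spearman_matrix(x)
  expect_s3_class(got, "correlation_matrix")
  expect_equal(got$rS, bf_spearman(x), tolerance = 1e-12)
  expect_true(isSymmetric(got$rS))
  expect_equal(unname(diag(got$rS)), rep(1, ncol(x)))
})

test_that("Spearman is invariant to monotone maps and flips sign", {
  x <- rand_table(nsub = 10, nfeat = 2)
  x[, 2] <- exp(x[, 1])           # monotone transform of feature 1
  expect_equal(spearman_matrix(x)$rS[1, 2], 1)
  x[, 2] <- -x[, 1]
  expect_equal(spearman_matrix(x)$rS[1, 2], -1)
})

test_that("degenerate inputs are rejected", {
  x <- rand_table()
  x[, 3] <- 5
  expect_error(spearman_matrix(x), "constant feature.*f3")
  expect_error(spearman_matrix(rand_table(nsub = 2)), "3 subjects")
})

test_that("quantile thresholding fixes the link density", {
  x <- rand_table(nsub = 30, nfeat = 20)
  corr <- spearman_matrix(x)
  th <- threshold_adjacency(corr, q = 0.85)
  n <- ncol(x); npairs <- n * (n - 1) / 2
  dens <- sum(th$A) / (n * (n - 1))
  expect_lte(abs(dens - 0.15), 1 / npairs)
  expect_true(isSymmetric(th$A))
  expect_equal(unname(diag(th$A)), rep(0, n))
})

test_that("thresholding selects exactly the top pairs", {
  # 5 nodes, 10 distinct off-diagonal values, q = 0.7 -> top 3 pairs
  set.seed(1)
  n <- 5
  rS <- diag(1, n)
  vals <- seq(-0.9, 0.9, length.out = 10)
  rS[upper.tri(rS)] <- sample(vals)
  rS[lower.tri(rS)] <- t(rS)[lower.tri(rS)]
  corr <- structure(list(rS = rS, feature_ids = paste0("f", 1:n)),
                    class = "correlation_matrix")
  th <- threshold_adjacency(corr, q = 0.7)
  expect_equal(sum(th$A) / 2, 3)
  # brute force: the 3 largest off-diagonal values are the linked pairs
  ut <- which(upper.tri(rS), arr.ind = TRUE)
  top <- ut[order(-rS[upper.tri(rS)])[1:3], , drop = FALSE]
  for (k in 1:3) expect_equal(th$A[top[k, 1], top[k, 2]], 1)

  # q near zero links essentially everything
  th0 <- threshold_adjacency(corr, q = 1e-6)
  expect_gte(sum(th0$A) / 2, 9)

  all_equal <- diag(1, 4); all_equal[upper.tri(all_equal)] <- 0.5
  all_equal[lower.tri(all_equal)] <- 0.5
  ce <- structure(list(rS = all_equal, feature_ids = paste0("f", 1:4)),
                  class = "correlation_matrix")
  expect_error(threshold_adjacency(ce), "degenerate")
})

test_that("chordal weights evaluate the closed form", {
  r <- c(1, -1, 0, 0.5)
  n <- length(r) + 1
  rS <- diag(1, n)
  rS[1, 2:n] <- r; rS[2:n, 1] <- r
  corr <- structure(list(rS = rS, feature_ids = paste0("f", 1:n)),
                    class = "correlation_matrix")
  A <- matrix(1, n, n) - diag(n)
  W <- chordal_weights(corr, A, sigma = 1)
  expect_equal(W[1, 2], 1)                      # r = 1 -> S = 0
  expect_equal(W[1, 3], exp(-1))                # r = -1 -> S = 1
  expect_equal(W[1, 4], exp(-1 / 2))            # r = 0 -> S = sqrt(2)/2
  expect_equal(W[1, 5], exp(-sin(acos(0.5) / 2)^2))
  # sigma rescales the kernel
  W2 <- chordal_weights(corr, A, sigma = 2)
  expect_equal(W2[1, 3], exp(-1 / 4))

  # monotone increasing in r at fixed sigma
  grid <- seq(-1, 1, by = 0.05)
  w <- exp(-sin(acos(grid) / 2)^2)
  expect_true(all(diff(w) > 0))

  bad <- corr; bad$rS[1, 2] <- 1.5; bad$rS[2, 1] <- 1.5
  expect_error(chordal_weights(bad, A), "outside")
})

test_that("build_network composes the stages coherently", {
  x <- rand_table(nsub = 25, nfeat = 15)
  net <- suppressWarnings(build_network(x, q = 0.8))
  expect_identical(net$W > 0, net$A == 1)
  expect_true(isSymmetric(net$W))
  expect_equal(unname(diag(net$W)), rep(0, 15))
  # weights reproduce the closed form on the source correlations
  idx <- which(net$A == 1, arr.ind = TRUE)[1, ]
  r <- net$corr$rS[idx[1], idx[2]]
  expect_equal(net$W[idx[1], idx[2]], exp(-sin(acos(r) / 2)^2))
})

test_that("networks are invariant to strictly monotone transforms", {
  x <- rand_table(nsub = 25, nfeat = 15)
  xf <- x
  transforms <- list(function(v) v^3, function(v) exp(v / 2),
                     function(v) 2 * v + 7, function(v) atan(v),
                     function(v) sinh(v))
  for (j in seq_len(ncol(x)))
    xf[, j] <- transforms[[(j %% 5) + 1]](x[, j])
  n1 <- suppressWarnings(build_network(x, q = 0.8))
  n2 <- suppressWarnings(build_network(xf, q = 0.8))
  expect_identical(n1$A, n2$A)
  expect_identical(n1$W, n2$W)
})

test_that("node-set selection drops normalizers and derived features", {
  cc <- small_cohort()
  net_aug <- suppressWarnings(build_network(cc$control))
  md_aug <- net_aug$metadata
  expect_false(any(md_aug$is_normalizer))
  expect_true(any(md_aug$hemisphere == "bilateral_avg"))
  net_base <- suppressWarnings(build_network(cc$control,
                                             node_set = "base"))
  expect_false(any(net_base$metadata$hemisphere %in%
                     c("bilateral_avg", "bilateral_asym")))
})

test_that("network export writes readable files", {
  x <- rand_table(nsub = 20, nfeat = 10)
  net <- suppressWarnings(build_network(x, q = 0.8))
  d <- withr::local_tempdir()
  paths <- export_network(net, d, prefix = "net")
  expect_true(all(file.exists(paths)))
  edges <- utils::read.delim(file.path(d, "net_edges.tsv"))
  expect_equal(nrow(edges), sum(net$A) / 2)
  expect_equal(edges$w, exp(-edges$S^2), tolerance = 1e-12)
  A2 <- as.matrix(Matrix::readMM(file.path(d, "net_adjacency.mtx")))
  expect_equal(unname(1 * A2), unname(net$A))
})
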