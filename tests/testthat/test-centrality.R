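test_that("every measure matches its brute-force oracle on tiny graphs", {
  lib <- graph_library()
  for (nm in names(lib)) {
    net <- lib[[nm]]
    ks <- degree_strength(net)
    expect_equal(ks$K, rowSums(net$A), info = nm, ignore_attr = TRUE)
    expect_equal(ks$S, rowSums(net$W), info = nm, ignore_attr = TRUE)

    nn <- nn_degree_strength(net)
    bf <- bf_nn(net)
    expect_equal(nn$Knn, bf$Knn, tolerance = 1e-9, info = nm,
                 ignore_attr = TRUE)
    expect_equal(nn$Snn, bf$Snn, tolerance = 1e-9, info = nm,
                 ignore_attr = TRUE)

    expect_equal(closeness_centrality(net, "topo"),
                 bf_closeness(net, "topo"), tolerance = 1e-9, info = nm,
                 ignore_attr = TRUE)
    expect_equal(closeness_centrality(net, "weighted"),
                 bf_closeness(net, "weighted"), tolerance = 1e-9,
                 info = nm, ignore_attr = TRUE)
    expect_equal(betweenness_centrality(net, "topo"),
                 bf_betweenness(net, "topo"), tolerance = 1e-9, info = nm,
                 ignore_attr = TRUE)
    expect_equal(betweenness_centrality(net, "weighted"),
                 bf_betweenness(net, "weighted"), tolerance = 1e-9,
                 info = nm, ignore_attr = TRUE)
    expect_equal(clustering_coefficient(net), bf_clustering(net),
                 tolerance = 1e-9, info = nm, ignore_attr = TRUE)
    expect_equal(inverse_participation_ratio(net), bf_ipr(net),
                 tolerance = 1e-9, info = nm, ignore_attr = TRUE)
  }
})

test_that("structural special cases come out exactly", {
  lib <- graph_library()
  # star: hub sees leaves of degree 1; each leaf sees the hub of degree 4
  knn <- nn_degree_strength(lib$star)$Knn
  expect_equal(unname(knn), c(1, 4, 4, 4, 4))
  # path a-b-c: CC(b) = 1, CC(a) = 2/3; BC(b) = 1, ends 0
  cc <- closeness_centrality(lib$p3, "topo")
  expect_equal(cc, c(2 / 3, 1, 2 / 3), ignore_attr = TRUE)
  bc <- betweenness_centrality(lib$p3, "topo")
  expect_equal(unname(bc), c(0, 1, 0))
  # complete graph: CC = 1 everywhere, BC = 0 everywhere
  expect_equal(closeness_centrality(lib$k5, "topo"), rep(1, 5),
               ignore_attr = TRUE)
  expect_equal(unname(betweenness_centrality(lib$k5, "topo")), rep(0, 5))
  # triangle: clustering 1; star hub: 0
  expect_equal(unname(clustering_coefficient(lib$triangle)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(lib$star))[1], 0)
})

test_that("spectral centrality matches the closed-form path eigenvector", {
  # P4 Fiedler vector: v_i = cos((i - 1/2) * pi / 4), eigenvalue
  # 2 - 2 cos(pi/4); SC_i computed directly from it
  net <- graph_library()$p4
  v <- cos((seq_len(4) - 0.5) * pi / 4)
  v <- v / sqrt(sum(v^2))
  L <- diag(rowSums(net$A)) - net$A
  expect_equal(unname(L %*% v), (2 - 2 * cos(pi / 4)) * v,
               tolerance = 1e-12, ignore_attr = TRUE)
  expected <- vapply(1:4, function(i)
    sum(net$A[i, ] * (v[i] - v)^2), 0)
  expect_equal(unname(spectral_centrality(net, "topo")), expected,
               tolerance = 1e-9)
})

test_that("spectral centrality symmetry and degeneracy handling", {
  lib <- graph_library()
  # complete graph: the Fiedler eigenvalue is degenerate; the
  # deterministic eigenvector choice is flagged with a warning and the
  # result is reproducible call to call
  expect_warning(sc1 <- spectral_centrality(lib$k5, "topo"), "degenerate")
  suppressWarnings(sc2 <- spectral_centrality(lib$k5, "topo"))
  expect_identical(sc1, sc2)
  # disconnected input is refused
  two <- as_net(as.matrix(Matrix::bdiag(matrix(1, 2, 2) - diag(2),
                                        matrix(1, 2, 2) - diag(2))))
  expect_error(spectral_centrality(two, "topo"), "disconnected")
})

test_that("IPR limits: uniform weights give 1/k, dominance gives ~1", {
  k <- 4
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  net <- as_net(star, star * 0.6)
  expect_equal(unname(inverse_participation_ratio(net))[1], 1 / k)
  dom <- star * 1e-6; dom[1, 2] <- dom[2, 1] <- 1
  netd <- as_net(star, dom)
  expect_gt(inverse_participation_ratio(netd)[1], 0.999)
  # isolated node is undefined
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_true(is.na(inverse_participation_ratio(as_net(iso))[3]))
})

test_that("uniform weights reduce weighted measures to topological ones", {
  net <- graph_library()$rand6
  c0 <- 0.37
  netu <- as_net(net$A, net$A * c0)
  expect_equal(closeness_centrality(netu, "weighted"),
               c0 * closeness_centrality(netu, "topo"),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(betweenness_centrality(netu, "weighted")),
               unname(betweenness_centrality(netu, "topo")),
               tolerance = 1e-9)
  nn <- nn_degree_strength(netu)
  expect_equal(nn$Snn, c0 * nn$Knn, tolerance = 1e-9)
  expect_equal(unname(inverse_participation_ratio(netu)),
               1 / unname(rowSums(netu$A)), tolerance = 1e-9)
})

test_that("profiles assemble all 12 measures with the missing-value policy", {
  net <- graph_library()$rand7a
  prof <- centrality_profile(net)
  expect_equal(colnames(prof), MEASURE_NAMES)
  expect_equal(nrow(prof), 7)
  expect_equal(sum(prof[, "degree"]), sum(net$A))
  expect_equal(sum(prof[, "strength"]), sum(net$W))
  # degree-1 nodes have undefined clustering
  k1 <- prof[, "degree"] == 1
  expect_true(all(is.na(prof[k1, "clustering"])))
  expect_equal(unname(attr(prof, "n_missing")["clustering"]), sum(k1))
})

test_that("profiles are equivariant under node relabeling", {
  net <- graph_library()$rand7b
  p <- sample(seq_len(7))
  A2 <- net$A[p, p]; W2 <- net$W[p, p]
  prof1 <- unclass(centrality_profile(net))
  prof2 <- unclass(centrality_profile(as_net(A2, W2)))
  expect_equal(prof2[order(p), ], prof1[rownames(prof1), ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("closeness on disconnected graphs uses per-component scaling", {
  A <- as.matrix(Matrix::bdiag(matrix(1, 3, 3) - diag(3),
                               matrix(1, 2, 2) - diag(2)))
  net <- as_net(A)
  cc <- closeness_centrality(net, "topo")
  expect_true(attr(cc, "disconnected"))
  # triangle component: reach 2 of 4, distances 1+1
  expect_equal(unname(cc[1]), (2 / 4) * (2 / 2))
  # pair component: reach 1 of 4, distance 1
  expect_equal(unname(cc[5]), (1 / 4) * (1 / 1))
})

test_that("spectral IPR variant is exposed and distinct", {
  net <- graph_library()$rand6
  y1 <- inverse_participation_ratio(net, "disparity")
  y2 <- inverse_participation_ratio(net, "spectral")
  expect_false(isTRUE(all.equal(y1, y2)))
  # per-node fourth powers of a unit-sum profile
  expect_equal(sum(y2), 1, tolerance = 1e-9)
  expect_true(all(y2 >= 0))
})
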