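# Brute-force oracles for the centrality measures, independent of both
# igraph and the package implementation: exhaustive simple-path
# enumeration for distances/betweenness, triple loops for triangles,
# rank-then-Pearson for Spearman. Usable only for tiny graphs (<= 7
# nodes), which is the point.

# wrap plain A/W matrices as a network object the centrality code accepts
as_net <- function(A, W = NULL, sigma = 1) {
  if (is.null(W)) W <- A
  if (is.null(dimnames(A)))
    dimnames(A) <- list(paste0("n", seq_len(nrow(A))),
                        paste0("n", seq_len(nrow(A))))
  dimnames(W) <- dimnames(A)
  structure(list(A = A, W = W, sigma = sigma, q = NA, threshold = NA,
                 density = sum(A) / (nrow(A) * (nrow(A) - 1)),
                 n_components = NA, metadata = NULL),
            class = "corr_network")
}

bf_spearman <- function(x) {
  r <- apply(x, 2L, rank)  # average ranks for ties
  n <- ncol(x)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- r[, i] - mean(r[, i]); b <- r[, j] - mean(r[, j])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  dimnames(out) <- list(colnames(x), colnames(x))
  out
}

# all simple paths between s and t over edge-length matrix len (Inf = no
# edge); returns minimal length and the list of minimal paths
bf_shortest <- function(len, s, t, tol = 1e-9) {
  n <- nrow(len)
  best <- Inf
  paths <- list()
  recurse <- function(node, visited, acc) {
    if (acc - best > tol) return()
    if (node == t) {
      if (acc < best - tol) {
        best <<- acc
        paths <<- list(visited)
      } else if (abs(acc - best) <= tol) {
        paths[[length(paths) + 1L]] <<- visited
      }
      return()
    }
    for (nb in seq_len(n)) {
      if (is.finite(len[node, nb]) && !(nb %in% visited))
        recurse(nb, c(visited, nb), acc + len[node, nb])
    }
  }
  recurse(s, s, 0)
  list(d = best, paths = paths)
}

edge_lengths <- function(net, mode) {
  if (mode == "topo") ifelse(net$A == 1, 1, Inf)
  else ifelse(net$A == 1, 1 / net$W, Inf)
}

bf_closeness <- function(net, mode = "topo") {
  len <- edge_lengths(net, mode)
  n <- nrow(len)
  vapply(seq_len(n), function(i) {
    d <- vapply(setdiff(seq_len(n), i),
                function(j) bf_shortest(len, i, j)$d, 0)
    reach <- sum(is.finite(d))
    if (reach == 0) return(0)
    (reach / (n - 1)) * (reach / sum(d[is.finite(d)]))
  }, 0)
}

bf_betweenness <- function(net, mode = "topo") {
  len <- edge_lengths(net, mode)
  n <- nrow(len)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    sp <- bf_shortest(len, s, t)
    if (!is.finite(sp$d)) next
    sigma <- length(sp$paths)
    for (i in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(sp$paths, function(p) i %in% p, TRUE))
      bc[i] <- bc[i] + through / sigma
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

bf_clustering <- function(net) {
  A <- net$A
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    tri / (k * (k - 1) / 2)
  }, 0)
}

bf_nn <- function(net) {
  A <- net$A
  K <- rowSums(A); S <- rowSums(net$W)
  n <- nrow(A)
  knn <- snn <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb)) {
      knn[i] <- mean(K[nb]); snn[i] <- mean(S[nb])
    }
  }
  list(Knn = knn, Snn = snn)
}

bf_ipr <- function(net) {
  S <- rowSums(net$W)
  vapply(seq_len(nrow(net$W)), function(i) {
    if (S[i] == 0) return(NA_real_)
    sum((net$W[i, ] / S[i])^2)
  }, 0)
}

# small library of connected test graphs (<= 7 nodes) with weights
graph_library <- function() {
  lib <- list()
  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
  path_A <- function(n) {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    A
  }
  lib$p3 <- as_net(path_A(3))
  lib$p4 <- as_net(path_A(4))
  tri <- matrix(1, 3, 3) - diag(3)
  lib$triangle <- as_net(tri, tri * 0.5)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  lib$star <- as_net(star)
  k5 <- matrix(1, 5, 5) - diag(5)
  lib$k5 <- as_net(k5)
  c5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; c5[i, j] <- c5[j, i] <- 1 }
  lib$c5 <- as_net(c5)
  # random connected weighted graphs, fixed seed
  set.seed(2024)
  for (nm in c("rand6", "rand7a", "rand7b")) {
    n <- if (nm == "rand6") 6 else 7
    repeat {
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.45)
      A <- sym(A)
      g_ok <- all(rowSums(A) > 0)
      if (g_ok) {
        # crude connectivity check by reachability
        reach <- (diag(n) + A) %*% (diag(n) + A) %*% (diag(n) + A) %*%
          (diag(n) + A) %*% (diag(n) + A) %*% (diag(n) + A)
        if (all(reach > 0)) break
      }
    }
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, 0.3, 1)
    W <- sym(W) * A
    lib[[nm]] <- as_net(A, W)
  }
  # equal-shortest-path graph: 4-cycle with uniform weights
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- c4[j, i] <- 1 }
  lib$c4 <- as_net(c4, c4 * 0.7)
  lib
}
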