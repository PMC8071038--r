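# Twelve node-centrality measures on a correlation network: degree and
# strength, nearest-neighbor degree/strength, topological and weighted
# closeness and betweenness, clustering coefficient, edge-weight disparity
# (inverse participation ratio), and topological/weighted spectral
# centrality from the Fiedler vector of the graph Laplacian.
#
# Conventions:
#  * weighted shortest paths use edge length 1/w by default (strong
#    similarity = short); "chordal" switches to the chordal distance S;
#  * betweenness is normalized by choose(N-1, 2), endpoints excluded;
#  * undefined values (clustering for K < 2, neighbor averages and
#    disparity for isolated nodes) are NA and excluded from averages.

#' Names of the twelve centrality measures
#' @export
MEASURE_NAMES <- c("degree", "strength", "nn_degree", "nn_strength",
                   "closeness", "w_closeness", "betweenness",
                   "w_betweenness", "clustering", "ipr",
                   "spectral", "w_spectral")

net_graphs <- function(net, weighted_distance = c("inverse", "chordal")) {
  weighted_distance <- match.arg(weighted_distance)
  g_topo <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
  gw <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                            weighted = TRUE)
  w <- igraph::E(gw)$weight
  len <- if (weighted_distance == "inverse") 1 / w else {
    # recover S from w = exp(-S^2 / sigma^2); zero-length edges (r = 1)
    # are nudged to a tiny positive length for path algorithms
    S2 <- -net$sigma^2 * log(pmin(w, 1))
    pmax(sqrt(pmax(S2, 0)), 1e-12)
  }
  igraph::E(gw)$length <- len
  list(topo = g_topo, weighted = gw)
}

#' Node degree and strength
#'
#' Row sums of the binary adjacency and of the weighted matrix.
#'
#' @param net a `corr_network`.
#' @return list with numeric vectors `K` (degree) and `S` (strength).
#' @export
degree_strength <- function(net) {
  list(K = rowSums(net$A), S = rowSums(net$W))
}

#' Average degree and strength of each node's nearest neighbors
#'
#' Unweighted arithmetic mean of `K` (resp. `S`) over the neighbors of each
#' node; NA for isolated nodes.
#'
#' @param net a `corr_network`.
#' @param K,S degree and strength vectors (computed if missing).
#' @return list with `Knn` and `Snn` vectors.
#' @export
nn_degree_strength <- function(net, K = NULL, S = NULL) {
  if (is.null(K) || is.null(S)) {
    ks <- degree_strength(net)
    K <- ks$K; S <- ks$S
  }
  denom <- ifelse(K > 0, K, NA_real_)
  list(Knn = as.vector(net$A %*% K) / denom,
       Snn = as.vector(net$A %*% S) / denom)
}

#' Closeness centrality
#'
#' `(N - 1) / sum_j d_ij` with hop-count distances (`mode = "topo"`) or
#' weighted shortest-path distances (`mode = "weighted"`). On disconnected
#' networks the Wasserman-Faust scaling is applied per component:
#' `(n_r - 1)/(N - 1) * (n_r - 1)/sum(d within component)`, where `n_r` is
#' the number of reachable nodes plus one; isolated nodes get 0. The
#' result carries `attr(, "disconnected")`.
#'
#' @param net a `corr_network`.
#' @param mode `"topo"` or `"weighted"`.
#' @param weighted_distance edge-length convention for weighted paths.
#' @return numeric vector of closeness values.
#' @export
closeness_centrality <- function(net, mode = c("topo", "weighted"),
                                 weighted_distance = c("inverse", "chordal")) {
  mode <- match.arg(mode)
  gs <- net_graphs(net, weighted_distance)
  g <- if (mode == "topo") gs$topo else gs$weighted
  wts <- if (mode == "topo") NA else igraph::E(g)$length
  D <- igraph::distances(g, weights = wts)
  diag(D) <- 0
  n <- nrow(D)
  finite <- is.finite(D)
  reach <- rowSums(finite) - 1   # reachable others
  tot <- rowSums(ifelse(finite, D, 0))
  disconnected <- any(!finite)
  cc <- ifelse(reach > 0, (reach / (n - 1)) * (reach / tot), 0)
  # connected case reduces exactly to (N-1)/sum d
  attr(cc, "disconnected") <- disconnected
  unname_keep_attr(cc, colnames(net$A))
}

unname_keep_attr <- function(x, nm) {
  names(x) <- nm
  x
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node (endpoints
#' excluded), normalized by `choose(N - 1, 2)` so values lie in `[0, 1]`.
#' Weighted mode counts shortest paths under the weighted edge length.
#'
#' @inheritParams closeness_centrality
#' @return numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net, mode = c("topo", "weighted"),
                                   weighted_distance = c("inverse",
                                                         "chordal")) {
  mode <- match.arg(mode)
  gs <- net_graphs(net, weighted_distance)
  g <- if (mode == "topo") gs$topo else gs$weighted
  wts <- if (mode == "topo") NULL else igraph::E(g)$length
  n <- igraph::vcount(g)
  bc <- igraph::betweenness(g, directed = FALSE, weights = wts)
  denom <- (n - 1) * (n - 2) / 2
  unname_keep_attr(as.numeric(bc) / denom, colnames(net$A))
}

#' Local clustering coefficient
#'
#' Fraction of pairs of a node's neighbors that are themselves linked:
#' `(A^3)_ii / 2` triangles over `choose(K_i, 2)` pairs. NA for nodes with
#' degree < 2, where the measure is undefined.
#'
#' @param net a `corr_network`.
#' @return numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(net) {
  gs <- igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
  cl <- igraph::transitivity(gs, type = "local", isolates = "NaN")
  cl[is.nan(cl)] <- NA_real_
  unname_keep_attr(as.numeric(cl), colnames(net$A))
}

# Fiedler vector of the combinatorial Laplacian D - M, with a fixed sign
# convention (first entry of largest magnitude made positive). Errors on
# disconnected graphs, where the second eigenvalue is still ~0 and the
# "first nontrivial" eigenvector is not defined.
fiedler_vector <- function(M) {
  n <- nrow(M)
  L <- diag(rowSums(M)) - M
  eig <- eigen(L, symmetric = TRUE)
  lambda <- rev(eig$values)          # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  tol <- max(1e-9, 1e-9 * max(abs(lambda)))
  if (n < 2L || lambda[2] <= tol)
    stop("graph is disconnected: Fiedler vector undefined; ",
         "restrict to a connected component")
  if (n >= 3L && abs(lambda[3] - lambda[2]) <= tol)
    warning("near-degenerate Fiedler eigenvalue; ",
            "eigenvector fixed by sign convention")
  v <- vecs[, 2]
  j <- which.max(abs(v))
  if (v[j] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Spectral centrality
#'
#' `SC_i = sum_j M_ij (v_i - v_j)^2` where `v` is the unit-norm Fiedler
#' vector (eigenvector of the second-smallest eigenvalue) of the
#' combinatorial Laplacian of `M`, with `M = A` (topological) or `M = W`
#' (weighted). Invariant under a global sign flip of `v`.
#'
#' @inheritParams closeness_centrality
#' @return numeric vector of spectral centralities.
#' @export
spectral_centrality <- function(net, mode = c("topo", "weighted")) {
  mode <- match.arg(mode)
  M <- if (mode == "topo") net$A else net$W
  v <- fiedler_vector(M)
  sc <- rowSums(M * outer(v, v, function(a, b) (a - b)^2))
  unname_keep_attr(sc, colnames(net$A))
}

#' Inverse participation ratio of edge weights (disparity)
#'
#' Concentration of a node's strength among its edges:
#' `Y_i = sum_j (W_ij / S_i)^2`, equal to `1/K_i` for uniform weights and
#' approaching 1 when one edge dominates. NA for nodes with zero strength.
#' `variant = "spectral"` instead returns the localization IPR of the
#' weighted Fiedler vector, `v_i^4 / (sum v^4)`-style per-node fourth
#' powers; the disparity form is the default interpretation.
#'
#' @param net a `corr_network`.
#' @param variant `"disparity"` (default) or `"spectral"`.
#' @return numeric vector of IPR values.
#' @export
inverse_participation_ratio <- function(net,
                                        variant = c("disparity",
                                                    "spectral")) {
  variant <- match.arg(variant)
  if (variant == "disparity") {
    S <- rowSums(net$W)
    denom <- ifelse(S > 0, S, NA_real_)
    y <- rowSums((net$W / denom)^2)
    return(unname_keep_attr(y, colnames(net$A)))
  }
  v <- fiedler_vector(net$W)
  unname_keep_attr(v^4 / sum(v^4), colnames(net$A))
}

#' Full centrality profile of a network
#'
#' Assembles all twelve measures into a node-by-measure matrix with columns
#' degree, strength, nn_degree, nn_strength, closeness, w_closeness,
#' betweenness, w_betweenness, clustering, ipr, spectral, w_spectral.
#' Undefined entries are NA;
#' their per-column counts are recorded in `attr(, "n_missing")`.
#'
#' @param net a `corr_network`.
#' @param weighted_distance edge-length convention for weighted paths.
#' @param ipr_variant IPR interpretation (see
#'   [inverse_participation_ratio()]).
#' @return numeric matrix (nodes x 12) of class `centrality_profile`.
#' @export
centrality_profile <- function(net,
                               weighted_distance = c("inverse", "chordal"),
                               ipr_variant = c("disparity", "spectral")) {
  weighted_distance <- match.arg(weighted_distance)
  ipr_variant <- match.arg(ipr_variant)
  ks <- degree_strength(net)
  nn <- nn_degree_strength(net, ks$K, ks$S)
  prof <- cbind(
    degree = ks$K,
    strength = ks$S,
    nn_degree = nn$Knn,
    nn_strength = nn$Snn,
    closeness = closeness_centrality(net, "topo"),
    w_closeness = closeness_centrality(net, "weighted", weighted_distance),
    betweenness = betweenness_centrality(net, "topo"),
    w_betweenness = betweenness_centrality(net, "weighted",
                                           weighted_distance),
    clustering = clustering_coefficient(net),
    ipr = inverse_participation_ratio(net, ipr_variant),
    spectral = spectral_centrality(net, "topo"),
    w_spectral = spectral_centrality(net, "weighted"))
  rownames(prof) <- colnames(net$A)
  attr(prof, "n_missing") <- colSums(is.na(prof))
  attr(prof, "conventions") <- list(weighted_distance = weighted_distance,
                                    ipr_variant = ipr_variant)
  class(prof) <- c("centrality_profile", class(prof))
  prof
}

#' Write a centrality profile as CSV with a JSON conventions sidecar
#'
#' @param profile a `centrality_profile`.
#' @param path CSV output path; conventions go to `<path>.meta.json`.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(feature_id = rownames(profile),
                   as.data.frame(unclass(profile)[, , drop = FALSE]))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  meta <- attr(profile, "conventions")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE)
  invisible(path)
}
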