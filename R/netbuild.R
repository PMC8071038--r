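# Weighted correlation network construction: Spearman matrix, quantile
# thresholding at fixed link density, chordal-distance edge weights.

#' Spearman correlation matrix of a feature table
#'
#' Pairwise Spearman rank correlation (average ranks for ties) across
#' subjects; the diagonal is forced to exactly 1. Because the downstream
#' pipeline is built on ranks, results are invariant to any strictly
#' monotone per-feature transform of the input.
#'
#' @param table a `feature_table`, or a subjects-by-features numeric matrix.
#' @return object of class `correlation_matrix`: list with `rS`
#'   (features x features) and `feature_ids`.
#' @export
spearman_matrix <- function(table) {
  vals <- if (inherits(table, "feature_table")) table$values else table
  stopifnot(is.matrix(vals), is.numeric(vals))
  if (nrow(vals) < 3L) stop("need at least 3 subjects")
  if (ncol(vals) < 2L) stop("need at least 2 features")
  const <- apply(vals, 2L, function(x) diff(range(x)) == 0)
  if (any(const))
    stop("constant feature(s), Spearman correlation undefined: ",
         paste(colnames(vals)[const], collapse = ", "))
  rS <- stats::cor(vals, method = "spearman")
  diag(rS) <- 1
  structure(list(rS = rS, feature_ids = colnames(vals)),
            class = "correlation_matrix")
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' The threshold is the empirical `q`-quantile (linear-interpolation
#' definition, `stats::quantile` type 7) of the signed off-diagonal
#' upper-triangle correlations; node pairs whose correlation strictly
#' exceeds it are linked. Self-loops are discarded. Because the point of
#' quantile thresholding is a link density fixed at `1 - q` for every
#' network, the number of links is made exact: when tied correlation
#' values straddle the quantile boundary (possible under subject
#' resampling, where duplicated subjects tie ranks), the tied pairs are
#' admitted in a deterministic order until the canonical count -- the
#' strictly-above count for distinct values -- is reached. With distinct
#' boundary values this rule coincides with the strict inequality.
#'
#' @param corr a `correlation_matrix`.
#' @param q quantile in (0, 1); default 0.85 fixes density at 0.15.
#' @return list with binary `A` (symmetric, zero diagonal) and the
#'   `threshold` used.
#' @export
threshold_adjacency <- function(corr, q = 0.85) {
  stopifnot(inherits(corr, "correlation_matrix"), q > 0, q < 1)
  rS <- corr$rS
  ut_mask <- upper.tri(rS)
  ut <- rS[ut_mask]
  if (diff(range(ut)) == 0)
    stop("degenerate correlation distribution: all off-diagonal values equal")
  thr <- unname(stats::quantile(ut, probs = q, type = 7))
  n_pairs <- length(ut)
  m <- n_pairs - floor((n_pairs - 1) * q + 1)   # fixed link count
  ord <- order(ut, seq_along(ut), decreasing = TRUE)
  sel <- ord[seq_len(m)]
  ut_idx <- which(ut_mask)
  A <- matrix(0, nrow(rS), ncol(rS), dimnames = dimnames(rS))
  A[ut_idx[sel]] <- 1
  A <- A + t(A)
  list(A = A, threshold = thr)
}

#' Chordal-distance edge weights
#'
#' For each linked pair the chordal distance
#' `S = sin(arccos(r) / 2)` maps the correlation `r` in `[-1, 1]` to
#' `[0, 1]`, and the weight is `w = exp(-S^2 / sigma^2)`. Weights are a
#' strictly increasing function of `r`: `w(1) = 1`, `w(0) = exp(-1/2)`,
#' `w(-1) = exp(-1)` at `sigma = 1`. Unlinked pairs get weight 0.
#'
#' @param corr a `correlation_matrix`.
#' @param A binary adjacency from [threshold_adjacency()].
#' @param sigma kernel width, > 0 (default 1).
#' @return weighted matrix `W` with the sparsity pattern of `A`.
#' @export
chordal_weights <- function(corr, A, sigma = 1) {
  stopifnot(inherits(corr, "correlation_matrix"), sigma > 0,
            identical(dim(A), dim(corr$rS)))
  rS <- corr$rS
  tol <- 1e-8
  if (any(abs(rS) > 1 + tol))
    stop("correlation values outside [-1, 1] beyond numeric tolerance")
  rS <- pmin(pmax(rS, -1), 1)
  S <- sin(acos(rS) / 2)
  W <- exp(-S^2 / sigma^2) * A
  dimnames(W) <- dimnames(rS)
  W
}

#' Build the binary and weighted correlation network for one group
#'
#' Composition of [spearman_matrix()], [threshold_adjacency()] and
#' [chordal_weights()]. Nodes default to the full feature set minus flagged
#' normalizer columns; `node_set = "base"` additionally drops the bilateral
#' average/asymmetry features.
#'
#' @param table a `feature_table` (or numeric matrix) for one subject group.
#' @param q threshold quantile (default 0.85).
#' @param sigma weight kernel width (default 1).
#' @param node_set `"augmented"` (all non-normalizer features) or `"base"`
#'   (drop bilateral_avg/bilateral_asym features as well).
#' @return object of class `corr_network`: list with `A`, `W`, `corr`
#'   (the source `correlation_matrix`), `threshold`, `q`, `sigma`,
#'   `density`, `n_components`, `metadata` (when available).
#' @export
build_network <- function(table, q = 0.85, sigma = 1,
                          node_set = c("augmented", "base")) {
  node_set <- match.arg(node_set)
  md <- NULL
  if (inherits(table, "feature_table")) {
    md <- table$metadata
    keep <- !md$is_normalizer & md$category != "normalizer"
    if (node_set == "base")
      keep <- keep & !(md$hemisphere %in% c("bilateral_avg",
                                            "bilateral_asym"))
    table <- ft_select_features(table, md$feature_id[keep])
    md <- table$metadata
  }
  corr <- spearman_matrix(table)
  th <- threshold_adjacency(corr, q = q)
  W <- chordal_weights(corr, th$A, sigma = sigma)
  n <- nrow(th$A)
  dens <- sum(th$A) / (n * (n - 1))
  g <- igraph::graph_from_adjacency_matrix(th$A, mode = "undirected")
  ncomp <- igraph::count_components(g)
  if (ncomp > 1L)
    warning("thresholded network has ", ncomp, " connected components")
  structure(list(A = th$A, W = W, corr = corr, threshold = th$threshold,
                 q = q, sigma = sigma, density = dens,
                 n_components = ncomp, metadata = md),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("corr_network:", nrow(x$A), "nodes,", sum(x$A) / 2, "links",
      sprintf("(density %.4f, q = %.3f, sigma = %g)\n",
              x$density, x$q, x$sigma))
  cat("  threshold rS >", format(x$threshold), "; components:",
      x$n_components, "\n")
  invisible(x)
}

#' Export a network as edge list, adjacency and node table
#'
#' Writes a weighted edge-list TSV (`i`, `j`, `rS`, `S`, `w`), the binary
#' adjacency in MatrixMarket format, a node table CSV with metadata, and a
#' GraphML file for external viewers.
#'
#' @param net a `corr_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- colnames(net$A)
  ut <- which(upper.tri(net$A) & net$A == 1, arr.ind = TRUE)
  r <- net$corr$rS[ut]
  edges <- data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
                      rS = r, S = sin(acos(pmin(pmax(r, -1), 1)) / 2),
                      w = net$W[ut])
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(edges, p_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_mtx <- file.path(dir, paste0(prefix, "_adjacency.mtx"))
  Matrix::writeMM(Matrix::Matrix(net$A, sparse = TRUE), p_mtx)
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.csv"))
  nodes <- if (!is.null(net$metadata)) net$metadata else
    data.frame(feature_id = ids)
  utils::write.csv(nodes, p_nodes, row.names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE)
  p_gml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(g, p_gml, format = "graphml")
  invisible(c(p_edges, p_mtx, p_nodes, p_gml))
}
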