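# Subsampling null engine and case-vs-control statistics.
#
# The case group is summarized by a single network built from all its
# subjects; the control group by a distribution of networks built from K
# subject subsamples of size M_sub (with replacement by default). Whole-
# network and single-node centrality values of the case are z-scored
# against the Box-Cox-regularized control distribution, with one-tailed
# empirical p-values counted in the direction of the case's deviation.

#' Centrality profiles of subsampled-group networks
#'
#' Draws `K` subject subsamples of size `M_sub`, builds a correlation
#' network from each and computes its centrality profile. Repetitions in
#' which the profile cannot be computed (e.g. the thresholded network
#' fragments, leaving the Fiedler vector undefined) are logged and
#' redrawn; their count is reported. Deterministic given `seed`.
#'
#' @param table `feature_table` (or numeric matrix) for one subject group.
#' @param M_sub subjects per subsample (at most the group size when
#'   `replace = FALSE`).
#' @param K number of repetitions.
#' @param seed integer seed.
#' @param replace draw subjects with replacement (default TRUE).
#' @param q,sigma,node_set network construction parameters, see
#'   [build_network()].
#' @param weighted_distance,ipr_variant centrality conventions, see
#'   [centrality_profile()].
#' @return list with `profiles` (K x nodes x 12 array), `feature_ids`,
#'   `n_failed` (redrawn repetitions), and the plan parameters.
#' @export
subsample_profiles <- function(table, M_sub, K, seed = 1, replace = TRUE,
                               q = 0.85, sigma = 1,
                               node_set = c("augmented", "base"),
                               weighted_distance = c("inverse", "chordal"),
                               ipr_variant = c("disparity", "spectral")) {
  node_set <- match.arg(node_set)
  weighted_distance <- match.arg(weighted_distance)
  ipr_variant <- match.arg(ipr_variant)
  vals <- if (inherits(table, "feature_table")) table$values else table
  n_subj <- nrow(vals)
  stopifnot(K >= 1L, M_sub >= 3L, replace || M_sub <= n_subj)
  set.seed(seed)
  arr <- NULL
  ids <- NULL
  n_failed <- 0L
  k <- 1L
  max_attempts <- 10L * K
  attempts <- 0L
  while (k <= K) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("too many failed subsampling repetitions (",
           n_failed, " failures)")
    idx <- sample.int(n_subj, M_sub, replace = replace)
    prof <- tryCatch({
      sub <- if (inherits(table, "feature_table")) {
        out <- table; out$values <- vals[idx, , drop = FALSE]
        rownames(out$values) <- paste0("rep", seq_along(idx))
        out
      } else vals[idx, , drop = FALSE]
      net <- suppressWarnings(build_network(sub, q = q, sigma = sigma,
                                            node_set = node_set))
      centrality_profile(net, weighted_distance, ipr_variant)
    }, error = function(e) e)
    if (inherits(prof, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(arr)) {
      ids <- rownames(prof)
      arr <- array(NA_real_, dim = c(K, length(ids), 12L),
                   dimnames = list(NULL, ids, MEASURE_NAMES))
    }
    arr[k, , ] <- unclass(prof)
    k <- k + 1L
  }
  list(profiles = arr, feature_ids = ids, n_failed = n_failed,
       plan = list(M_sub = M_sub, K = K, seed = seed, replace = replace,
                   q = q, sigma = sigma, node_set = node_set,
                   weighted_distance = weighted_distance,
                   ipr_variant = ipr_variant))
}

#' Whole-network centrality distributions
#'
#' For each of the 12 measures, the node-average centrality of every
#' repetition (undefined node values excluded from the average).
#'
#' @param profiles K x nodes x 12 array from [subsample_profiles()], or a
#'   single `centrality_profile` matrix.
#' @return K x 12 matrix of node-averaged centralities.
#' @export
whole_network_stats <- function(profiles) {
  if (inherits(profiles, "centrality_profile") ||
      (is.matrix(profiles) && length(dim(profiles)) == 2L))
    return(matrix(colMeans(profiles, na.rm = TRUE), nrow = 1,
                  dimnames = list(NULL, colnames(profiles))))
  apply(profiles, c(1L, 3L), mean, na.rm = TRUE)
}

#' Box-Cox transform by maximum likelihood
#'
#' Fits the power-transform parameter lambda by profile maximum likelihood
#' on `values`. When the minimum of `values` (or of `cover`, additional
#' points the fitted transform must be applicable to) is non-positive, an
#' automatic shift of `-min + epsilon` is applied first and recorded.
#' Constant input yields an identity transform with `lambda = NA` and
#' `constant = TRUE`.
#'
#' @param values numeric vector (the control distribution).
#' @param cover additional values the transform domain must cover (e.g.
#'   the case value); not used in fitting lambda.
#' @param lambda_range search interval for lambda.
#' @return list with `lambda`, `shift`, `transformed` (transformed
#'   `values`), and `constant`.
#' @export
boxcox_fit <- function(values, cover = numeric(0),
                       lambda_range = c(-5, 5)) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  all_v <- c(values, cover)
  shift <- 0
  if (min(all_v) <= 0)
    shift <- -min(all_v) + 1e-6 * max(diff(range(all_v)), 1)
  if (diff(range(values)) == 0)
    return(list(lambda = NA_real_, shift = shift, transformed = values,
                constant = TRUE))
  y <- values + shift
  n <- length(y)
  slog <- sum(log(y))
  loglik <- function(lambda) {
    yt <- boxcox_transform(y, lambda)
    v <- stats::var(yt) * (n - 1) / n
    -n / 2 * log(v) + (lambda - 1) * slog
  }
  opt <- stats::optimize(loglik, interval = lambda_range, maximum = TRUE)
  lambda <- opt$maximum
  list(lambda = lambda, shift = shift,
       transformed = boxcox_transform(y, lambda), constant = FALSE)
}

#' Apply a Box-Cox transform
#' @param x positive numeric vector.
#' @param lambda transform parameter; `log(x)` at `lambda = 0`.
#' @return transformed vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

# transform new values with a previously fitted transform
boxcox_apply <- function(x, fit) {
  if (fit$constant) return(x)
  y <- x + fit$shift
  if (any(y <= 0)) {
    # outside the fitted domain: clamp to a tiny positive value and flag
    y <- pmax(y, 1e-12)
  }
  boxcox_transform(y, fit$lambda)
}

#' z-score of a case value against a control distribution
#'
#' `(c_case - mean(controls)) / sd(controls)`. When the control standard
#' deviation is zero the value is 0 with flag `"by_construction"` if the
#' numerator is also zero, otherwise signed infinity with flag
#' `"degenerate_sd"`.
#'
#' @param case_value scalar.
#' @param control_values numeric vector.
#' @return list with `z` and `flag` (`""` when unremarkable).
#' @export
zscore <- function(case_value, control_values) {
  m <- mean(control_values)
  s <- stats::sd(control_values)
  if (length(control_values) < 2L || s == 0) {
    d <- case_value - m
    if (d == 0) return(list(z = 0, flag = "by_construction"))
    return(list(z = sign(d) * Inf, flag = "degenerate_sd"))
  }
  list(z = (case_value - m) / s, flag = "")
}

#' Empirical p-value of a case value under a control distribution
#'
#' Counts the control values more extreme than the case value. One-tailed
#' (default): extremeness is measured in the direction of the case's
#' deviation from the control mean. Two-tailed: absolute deviation from
#' the control mean. A zero count is reported as the resolution bound
#' `p = 1/K` with `bound = TRUE` (read "p < 1/K"). A case value exactly at
#' the control mean of a degenerate (constant) distribution yields `p = 1`
#' flagged `"by_construction"`.
#'
#' @param case_value scalar.
#' @param control_values numeric vector of K null values.
#' @param tail `"one"` or `"two"`.
#' @return list with `p`, `bound` (logical), and `flag`.
#' @export
empirical_pvalue <- function(case_value, control_values,
                             tail = c("one", "two")) {
  tail <- match.arg(tail)
  K <- length(control_values)
  m <- mean(control_values)
  d <- case_value - m
  if (d == 0 && stats::sd(control_values) %in% c(0, NA)) {
    return(list(p = 1, bound = FALSE, flag = "by_construction"))
  }
  count <- if (tail == "two") {
    sum(abs(control_values - m) > abs(d))
  } else if (d > 0) {
    sum(control_values > case_value)
  } else if (d < 0) {
    sum(control_values < case_value)
  } else {
    sum(abs(control_values - m) > 0)  # d == 0, non-degenerate: ~everything
  }
  if (count == 0L)
    list(p = 1 / K, bound = TRUE, flag = "")
  else
    list(p = count / K, bound = FALSE, flag = "")
}

# shared kernel: Box-Cox regularized z and empirical p of one case value
# against one control vector (raw scale in, transformed-scale z out; the
# empirical p is rank-based and unaffected by the monotone transform)
bc_z_p <- function(case_value, control_values, tail) {
  fit <- boxcox_fit(control_values, cover = case_value)
  zt <- zscore(boxcox_apply(case_value, fit), fit$transformed)
  pv <- empirical_pvalue(case_value, control_values, tail)
  list(z = zt$z, z_flag = zt$flag, p = pv$p, p_bound = pv$bound,
       p_flag = pv$flag, lambda = fit$lambda, shift = fit$shift,
       ctrl_mean = mean(control_values), ctrl_sd = stats::sd(control_values))
}

#' Whole-network comparison of a case profile against subsampled controls
#'
#' @param case_profile `centrality_profile` of the case network.
#' @param control `subsample_profiles()` result (or a K x nodes x 12 array).
#' @param tail p-value sidedness, see [empirical_pvalue()].
#' @return data.frame, one row per measure: case value, control mean/sd,
#'   Box-Cox lambda, z, p, bound and flags.
#' @export
compare_whole_network <- function(case_profile, control,
                                  tail = c("one", "two")) {
  tail <- match.arg(tail)
  arr <- if (is.list(control)) control$profiles else control
  ctrl <- whole_network_stats(arr)
  case_avg <- colMeans(case_profile, na.rm = TRUE)
  rows <- lapply(MEASURE_NAMES, function(m) {
    r <- bc_z_p(case_avg[[m]], ctrl[, m], tail)
    data.frame(measure = m, case_value = case_avg[[m]],
               ctrl_mean = r$ctrl_mean, ctrl_sd = r$ctrl_sd,
               lambda = r$lambda, z = r$z, p = r$p,
               p_bound = r$p_bound,
               flag = if (nzchar(r$z_flag)) r$z_flag else r$p_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-node comparison of a case profile against subsampled controls
#'
#' Applies the Box-Cox z-score and empirical p-value per node and measure.
#' Node/measure cells whose control values are missing in more than
#' `max_missing` of the repetitions, or whose case value is undefined, are
#' excluded (NA) and counted.
#'
#' @inheritParams compare_whole_network
#' @param max_missing tolerated fraction of missing control repetitions.
#' @return list with matrices `z`, `p`, `p_bound`, `excluded` (nodes x 12)
#'   and the per-measure exclusion counts.
#' @export
single_node_stats <- function(case_profile, control,
                              tail = c("one", "two"), max_missing = 0.5) {
  tail <- match.arg(tail)
  arr <- if (is.list(control)) control$profiles else control
  ids <- dimnames(arr)[[2]]
  if (!identical(ids, rownames(case_profile)))
    stop("node sets of case profile and control profiles differ")
  n <- length(ids)
  z <- p <- matrix(NA_real_, n, 12L, dimnames = list(ids, MEASURE_NAMES))
  pb <- excl <- matrix(FALSE, n, 12L, dimnames = list(ids, MEASURE_NAMES))
  for (m in seq_len(12L)) {
    for (i in seq_len(n)) {
      v <- arr[, i, m]
      cv <- case_profile[i, m]
      na_frac <- mean(is.na(v))
      if (is.na(cv) || na_frac > max_missing) {
        excl[i, m] <- TRUE
        next
      }
      v <- v[!is.na(v)]
      r <- bc_z_p(cv, v, tail)
      z[i, m] <- r$z
      p[i, m] <- r$p
      pb[i, m] <- r$p_bound
    }
  }
  list(z = z, p = p, p_bound = pb, excluded = excl,
       n_excluded = colSums(excl))
}

#' Top-k node ranking by absolute z-score
#'
#' Ranks nodes for one measure by `|z|` (sign retained in the output),
#' tie-broken by feature ID, and formats the result with the feature's
#' hemisphere, region and measure kind when metadata is available.
#'
#' @param node_stats result of [single_node_stats()], or a comparison
#'   result containing one.
#' @param measure one of the 12 measure names.
#' @param k number of rows (truncated at the node count).
#' @param metadata optional feature metadata for annotation.
#' @return data.frame with columns rank, hemisphere, region,
#'   feature_measure, feature_id, z.
#' @export
rank_nodes <- function(node_stats, measure, k = 5L, metadata = NULL) {
  if (!is.null(node_stats$nodes)) {
    if (is.null(metadata)) metadata <- node_stats$metadata
    node_stats <- node_stats$nodes
  }
  stopifnot(measure %in% MEASURE_NAMES)
  zs <- node_stats$z[, measure]
  ids <- rownames(node_stats$z)
  keep <- !is.na(zs)
  ids <- ids[keep]; zs <- zs[keep]
  ord <- order(-abs(zs), ids)
  k <- min(k, length(ord))
  sel <- ord[seq_len(k)]
  out <- data.frame(rank = seq_len(k), hemisphere = NA_character_,
                    region = ids[sel], feature_measure = NA_character_,
                    feature_id = ids[sel], z = zs[sel],
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    mi <- match(out$feature_id, metadata$feature_id)
    ok <- !is.na(mi)
    out$hemisphere[ok] <- metadata$hemisphere[mi[ok]]
    out$region[ok] <- metadata$region[mi[ok]]
    out$feature_measure[ok] <- metadata$measure[mi[ok]]
  }
  rownames(out) <- NULL
  out
}

#' Cross-correlation cluster map of the centrality measures
#'
#' Spearman correlation between the node-value vectors of the 12 measures
#' (pairwise-complete over undefined entries), turned into a distance
#' `1 - r` and clustered by average-linkage hierarchical clustering.
#'
#' @param profile node-by-measure matrix: a single `centrality_profile` or
#'   the repetition-averaged control profile.
#' @param k number of clusters to cut the dendrogram into (default 4).
#' @return list with the 12 x 12 `correlation` matrix, the `hclust` tree,
#'   cluster `labels`, and the dendrogram `order`.
#' @export
centrality_cluster_map <- function(profile, k = 4L) {
  m <- unclass(profile)[, MEASURE_NAMES, drop = FALSE]
  r <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  if (anyNA(r))
    warning("cluster map has undefined correlations (constant measure?)")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = min(k, ncol(m)))
  list(correlation = r, hclust = hc, labels = labels, order = hc$order)
}

# repetition-averaged control profile (nodes x 12)
mean_profile <- function(control) {
  arr <- if (is.list(control)) control$profiles else control
  apply(arr, c(2L, 3L), mean, na.rm = TRUE)
}

#' Compare a case group against a control group
#'
#' Full comparison engine. In `"single_case"` mode (the primary analysis)
#' the case group is represented by one network built from all its
#' subjects and the control group by `K` subsampled networks of `M_sub`
#' subjects each. In `"both"` mode both groups are subsampled and the
#' z-score contrasts the two distributions,
#' `z = (mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2)`;
#' the engine is otherwise symmetric.
#'
#' @param case_table,control_table `feature_table`s (or numeric matrices)
#'   restricted to the two groups.
#' @param M_sub subsample size; defaults to the case group size
#'   (single-case mode) or the smaller group size (both mode).
#' @param K repetitions.
#' @param seed integer seed (controls all resampling).
#' @param mode `"single_case"` or `"both"`.
#' @param tail p-value sidedness.
#' @param replace subject resampling with replacement.
#' @param q,sigma,node_set,weighted_distance,ipr_variant see
#'   [build_network()] and [centrality_profile()].
#' @param max_missing see [single_node_stats()].
#' @return object of class `wcn_comparison`: list with `whole` (per-measure
#'   table), `nodes` (per-node matrices), `case_profile`,
#'   `ctrl_mean_profile`, `metadata`, `plan`, `n_failed`, `mode`, `tail`.
#' @export
compare_groups <- function(case_table, control_table, M_sub = NULL,
                           K = 200L, seed = 1L,
                           mode = c("single_case", "both"),
                           tail = c("one", "two"), replace = TRUE,
                           q = 0.85, sigma = 1,
                           node_set = c("augmented", "base"),
                           weighted_distance = c("inverse", "chordal"),
                           ipr_variant = c("disparity", "spectral"),
                           max_missing = 0.5) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  node_set <- match.arg(node_set)
  weighted_distance <- match.arg(weighted_distance)
  ipr_variant <- match.arg(ipr_variant)
  n_case <- if (inherits(case_table, "feature_table"))
    nrow(case_table$values) else nrow(case_table)
  n_ctrl <- if (inherits(control_table, "feature_table"))
    nrow(control_table$values) else nrow(control_table)
  if (is.null(M_sub))
    M_sub <- if (mode == "single_case") n_case else min(n_case, n_ctrl)

  ctrl <- subsample_profiles(control_table, M_sub = M_sub, K = K,
                             seed = seed, replace = replace, q = q,
                             sigma = sigma, node_set = node_set,
                             weighted_distance = weighted_distance,
                             ipr_variant = ipr_variant)
  n_failed <- ctrl$n_failed

  if (mode == "single_case") {
    case_net <- suppressWarnings(build_network(case_table, q = q,
                                               sigma = sigma,
                                               node_set = node_set))
    case_profile <- centrality_profile(case_net, weighted_distance,
                                       ipr_variant)
    md <- case_net$metadata
    whole <- compare_whole_network(case_profile, ctrl, tail)
    nodes <- single_node_stats(case_profile, ctrl, tail, max_missing)
  } else {
    case_sub <- subsample_profiles(case_table, M_sub = M_sub, K = K,
                                   seed = seed + 1L, replace = replace,
                                   q = q, sigma = sigma,
                                   node_set = node_set,
                                   weighted_distance = weighted_distance,
                                   ipr_variant = ipr_variant)
    n_failed <- n_failed + case_sub$n_failed
    md <- if (inherits(case_table, "feature_table")) {
      keep <- !case_table$metadata$is_normalizer &
        case_table$metadata$category != "normalizer"
      if (node_set == "base")
        keep <- keep & !(case_table$metadata$hemisphere %in%
                           c("bilateral_avg", "bilateral_asym"))
      case_table$metadata[keep, ]
    } else NULL
    whole <- compare_two_distributions(case_sub, ctrl, tail)
    nodes <- single_node_two_distributions(case_sub, ctrl, tail,
                                           max_missing)
    case_profile <- mean_profile(case_sub)
  }

  structure(list(whole = whole, nodes = nodes,
                 case_profile = case_profile,
                 ctrl_mean_profile = mean_profile(ctrl),
                 metadata = md, plan = ctrl$plan, n_failed = n_failed,
                 mode = mode, tail = tail),
            class = "wcn_comparison")
}

# whole-network contrast of two subsampled distributions (appendix-style
# symmetric analysis): z from the transformed means and pooled sd
compare_two_distributions <- function(case_sub, ctrl_sub, tail) {
  case_w <- whole_network_stats(case_sub$profiles)
  ctrl_w <- whole_network_stats(ctrl_sub$profiles)
  rows <- lapply(MEASURE_NAMES, function(m) {
    cv <- case_w[, m]; tv <- ctrl_w[, m]
    fit <- boxcox_fit(tv, cover = cv)
    ct <- fit$transformed
    at <- boxcox_apply(cv, fit)
    s <- sqrt(stats::sd(at)^2 + stats::sd(ct)^2)
    d <- mean(at) - mean(ct)
    flag <- ""
    z <- if (is.na(s) || s == 0) {
      flag <- if (d == 0) "by_construction" else "degenerate_sd"
      if (d == 0) 0 else sign(d) * Inf
    } else d / s
    pv <- empirical_pvalue(mean(cv), tv, tail)
    data.frame(measure = m, case_value = mean(cv), ctrl_mean = mean(tv),
               ctrl_sd = stats::sd(tv), lambda = fit$lambda, z = z,
               p = pv$p, p_bound = pv$bound,
               flag = if (nzchar(flag)) flag else pv$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

single_node_two_distributions <- function(case_sub, ctrl_sub, tail,
                                          max_missing) {
  ca <- case_sub$profiles
  ta <- ctrl_sub$profiles
  ids <- dimnames(ta)[[2]]
  n <- length(ids)
  z <- p <- matrix(NA_real_, n, 12L, dimnames = list(ids, MEASURE_NAMES))
  pb <- excl <- matrix(FALSE, n, 12L, dimnames = list(ids, MEASURE_NAMES))
  for (m in seq_len(12L)) {
    for (i in seq_len(n)) {
      cv <- ca[, i, m]; tv <- ta[, i, m]
      if (mean(is.na(cv)) > max_missing || mean(is.na(tv)) > max_missing) {
        excl[i, m] <- TRUE
        next
      }
      cv <- cv[!is.na(cv)]; tv <- tv[!is.na(tv)]
      fit <- boxcox_fit(tv, cover = cv)
      at <- boxcox_apply(cv, fit); ct <- fit$transformed
      s <- sqrt(stats::sd(at)^2 + stats::sd(ct)^2)
      d <- mean(at) - mean(ct)
      z[i, m] <- if (is.na(s) || s == 0) {
        if (d == 0) 0 else sign(d) * Inf
      } else d / s
      pv <- empirical_pvalue(mean(cv), tv, tail)
      p[i, m] <- pv$p
      pb[i, m] <- pv$bound
    }
  }
  list(z = z, p = p, p_bound = pb, excluded = excl,
       n_excluded = colSums(excl))
}

#' @export
print.wcn_comparison <- function(x, ...) {
  cat("wcn_comparison (", x$mode, " mode, ", x$tail, "-tailed)\n", sep = "")
  cat("  K =", x$plan$K, " M_sub =", x$plan$M_sub, " q =", x$plan$q,
      " sigma =", x$plan$sigma, "\n")
  if (x$n_failed > 0) cat("  redrawn repetitions:", x$n_failed, "\n")
  w <- x$whole
  w$z <- round(w$z, 3)
  print(w[, c("measure", "z", "p", "p_bound", "flag")], row.names = FALSE)
  invisible(x)
}

#' Write comparison results as CSV + JSON metadata
#'
#' @param result a `wcn_comparison`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_comparison <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_whole <- file.path(dir, "whole_network.csv")
  utils::write.csv(result$whole, p_whole, row.names = FALSE)
  nz <- result$nodes$z
  long <- data.frame(
    feature_id = rep(rownames(nz), times = ncol(nz)),
    measure = rep(colnames(nz), each = nrow(nz)),
    z = as.vector(nz), p = as.vector(result$nodes$p),
    p_bound = as.vector(result$nodes$p_bound),
    excluded = as.vector(result$nodes$excluded))
  p_nodes <- file.path(dir, "single_node.csv")
  utils::write.csv(long, p_nodes, row.names = FALSE)
  p_meta <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(c(result$plan,
                         list(mode = result$mode, tail = result$tail,
                              n_failed = result$n_failed)),
                       p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(p_whole, p_nodes, p_meta))
}
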