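# End-to-end orchestration: ingest -> select cohort -> normalize/augment ->
# build networks -> centrality -> subsampled comparison -> report bundle.

#' Run the full structural-covariance comparison pipeline
#'
#' Reads (or accepts) a raw feature table and phenotype table, selects the
#' cohort, normalizes and augments the features, builds the case and
#' control networks, runs the subsampled comparison and writes a result
#' bundle: network exports, centrality profiles, whole-network and
#' single-node statistics, top-k node tables for selected measures, the
#' centrality cluster map, and a JSON run-configuration record.
#'
#' @param features a `feature_table`, or character paths to FreeSurfer
#'   stats tables for [read_freesurfer_tables()].
#' @param pheno phenotype data.frame, or a CSV path for
#'   [read_phenotype()].
#' @param out_dir output directory; NULL skips all file output.
#' @param criteria cohort selection criteria (see [select_cohort()]).
#' @param augment append bilateral average/asymmetry features.
#' @param top_k rows in the per-measure node-ranking tables.
#' @param rank_measures measures to rank nodes for.
#' @param ... comparison parameters passed to [compare_groups()]
#'   (`M_sub`, `K`, `seed`, `mode`, `tail`, `q`, `sigma`, `node_set`, ...).
#' @return list with the prepared `table`, the cohort `selection`, the
#'   `comparison` (a `wcn_comparison`), the `cluster_map`, the `rankings`,
#'   and the age `balance` check.
#' @export
run_pipeline <- function(features, pheno, out_dir = NULL,
                         criteria = list(), augment = TRUE, top_k = 5L,
                         rank_measures = c("betweenness", "clustering",
                                           "ipr", "w_spectral"),
                         ...) {
  if (is.character(features))
    features <- read_freesurfer_tables(features)
  if (is.character(pheno))
    pheno <- read_phenotype(pheno)
  pheno <- pheno[pheno$subject_id %in% rownames(features$values), ]

  sel <- select_cohort(pheno, criteria)
  ages <- function(ids) pheno$age[match(ids, pheno$subject_id)]
  balance <- cohort_balance_check(ages(sel$case), ages(sel$control))

  prepped <- prepare_features(features, augment = augment)
  case_tab <- ft_select_subjects(prepped, sel$case)
  ctrl_tab <- ft_select_subjects(prepped, sel$control)

  cmp <- compare_groups(case_tab, ctrl_tab, ...)
  cmap <- centrality_cluster_map(cmp$ctrl_mean_profile)
  rankings <- stats::setNames(
    lapply(rank_measures, function(m)
      rank_nodes(cmp$nodes, m, k = top_k, metadata = cmp$metadata)),
    rank_measures)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_comparison(cmp, out_dir)
    case_net <- suppressWarnings(build_network(case_tab,
                                               q = cmp$plan$q,
                                               sigma = cmp$plan$sigma,
                                               node_set = cmp$plan$node_set))
    export_network(case_net, out_dir, prefix = "case_network")
    write_profile_csv(cmp$case_profile,
                      file.path(out_dir, "case_profile.csv"))
    utils::write.csv(
      data.frame(feature_id = rownames(cmp$ctrl_mean_profile),
                 cmp$ctrl_mean_profile),
      file.path(out_dir, "control_mean_profile.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(measure = rownames(cmap$correlation), cmap$correlation,
                 cluster = cmap$labels[rownames(cmap$correlation)],
                 dendrogram_position = order(cmap$order)),
      file.path(out_dir, "cluster_map.csv"), row.names = FALSE)
    for (m in names(rankings))
      utils::write.csv(rankings[[m]],
                       file.path(out_dir, paste0("top_nodes_", m, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      list(balance_check = balance, cohort_counts = as.list(sel$counts),
           augment = augment, n_features = ncol(prepped$values)),
      file.path(out_dir, "pipeline_metadata.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(table = prepped, selection = sel, balance = balance,
       comparison = cmp, cluster_map = cmap, rankings = rankings)
}
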