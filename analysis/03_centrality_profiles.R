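#!/usr/bin/env Rscript
# Compute the twelve node-centrality measures for each group network and
# the cross-correlation cluster map of the measures.

source("analysis/00_config.R")

fix_dir <- file.path("results", "cohort")
tab <- read_freesurfer_tables(
  list.files(fix_dir, pattern = "\\.tsv$", full.names = TRUE))
pheno <- read_phenotype(file.path(fix_dir, "phenotype.csv"))
prep <- prepare_features(tab)
sel <- select_cohort(pheno)

out <- res_dir("centrality")
profs <- list()
for (grp in c("case", "control")) {
  net <- build_network(ft_select_subjects(prep, sel[[grp]]))
  profs[[grp]] <- centrality_profile(net)
  write_profile_csv(profs[[grp]],
                    file.path(out, paste0(grp, "_profile.csv")))
  nm <- attr(profs[[grp]], "n_missing")
  cat(grp, "profile:", nrow(profs[[grp]]), "nodes;",
      "undefined entries:", sum(nm), "\n")
}

cm <- centrality_cluster_map(profs$control, k = 4)
cat("measure clusters on the control network:\n")
for (k in sort(unique(cm$labels)))
  cat("  cluster", k, ":",
      paste(names(cm$labels)[cm$labels == k], collapse = ", "), "\n")
utils::write.csv(
  data.frame(measure = rownames(cm$correlation), cm$correlation,
             cluster = cm$labels),
  file.path(out, "cluster_map.csv"), row.names = FALSE)
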