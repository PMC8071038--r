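#!/usr/bin/env Rscript
# Ingest the simulated stats tables, normalize and augment the features,
# and build the binarized + weighted correlation network of each group
# at the standard settings (85th-percentile threshold, chordal weights,
# sigma = 1).

source("analysis/00_config.R")

fix_dir <- file.path("results", "cohort")
tsvs <- list.files(fix_dir, pattern = "\\.tsv$", full.names = TRUE)
tab <- read_freesurfer_tables(tsvs)
pheno <- read_phenotype(file.path(fix_dir, "phenotype.csv"))
cat("ingested", nrow(tab$values), "subjects x", ncol(tab$values),
    "features from", length(tsvs), "tables\n")

prep <- prepare_features(tab)
cat("after normalization + left/right augmentation:",
    ncol(prep$values), "features\n")

sel <- select_cohort(pheno, list(sex = "M", handedness = "R"))
net_dir <- res_dir("networks")
for (grp in c("case", "control")) {
  net <- build_network(ft_select_subjects(prep, sel[[grp]]))
  cat(sprintf("%s network: %d nodes, %d links, density %.4f, threshold rS > %.4f, %d component(s)\n",
              grp, nrow(net$A), sum(net$A) / 2, net$density,
              net$threshold, net$n_components))
  export_network(net, net_dir, prefix = paste0(grp, "_network"))
}
cat("network exports written under", net_dir, "\n")
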