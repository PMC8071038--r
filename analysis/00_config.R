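# Shared study configuration for the analysis scripts.
#
# The demonstration cohort is a scaled-down version of the unbalanced
# two-group design the pipeline targets: a 157-feature schema (16
# bilateral cortical regions x 4 measures, 8 bilateral subcortical
# volumes, 6 unpaired volumes, 7 global measures), 120 cases vs 200
# controls, K = 200 subsampling repetitions. A mild correlation
# perturbation is planted on the six cuneus features of the case group
# so the single-node analysis has a known target.

library(brainwcn)

study_schema <- make_canonical_schema(
  cortical_regions = DKT_CORTICAL_REGIONS[1:16],
  cortical_measures = c("volume", "area", "thickness", "thicknessstd"),
  subcortical_bilateral = SUBCORTICAL_BILATERAL[1:8],
  subcortical_other = SUBCORTICAL_OTHER[1:6])

planted_set <- c("lh_cuneus_volume", "rh_cuneus_volume",
                 "lh_cuneus_area", "rh_cuneus_area",
                 "lh_cuneus_thickness", "rh_cuneus_thickness")

study_config <- synth_config(
  n_case = 120L, n_control = 200L, schema = study_schema,
  planted_nodes = planted_set, planted_delta = 0.6, seed = 42L)

study_K <- 200L
study_seed <- 7L

res_dir <- function(...) {
  p <- file.path("results", ...)
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
  p
}
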