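# Shared reduced schema and cached synthetic cohorts so the slower
# statistical tests reuse one generation pass per configuration.

test_schema <- function(regions = 8, measures = c("volume", "area",
                                                  "thickness")) {
  make_canonical_schema(
    cortical_regions = DKT_CORTICAL_REGIONS[seq_len(regions)],
    cortical_measures = measures,
    subcortical_bilateral = SUBCORTICAL_BILATERAL[1:4],
    subcortical_other = SUBCORTICAL_OTHER[1:2])
}

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# small null cohort, prepared, with connected group networks
small_cohort <- function() cached("small", {
  cfg <- synth_config(n_case = 40, n_control = 60, schema = test_schema(4),
                      seed = 11L)
  generate_connected_cohort(cfg)
})

# mid-size null cohort for comparison tests
mid_cohort <- function() cached("mid", {
  cfg <- synth_config(n_case = 60, n_control = 100, schema = test_schema(),
                      seed = 21L)
  generate_connected_cohort(cfg)
})

planted_features <- c("lh_cuneus_volume", "rh_cuneus_volume",
                      "lh_cuneus_area", "rh_cuneus_area",
                      "lh_cuneus_thickness", "rh_cuneus_thickness")

# frozen planted-effect cohort (calibrated once: delta = 0.6, seed 42)
planted_cohort <- function() cached("planted", {
  cfg <- synth_config(n_case = 120, n_control = 200,
                      schema = test_schema(), seed = 42L,
                      planted_nodes = planted_features,
                      planted_delta = 0.6)
  generate_connected_cohort(cfg)
})
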