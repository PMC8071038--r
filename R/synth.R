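# Synthetic two-group cohort generator: a Gaussian copula built from
# layered latent factors (global size, anatomical blocks, measure kinds,
# a smooth anatomical covariance gradient with symmetric and
# hemisphere-antisymmetric parts), monotone positive-valued marginal maps
# per feature class, and a plantable between-group difference implemented
# as reduced factor loadings on a chosen node set in the case group.
# Because the analysis pipeline is rank-based, the choice of marginal
# maps cannot affect downstream results; the copula carries all the
# signal.

#' Synthetic cohort configuration
#'
#' All `rho_*` parameters are variance shares of latent factors; the
#' shares (plus residual noise) of each feature sum to 1, so the implied
#' correlation matrix is positive semi-definite by construction.
#'
#' @param n_case,n_control group sizes (>= 3). Defaults mirror the
#'   unbalanced two-group setting the pipeline is designed for
#'   (235 cases vs 418 controls).
#' @param schema feature metadata (default: the canonical 419-feature
#'   schema from [make_canonical_schema()]).
#'
#' @param rho_block variance share of the per-block (anatomical grouping)
#'   factor; scalar or named per-block vector. Same-hemisphere block
#'   mates correlate at roughly `rho_global + rho_block + rho_continuum +
#'   rho_lateral` (their gradient angles nearly coincide).
#' @param rho_global variance share of a factor common to all features (a
#'   global "brain size" factor); gives every feature pair a correlation
#'   floor, tying the blocks together so the thresholded network stays
#'   connected, as in real structural-covariance data.
#' @param rho_lateral variance share of the antisymmetric part of the
#'   gradient: left features load positively and right features
#'   negatively on a second ring over the same anatomical angle. It
#'   survives the left-minus-right difference, so derived asymmetry
#'   features of nearby regions correlate (directional asymmetry, as in
#'   real morphometry) and form a connected chain instead of being pure
#'   noise.
#' @param rho_measure variance share of a per-measure-kind factor (all
#'   volumes covary, all thicknesses covary, ...), emulating the
#'   measure-wise covariance continuum of real morphometry that spreads
#'   moderate correlations across anatomical groupings.
#' @param rho_continuum variance share of a smooth covariance gradient:
#'   every feature loads on a two-factor layer at an angle that advances
#'   evenly (with jitter) along the feature list, closing into a ring.
#'   Pairwise it contributes `rho_continuum * cos(angle difference)` --
#'   a continuum of mild positive and negative correlations whose
#'   near-neighbor values approach `rho_continuum` itself, so every
#'   feature has a guaranteed corridor of moderate correlations. This
#'   emulates the pervasive covariance continuum of real morphometry and
#'   keeps the quantile-thresholded network from decomposing into
#'   correlation islands.
#' @param block_structure named character vector mapping feature_id to
#'   block label; default blocks features by anatomical region within
#'   category, with all global features in one block.
#' @param planted_nodes feature IDs whose correlation structure differs in
#'   the case group.
#' @param planted_delta fraction of the planted nodes' structural variance
#'   turned into independent noise in the case group: every factor loading
#'   of a planted node is scaled by `sqrt(1 - planted_delta)`. 0 = null
#'   (identical correlation structure); 1 = planted nodes fully
#'   decorrelated from the rest.
#' @param age_case,age_control age distribution specs:
#'   `list(min =, meanlog =, sdlog =)` for `min + lognormal` ages in years.
#' @param seed integer seed.
#' @return list of class `synth_config` (validated).
#' @export
synth_config <- function(n_case = 235L, n_control = 418L,
                         schema = make_canonical_schema(),
                         rho_block = 0.12,
                         rho_global = 0.08,
                         rho_lateral = 0.18,
                         rho_measure = 0.05,
                         rho_continuum = 0.3,
                         block_structure = NULL,
                         planted_nodes = character(0),
                         planted_delta = 0,
                         age_case = list(min = 7, meanlog = log(9),
                                         sdlog = 0.55),
                         age_control = list(min = 7, meanlog = log(9),
                                            sdlog = 0.55),
                         seed = 1L) {
  stopifnot(n_case >= 3L, n_control >= 3L,
            planted_delta >= 0, planted_delta <= 1)
  if (is.null(block_structure)) block_structure <- default_blocks(schema)
  stopifnot(all(schema$feature_id %in% names(block_structure)))
  blocks <- unique(block_structure)
  if (length(rho_block) == 1L && is.null(names(rho_block)))
    rho_block <- stats::setNames(rep(rho_block, length(blocks)), blocks)
  stopifnot(all(blocks %in% names(rho_block)),
            all(rho_block >= 0), rho_global >= 0, rho_lateral >= 0,
            rho_measure >= 0, rho_continuum >= 0,
            all(rho_block + rho_global + rho_lateral + rho_measure +
                  rho_continuum < 1))
  bad <- setdiff(planted_nodes, schema$feature_id)
  if (length(bad)) stop("planted nodes not in schema: ",
                        paste(bad, collapse = ", "))
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control), schema = schema,
                 rho_block = rho_block, rho_global = rho_global,
                 rho_lateral = rho_lateral, rho_measure = rho_measure,
                 rho_continuum = rho_continuum,
                 block_structure = block_structure,
                 planted_nodes = planted_nodes,
                 planted_delta = planted_delta,
                 age_case = age_case, age_control = age_control,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# default partition: cortical and bilateral-subcortical features grouped
# by region; unpaired subcortical features and the global/normalizer
# features form one block each
default_blocks <- function(schema) {
  blk <- ifelse(schema$category %in% c("cortical", "subcortical_bilateral"),
                paste(schema$category, schema$region, sep = ":"),
                ifelse(schema$category == "subcortical_other",
                       paste("other", schema$region, sep = ":"),
                       "global"))
  stats::setNames(blk, schema$feature_id)
}

#' Generate a synthetic two-group cohort
#'
#' Draws a latent Gaussian factor model per group with five layers: a
#' global factor every feature loads on, one factor per measure kind, one
#' factor per anatomical block, and a ring-shaped anatomical covariance
#' gradient with a symmetric part and a hemisphere-antisymmetric part
#' (left features load `+`, right `-`); each contributes its `rho_*`
#' variance share and the remainder is feature noise. In the case group, every factor loading of a planted
#' node is scaled by `sqrt(1 - planted_delta)` (the lost variance becomes
#' independent noise), which weakens all its correlations and so perturbs
#' its network neighborhood. Latents are mapped to positive morphometric
#' scales through per-feature strictly increasing maps (lognormal-type for
#' volumes and areas, scaled-exponential for thicknesses). Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `table` (raw `feature_table`, both groups stacked)
#'   and `pheno` (phenotype data.frame: subject_id, group, age, sex,
#'   handedness).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  schema <- cfg$schema
  F <- nrow(schema)
  ids <- schema$feature_id
  blk <- cfg$block_structure[ids]
  l_blk <- cfg$rho_block[blk]        # block-factor share
  a <- cfg$rho_global                # global-factor share
  meas <- schema$measure
  m_meas <- rep(cfg$rho_measure, F)  # measure-family share
  lat_sign <- ifelse(schema$hemisphere == "left", 1,
                     ifelse(schema$hemisphere == "right", -1, 0))

  # per-feature marginal map parameters (shared by both groups); regional
  # volumes and areas are kept within one order of magnitude so that
  # sum-type normalizers are balanced averages, as in real morphometry
  mu_vol <- stats::runif(F, 7, 8.2)
  s_vol <- stats::runif(F, 0.15, 0.35)
  t_base <- stats::runif(F, 2, 3)
  c_base <- stats::runif(F, 0.1, 0.2)
  t_scale <- rep(0.08, F)
  # whole-brain aggregates (the normalizer features) vary far less across
  # subjects than single regions; without this, dividing by them injects
  # a large common noise into every normalized feature
  s_vol[schema$is_normalizer] <- 0.03
  t_scale[schema$is_normalizer] <- 0.015
  mu_vol[schema$is_normalizer & schema$measure == "volume"] <- 12

  # covariance-gradient loadings: unit directions advancing around a
  # ring along an anatomical axis -- one angle per region group, so
  # homologs and block mates sit at nearly the same angle and adjacent
  # regions correlate at close to the full gradient share (fixed across
  # groups)
  reg_grp <- paste(schema$category, schema$region)
  g_idx <- match(reg_grp, unique(reg_grp))
  G <- length(unique(reg_grp))
  theta <- 2 * pi * (g_idx - 1) / G +
    stats::runif(F, 0, pi / max(G, 1))
  lam <- sqrt(cfg$rho_continuum) * cbind(cos(theta), sin(theta))
  # antisymmetric ring: same anatomical angle, hemisphere-signed loading
  lam_lat <- sqrt(cfg$rho_lateral) * lat_sign * cbind(cos(theta),
                                                      sin(theta))

  to_scale <- function(z) {
    x <- matrix(NA_real_, nrow(z), F)
    for (j in seq_len(F)) {
      x[, j] <- switch(schema$measure[j],
        volume = exp(mu_vol[j] + s_vol[j] * z[, j]),
        surface_area = exp(mu_vol[j] - 1 + s_vol[j] * z[, j]),
        thickness_mean = ,
        thickness_sd = t_base[j] * exp(t_scale[j] * z[, j]),
        c_base[j] + 0.05 * z[, j])
    }
    x
  }

  draw_group <- function(n, planted) {
    # planted nodes: scale every structural loading, absorb into noise
    mult <- rep(1, F)
    mult[ids %in% planted] <- sqrt(1 - cfg$planted_delta)
    h <- stats::rnorm(n)             # global factor
    g <- matrix(stats::rnorm(n * length(unique(blk))), n)
    colnames(g) <- unique(blk)
    mf <- matrix(stats::rnorm(n * length(unique(meas))), n)
    colnames(mf) <- unique(meas)
    fac <- matrix(stats::rnorm(n * 2L), n, 2L)   # symmetric gradient
    fac_lat <- matrix(stats::rnorm(n * 2L), n, 2L) # antisymmetric
    eps <- matrix(stats::rnorm(n * F), n, F)
    s_lat <- cfg$rho_lateral * as.numeric(lat_sign != 0)
    struct <- sqrt(a) * h +
      sweep(g[, blk, drop = FALSE], 2L, sqrt(l_blk), `*`) +
      sweep(mf[, meas, drop = FALSE], 2L, sqrt(m_meas), `*`) +
      fac %*% t(lam) +
      fac_lat %*% t(lam_lat)
    shares <- a + s_lat + l_blk + m_meas + cfg$rho_continuum
    sweep(struct, 2L, mult, `*`) +
      sweep(eps, 2L, sqrt(1 - mult^2 * shares), `*`)
  }

  draw_ages <- function(n, spec)
    spec$min + stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog)

  z_case <- draw_group(cfg$n_case, cfg$planted_nodes)
  z_ctrl <- draw_group(cfg$n_control, character(0))
  vals <- rbind(to_scale(z_case), to_scale(z_ctrl))
  subj <- c(sprintf("case_%04d", seq_len(cfg$n_case)),
            sprintf("control_%04d", seq_len(cfg$n_control)))
  dimnames(vals) <- list(subj, ids)
  pheno <- data.frame(
    subject_id = subj,
    group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
    age = c(draw_ages(cfg$n_case, cfg$age_case),
            draw_ages(cfg$n_control, cfg$age_control)),
    sex = "M", handedness = "R", stringsAsFactors = FALSE)
  list(table = feature_table(vals, schema), pheno = pheno)
}

#' Write a synthetic cohort as FreeSurfer-dialect fixture files
#'
#' Emits the tables that [read_freesurfer_tables()] ingests: one
#' `aseg.tsv` with the subcortical/global/normalizer volume columns, one
#' `aparc_<hemi>_<measure>.tsv` per cortical measure table (the thickness
#' tables carry the MeanThickness columns, as FreeSurfer's do), and a
#' `phenotype.csv`. Numbers round-trip exactly: write -> read -> write is
#' byte-identical.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort$table
  md <- tab$metadata
  paths <- character(0)
  aseg_ids <- md$feature_id[!grepl("^(lh|rh)_", md$feature_id)]
  if (length(aseg_ids)) {
    p <- file.path(dir, "aseg.tsv")
    write_feature_tsv(ft_select_features(tab, aseg_ids), p,
                      subject_col = "Measure:volume")
    paths <- c(paths, p)
  }
  cort <- md$feature_id[grepl("^(lh|rh)_", md$feature_id)]
  if (length(cort)) {
    suffix <- sub("^.*_", "", cort)
    hemi <- sub("^(lh|rh)_.*$", "\\1", cort)
    for (h in unique(hemi)) for (s in unique(suffix[hemi == h])) {
      sel <- cort[hemi == h & suffix == s]
      p <- file.path(dir, paste0("aparc_", h, "_", s, ".tsv"))
      write_feature_tsv(ft_select_features(tab, sel), p,
                        subject_col = paste0(h, ".aparc.", s))
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "phenotype.csv")
  write_phenotype_csv(cohort$pheno, p)
  invisible(c(paths, p))
}

#' Generate a cohort whose group networks are connected
#'
#' The link density of the network construction is chosen (here, as in
#' practice) so that thresholded networks stay connected; with small
#' synthetic cohorts a sampling draw can still fragment. This helper
#' regenerates the cohort with consecutive seeds (`seed`, `seed + 1`,
#' ...) until the full-group case and control networks are both
#' connected, keeping the procedure deterministic given the initial
#' seed. Subsampled repetitions that fragment are redrawn independently
#' by [subsample_profiles()].
#'
#' @param cfg a [synth_config()].
#' @param q,sigma,node_set network construction parameters used for the
#'   connectivity check.
#' @param augment append bilateral average/asymmetry features before
#'   checking.
#' @param max_tries attempts before giving up.
#' @return list with `cohort`, the `prepared` (normalized/augmented)
#'   table, `case` and `control` prepared sub-tables, `seed_used`, and
#'   the number of `tries`.
#' @export
generate_connected_cohort <- function(cfg, q = 0.85, sigma = 1,
                                      node_set = "augmented",
                                      augment = TRUE, max_tries = 25L) {
  for (k in seq_len(max_tries)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + (k - 1L)
    coh <- generate_cohort(cfg_k)
    prep <- suppressWarnings(prepare_features(coh$table,
                                              augment = augment))
    tabs <- lapply(c(case = "case", control = "control"), function(grp)
      ft_select_subjects(prep,
                         coh$pheno$subject_id[coh$pheno$group == grp]))
    ncomp <- vapply(tabs, function(tab)
      suppressWarnings(build_network(tab, q = q, sigma = sigma,
                                     node_set = node_set))$n_components,
      0)
    if (all(ncomp == 1L))
      return(list(cohort = coh, prepared = prep, case = tabs$case,
                  control = tabs$control, seed_used = cfg_k$seed,
                  tries = k))
  }
  stop("no connected cohort found in ", max_tries, " tries")
}
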