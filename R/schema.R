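# Feature schema: metadata for morphometric features in the FreeSurfer
# aseg/aparc stats-table dialect, plus the canonical 419-feature layout
# (31 bilateral cortical regions x 6 measures, 28 bilateral subcortical
# volumes, 12 unpaired subcortical volumes, 7 global measures).

#' Cortical parcellation region names
#'
#' The 31 bilateral cortical regions of the Desikan-Killiany-Tourville
#' parcellation used by the canonical schema.
#' @export
DKT_CORTICAL_REGIONS <- c(
  "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus", "entorhinal",
  "fusiform", "inferiorparietal", "inferiortemporal", "isthmuscingulate",
  "lateraloccipital", "lateralorbitofrontal", "lingual", "medialorbitofrontal",
  "middletemporal", "parahippocampal", "paracentral", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "transversetemporal", "insula")

#' Cortical measure suffixes
#'
#' Map from `aparcstats2table` column suffix to measure kind and
#' normalization class.
#' @export
CORTICAL_MEASURES <- data.frame(
  suffix     = c("volume", "area", "thickness", "thicknessstd",
                 "meancurv", "curvind"),
  measure    = c("volume", "surface_area", "thickness_mean", "thickness_sd",
                 "mean_curvature", "curvature_index"),
  norm_class = c("volume_like", "area_like", "thickness_like",
                 "thickness_like", "none", "none"),
  stringsAsFactors = FALSE)

#' Bilateral subcortical structures
#'
#' `asegstats2table` structures with left/right homologs (14 pairs).
#' @export
SUBCORTICAL_BILATERAL <- c(
  "Thalamus-Proper", "Caudate", "Putamen", "Pallidum", "Hippocampus",
  "Amygdala", "Accumbens-area", "VentralDC", "Cerebellum-White-Matter",
  "Cerebellum-Cortex", "Lateral-Ventricle", "Inf-Lat-Vent",
  "choroid-plexus", "vessel")

#' Unpaired subcortical structures
#'
#' The 12 subcortical volumes without left/right homologs.
#' @export
SUBCORTICAL_OTHER <- c(
  "Brain-Stem", "CSF", "3rd-Ventricle", "4th-Ventricle", "5th-Ventricle",
  "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior",
  "CC_Anterior", "Optic-Chiasm", "WM-hypointensities")

HEMISPHERE_LEVELS <- c("left", "right", "bilateral_avg", "bilateral_asym",
                       "global")
MEASURE_LEVELS <- c("volume", "surface_area", "thickness_mean",
                    "thickness_sd", "mean_curvature", "curvature_index",
                    "other")
NORM_CLASS_LEVELS <- c("volume_like", "thickness_like", "area_like", "none")

new_feature_metadata <- function(feature_id, region, hemisphere, measure,
                                 norm_class, category,
                                 is_normalizer = FALSE) {
  stopifnot(all(hemisphere %in% HEMISPHERE_LEVELS),
            all(measure %in% MEASURE_LEVELS),
            all(norm_class %in% NORM_CLASS_LEVELS))
  if (anyDuplicated(feature_id))
    stop("duplicate feature_id in schema: ",
         paste(feature_id[duplicated(feature_id)], collapse = ", "))
  data.frame(feature_id = feature_id, region = region,
             hemisphere = hemisphere, measure = measure,
             norm_class = norm_class, category = category,
             is_normalizer = is_normalizer, stringsAsFactors = FALSE)
}

#' Parse a FreeSurfer stats-table column name into feature metadata
#'
#' Understands the `aparcstats2table` dialect (`lh_<region>_<measure>`,
#' `rh_<region>_<measure>`, `lh_MeanThickness_thickness`) and the
#' `asegstats2table` dialect (`Left-<structure>`, `Right-<structure>`,
#' global volume columns such as `TotalGrayVol` and `BrainSegVolNotVent`).
#' Unrecognized names fall back to a global/other classification so foreign
#' columns survive ingestion.
#'
#' @param name character vector of column names.
#' @return a data.frame of feature metadata, one row per name, with columns
#'   `feature_id`, `region`, `hemisphere`, `measure`, `norm_class`,
#'   `category`, `is_normalizer`.
#' @export
parse_feature_name <- function(name) {
  one <- function(nm) {
    if (nm == "BrainSegVolNotVent")
      return(list(region = "BrainSegVolNotVent", hemisphere = "global",
                  measure = "volume", norm_class = "none",
                  category = "normalizer", is_normalizer = TRUE))
    m <- regmatches(nm, regexec("^(lh|rh)_(.+)_([a-z]+)$", nm))[[1]]
    if (length(m) == 4L) {
      hemi <- if (m[2] == "lh") "left" else "right"
      idx <- match(m[4], CORTICAL_MEASURES$suffix)
      if (!is.na(idx)) {
        if (m[3] == "MeanThickness")
          return(list(region = "MeanThickness", hemisphere = hemi,
                      measure = "thickness_mean",
                      norm_class = "thickness_like",
                      category = "global", is_normalizer = TRUE))
        return(list(region = m[3], hemisphere = hemi,
                    measure = CORTICAL_MEASURES$measure[idx],
                    norm_class = CORTICAL_MEASURES$norm_class[idx],
                    category = "cortical", is_normalizer = FALSE))
      }
    }
    m <- regmatches(nm, regexec("^(Left|Right)-(.+)$", nm))[[1]]
    if (length(m) == 3L) {
      hemi <- if (m[2] == "Left") "left" else "right"
      return(list(region = m[3], hemisphere = hemi, measure = "volume",
                  norm_class = "volume_like",
                  category = "subcortical_bilateral", is_normalizer = FALSE))
    }
    m <- regmatches(nm, regexec("^(lh|rh)(CortexVol|CerebralWhiteMatterVol)$",
                                nm))[[1]]
    if (length(m) == 3L) {
      hemi <- if (m[2] == "lh") "left" else "right"
      return(list(region = m[3], hemisphere = hemi, measure = "volume",
                  norm_class = "volume_like", category = "global",
                  is_normalizer = FALSE))
    }
    if (nm == "TotalGrayVol")
      return(list(region = "TotalGrayVol", hemisphere = "global",
                  measure = "volume", norm_class = "volume_like",
                  category = "global", is_normalizer = FALSE))
    if (nm %in% SUBCORTICAL_OTHER)
      return(list(region = nm, hemisphere = "global", measure = "volume",
                  norm_class = "volume_like", category = "subcortical_other",
                  is_normalizer = FALSE))
    # fallback: unclassified global feature, left untouched by normalization
    list(region = nm, hemisphere = "global", measure = "other",
         norm_class = "none", category = "global", is_normalizer = FALSE)
  }
  rows <- lapply(name, one)
  new_feature_metadata(
    feature_id = name,
    region = vapply(rows, `[[`, "", "region"),
    hemisphere = vapply(rows, `[[`, "", "hemisphere"),
    measure = vapply(rows, `[[`, "", "measure"),
    norm_class = vapply(rows, `[[`, "", "norm_class"),
    category = vapply(rows, `[[`, "", "category"),
    is_normalizer = vapply(rows, `[[`, NA, "is_normalizer"))
}

#' Canonical morphometric feature schema
#'
#' Builds the 419-feature base schema: volume, surface area, mean/sd
#' thickness, mean curvature and curvature index for 31 bilateral cortical
#' regions (372 features); 14 bilateral subcortical volumes (28); 12
#' unpaired subcortical volumes; and 7 global measures (left/right cortex
#' volume, left/right mean thickness, left/right cerebral white matter
#' volume, total gray volume). The global normalizer column
#' `BrainSegVolNotVent` is appended as an extra flagged feature outside the
#' 419 count. Passing subsets of the region/measure arguments yields a
#' reduced schema with the same structure, which the synthetic generator and
#' the tests use for small cohorts.
#'
#' @param cortical_regions cortical region names (default: all 31).
#' @param cortical_measures measure suffixes to include (default: all 6).
#' @param subcortical_bilateral bilateral subcortical structure names.
#' @param subcortical_other unpaired subcortical structure names.
#' @param include_global include the 7 global features and the
#'   `BrainSegVolNotVent` normalizer (required for normalization).
#' @return feature metadata data.frame (see [parse_feature_name()]).
#' @export
make_canonical_schema <- function(cortical_regions = DKT_CORTICAL_REGIONS,
                                  cortical_measures = CORTICAL_MEASURES$suffix,
                                  subcortical_bilateral = SUBCORTICAL_BILATERAL,
                                  subcortical_other = SUBCORTICAL_OTHER,
                                  include_global = TRUE) {
  stopifnot(all(cortical_measures %in% CORTICAL_MEASURES$suffix))
  ids <- character(0)
  if (length(cortical_regions))
    for (hemi in c("lh", "rh"))
      for (suf in cortical_measures)
        ids <- c(ids, paste0(hemi, "_", cortical_regions, "_", suf))
  if (length(subcortical_bilateral))
    for (side in c("Left", "Right"))
      ids <- c(ids, paste0(side, "-", subcortical_bilateral))
  ids <- c(ids, subcortical_other)
  if (include_global)
    ids <- c(ids, "lhCortexVol", "rhCortexVol",
             "lh_MeanThickness_thickness", "rh_MeanThickness_thickness",
             "lhCerebralWhiteMatterVol", "rhCerebralWhiteMatterVol",
             "TotalGrayVol", "BrainSegVolNotVent")
  parse_feature_name(ids)
}

#' Count schema features per category
#'
#' @param schema feature metadata data.frame.
#' @return named integer vector with per-category counts and `base_total`,
#'   the number of features excluding extra normalizer columns.
#' @export
schema_counts <- function(schema) {
  n <- function(cat) sum(schema$category == cat)
  c(cortical = n("cortical"),
    subcortical_bilateral = n("subcortical_bilateral"),
    subcortical_other = n("subcortical_other"),
    global = n("global"),
    normalizer = n("normalizer"),
    base_total = sum(schema$category != "normalizer"))
}

# left/right homolog pairs: rows (left_id, right_id), matched on
# region + measure. Unpaired lateral features are returned in $unpaired.
# Normalizer-flagged features are not paired: the bilateral average of the
# hemisphere mean-thickness columns after normalization by their own mean
# is identically 1 (a degenerate feature), so derived features are not
# generated for them.
lr_pairs <- function(schema) {
  schema <- schema[!schema$is_normalizer, ]
  left <- schema[schema$hemisphere == "left", ]
  right <- schema[schema$hemisphere == "right", ]
  key <- function(df) paste(df$region, df$measure, sep = "\r")
  lk <- key(left); rk <- key(right)
  if (anyDuplicated(lk) || anyDuplicated(rk))
    stop("ambiguous left/right pairing: duplicated region+measure keys")
  m <- match(lk, rk)
  paired <- !is.na(m)
  list(pairs = data.frame(left_id = left$feature_id[paired],
                          right_id = right$feature_id[m[paired]],
                          region = left$region[paired],
                          measure = left$measure[paired],
                          stringsAsFactors = FALSE),
       unpaired = c(left$feature_id[!paired],
                    right$feature_id[setdiff(seq_len(nrow(right)),
                                             m[paired])]))
}

#' Construct a feature table
#'
#' A feature table couples a subjects-by-features numeric matrix with
#' per-feature metadata. Values must be finite; positive-valued classes
#' (volumes, areas, thicknesses) are checked when `check_positive` is TRUE.
#'
#' @param values numeric matrix, subjects in rows (rownames = subject IDs),
#'   features in columns (colnames = feature IDs).
#' @param metadata feature metadata aligned with `colnames(values)`; parsed
#'   from the names when omitted.
#' @param check_positive verify strict positivity of volume/area/thickness
#'   features (pre-normalization contract).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, metadata = NULL, check_positive = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (is.null(metadata)) metadata <- parse_feature_name(colnames(values))
  stopifnot(identical(metadata$feature_id, colnames(values)))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("non-finite values, e.g. subject ", rownames(values)[bad[1, 1]],
         ", feature ", colnames(values)[bad[1, 2]])
  }
  if (check_positive) {
    pos <- metadata$norm_class %in% c("volume_like", "thickness_like",
                                      "area_like")
    if (any(pos) && any(values[, pos, drop = FALSE] <= 0)) {
      bad <- which(values[, pos, drop = FALSE] <= 0, arr.ind = TRUE)
      stop("non-positive value in positive-valued feature class: subject ",
           rownames(values)[bad[1, 1]], ", feature ",
           colnames(values[, pos, drop = FALSE])[bad[1, 2]])
    }
  }
  structure(list(values = values, metadata = metadata,
                 normalized = FALSE, augmented = FALSE),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "subjects x", ncol(x$values),
      "features\n")
  cat("  normalized:", x$normalized, " augmented:", x$augmented, "\n")
  print(table(x$metadata$category))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by feature IDs (metadata kept aligned)
#' @param table a `feature_table`.
#' @param feature_ids feature IDs to keep, in order.
#' @return the subset `feature_table`.
#' @export
ft_select_features <- function(table, feature_ids) {
  idx <- match(feature_ids, table$metadata$feature_id)
  if (anyNA(idx)) stop("unknown feature ids: ",
                       paste(feature_ids[is.na(idx)], collapse = ", "))
  out <- table
  out$values <- table$values[, idx, drop = FALSE]
  out$metadata <- table$metadata[idx, , drop = FALSE]
  rownames(out$metadata) <- NULL
  out
}

#' Subset a feature table by subject IDs
#' @param table a `feature_table`.
#' @param subject_ids subject IDs to keep, in order.
#' @return the subset `feature_table`.
#' @export
ft_select_subjects <- function(table, subject_ids) {
  idx <- match(subject_ids, rownames(table$values))
  if (anyNA(idx)) stop("unknown subject ids: ",
                       paste(subject_ids[is.na(idx)], collapse = ", "))
  out <- table
  out$values <- table$values[idx, , drop = FALSE]
  out
}
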