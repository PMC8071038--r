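# Normalization for inter-individual variability and left/right
# augmentation. Order of operations in the standard pipeline: normalize
# first, then augment, so bilateral averages and asymmetries are computed
# on normalized values.

#' Normalize features for inter-individual variability
#'
#' Per subject: volume-like features are divided by the global brain volume
#' (`BrainSegVolNotVent`); thickness-like features by the mean cortical
#' thickness, computed as the average of the left- and right-hemisphere
#' average thickness columns; area-like features by the sum of all cortical
#' surface-area columns. Features with `norm_class = "none"` are untouched.
#' All normalizers are computed from the raw table before any division, and
#' the normalizer columns themselves are retained (flagged in the metadata).
#' This is a one-shot transform: re-applying it divides again.
#'
#' @param table a `feature_table` of raw values.
#' @return the normalized `feature_table` (`$normalized` set to TRUE).
#' @export
normalize_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized)
    warning("table is already normalized; normalizing again")
  md <- table$metadata
  vals <- table$values
  subj <- rownames(vals)

  get_col <- function(id, what) {
    j <- match(id, md$feature_id)
    if (is.na(j)) stop("normalizer feature missing: ", id, " (", what, ")")
    vals[, j]
  }
  brain_vol <- get_col("BrainSegVolNotVent", "global brain volume")
  lh_th <- get_col("lh_MeanThickness_thickness", "left mean thickness")
  rh_th <- get_col("rh_MeanThickness_thickness", "right mean thickness")
  mean_th <- (lh_th + rh_th) / 2
  area_cols <- md$category == "cortical" & md$measure == "surface_area"
  if (!any(area_cols))
    stop("normalizer feature missing: cortical surface-area columns")
  total_area <- rowSums(vals[, area_cols, drop = FALSE])

  check_pos <- function(x, what) {
    bad <- which(x <= 0)
    if (length(bad))
      stop("non-positive ", what, " for subject ", subj[bad[1]])
  }
  check_pos(brain_vol, "global brain volume")
  check_pos(mean_th, "mean cortical thickness")
  check_pos(total_area, "total cortical surface area")

  out <- vals
  cls <- md$norm_class
  # normalizer columns keep their raw values (flagged via is_normalizer)
  active <- !md$is_normalizer
  vcol <- which(cls == "volume_like" & active)
  tcol <- which(cls == "thickness_like" & active)
  acol <- which(cls == "area_like" & active)
  if (length(vcol)) out[, vcol] <- vals[, vcol, drop = FALSE] / brain_vol
  if (length(tcol)) out[, tcol] <- vals[, tcol, drop = FALSE] / mean_th
  if (length(acol)) out[, acol] <- vals[, acol, drop = FALSE] / total_area

  res <- table
  res$values <- out
  res$normalized <- TRUE
  res
}

#' Append bilateral average and asymmetry features
#'
#' For every homologous left/right feature pair (matched on region +
#' measure) two features are appended: the bilateral average `(L + R) / 2`
#' and the asymmetry `(L - R) / 2` (sign convention: left minus right).
#' Original features are retained. Lateral features without a homolog are
#' skipped with a warning.
#'
#' @param table a `feature_table`.
#' @return the augmented `feature_table` (`$augmented` set to TRUE); the
#'   number of pairs used is recorded in `attr(, "n_pairs")`.
#' @export
augment_lr <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  pr <- lr_pairs(table$metadata)
  if (length(pr$unpaired))
    warning("unpaired lateral features skipped: ",
            paste(pr$unpaired, collapse = ", "))
  pairs <- pr$pairs
  if (nrow(pairs) == 0L) {
    warning("no homologous left/right pairs found; table unchanged")
    out <- table
    out$augmented <- TRUE
    attr(out, "n_pairs") <- 0L
    return(out)
  }
  li <- match(pairs$left_id, table$metadata$feature_id)
  ri <- match(pairs$right_id, table$metadata$feature_id)
  L <- table$values[, li, drop = FALSE]
  R <- table$values[, ri, drop = FALSE]
  avg <- (L + R) / 2
  asym <- (L - R) / 2
  base_name <- sub("^(lh_|Left-|lh)", "", pairs$left_id)
  avg_ids <- paste0("avg_", base_name)
  asym_ids <- paste0("asym_", base_name)
  colnames(avg) <- avg_ids
  colnames(asym) <- asym_ids
  md_l <- table$metadata[li, ]
  new_md <- function(ids, hemi) {
    new_feature_metadata(feature_id = ids, region = md_l$region,
                         hemisphere = hemi, measure = md_l$measure,
                         norm_class = "none",
                         category = md_l$category, is_normalizer = FALSE)
  }
  out <- table
  out$values <- cbind(table$values, avg, asym)
  out$metadata <- rbind(table$metadata,
                        new_md(avg_ids, "bilateral_avg"),
                        new_md(asym_ids, "bilateral_asym"))
  rownames(out$metadata) <- NULL
  out$augmented <- TRUE
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Prepare a raw table for network construction
#'
#' Convenience composition: [normalize_features()] then [augment_lr()].
#'
#' @param table raw `feature_table`.
#' @param augment append bilateral average/asymmetry features.
#' @return prepared `feature_table`.
#' @export
prepare_features <- function(table, augment = TRUE) {
  out <- normalize_features(table)
  if (augment) out <- augment_lr(out)
  out
}
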