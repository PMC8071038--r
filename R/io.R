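# Ingestion of FreeSurfer asegstats2table/aparcstats2table TSV output and
# phenotype CSVs, plus round-trip-exact writers for tables and metadata.

# format doubles so that read -> write -> read is value-exact
fmt_num <- function(x) sprintf("%.17g", x)

read_one_stats_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("stats table ", path, " has no feature columns")
  subjects <- df[[1L]]
  if (anyDuplicated(subjects))
    stop("duplicate subject IDs in ", path, ": ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  feat <- df[-1L]
  vals <- matrix(NA_real_, nrow(feat), ncol(feat),
                 dimnames = list(subjects, colnames(feat)))
  for (j in seq_len(ncol(feat))) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric cell in ", basename(path), ": subject '",
           subjects[bad[1]], "', feature '", colnames(feat)[j],
           "' (value '", feat[[j]][bad[1]], "')")
    vals[, j] <- v
  }
  vals
}

#' Read and merge FreeSurfer stats tables
#'
#' Reads one or more tab-separated tables in the layout written by the
#' FreeSurfer `asegstats2table`/`aparcstats2table` scripts (first column the
#' subject label, remaining columns numeric features), restricts them to the
#' subjects present in every file, and merges the feature columns into a
#' single [feature_table()] with metadata inferred from the column-naming
#' conventions.
#'
#' @param paths character vector of file paths.
#' @param check_positive passed to [feature_table()].
#' @return a `feature_table` covering the subject intersection.
#' @export
read_freesurfer_tables <- function(paths, check_positive = TRUE) {
  stopifnot(length(paths) >= 1L)
  mats <- lapply(paths, read_one_stats_table)
  subjects <- Reduce(intersect, lapply(mats, rownames))
  if (length(subjects) == 0L)
    stop("no subjects shared by all input tables")
  mats <- lapply(mats, function(m) m[subjects, , drop = FALSE])
  all_feats <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_feats))
    stop("duplicate feature name across tables: ",
         paste(unique(all_feats[duplicated(all_feats)]), collapse = ", "))
  values <- do.call(cbind, mats)
  feature_table(values, check_positive = check_positive)
}

#' Read a subject phenotype table
#'
#' CSV with header columns `subject_id`, `group`, `age`, `sex`,
#' `handedness`. `group` must be `case` or `control`.
#'
#' @param path file path.
#' @return a data.frame with the five phenotype columns.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex", "handedness")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in phenotype table")
  if (!all(df$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive and finite")
  df[req]
}

#' Write a feature table as a FreeSurfer-dialect TSV
#'
#' Numbers are formatted so that reading the file back reproduces the
#' doubles exactly; write -> read -> write is byte-identical.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param subject_col name of the leading subject-ID column.
#' @export
write_feature_tsv <- function(table, path, subject_col = "Measure:volume") {
  vals <- table$values
  lines <- c(paste(c(subject_col, colnames(vals)), collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i)
               paste(c(rownames(vals)[i], fmt_num(vals[i, ])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write feature metadata as CSV
#' @param metadata feature metadata data.frame.
#' @param path output path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a phenotype table as CSV
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @export
write_phenotype_csv <- function(pheno, path) {
  out <- pheno
  out$age <- fmt_num(pheno$age)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
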