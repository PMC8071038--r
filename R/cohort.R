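# Cohort selection on phenotype metadata and the age-balance check.

#' Select subjects by phenotype criteria
#'
#' Filters the phenotype table on exact matches of the supplied criteria
#' (e.g. `list(sex = "M", handedness = "R")`) and partitions the selected
#' IDs by group. An empty criteria list selects everyone.
#'
#' @param pheno phenotype data.frame (see [read_phenotype()]).
#' @param criteria named list; each element gives the accepted value(s) of a
#'   phenotype column.
#' @return list with `case` and `control` character vectors of subject IDs
#'   and a `counts` summary.
#' @export
select_cohort <- function(pheno, criteria = list()) {
  unknown <- setdiff(names(criteria), colnames(pheno))
  if (length(unknown))
    stop("criteria name unknown phenotype fields: ",
         paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(pheno))
  for (field in names(criteria))
    keep <- keep & pheno[[field]] %in% criteria[[field]]
  if (!any(keep)) stop("cohort selection is empty")
  sel <- pheno[keep, ]
  out <- list(case = sel$subject_id[sel$group == "case"],
              control = sel$subject_id[sel$group == "control"])
  out$counts <- c(case = length(out$case), control = length(out$control))
  out
}

#' Two-sample Kolmogorov-Smirnov age-balance check
#'
#' Compares the age distributions of two groups with a two-tailed,
#' two-sample KS test; used to verify that a metadata-based cohort
#' restriction introduced no age bias.
#'
#' @param ages_a,ages_b numeric age vectors (each of length >= 2).
#' @return list with the KS statistic `D` and two-tailed `p`.
#' @export
cohort_balance_check <- function(ages_a, ages_b) {
  if (length(ages_a) < 2L || length(ages_b) < 2L)
    stop("each age sample needs at least 2 observations")
  kt <- suppressWarnings(stats::ks.test(ages_a, ages_b,
                                        alternative = "two.sided"))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
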