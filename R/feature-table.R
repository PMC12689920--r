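# Scenario feature-table assembly: MoCA-based group labels, modality
# selection (clinical always included), and z-score normalization.

#' Clinical model features
#'
#' The six clinical parameters used as model features: age, sex,
#' Hoehn & Yahr stage, UPDRS III, levodopa equivalent daily dose and
#' disease duration. MoCA defines the label and is never a feature;
#' education is recorded by the generator but not used as a feature.
#' @return character vector of length 6.
#' @export
clinical_feature_names <- function() {
  c("age", "sex", "hy_stage", "updrs3", "ledd", "duration")
}

#' Assign cognitive groups from MoCA scores
#'
#' Total mapping over integer scores 0-30: 24 and above is unimpaired
#' (`PD-ND`); 16-21 is impaired (`PD-CD`); borderline scores 22-23 and
#' scores below 16 (manifest dementia) are excluded.
#'
#' @param moca integer MoCA scores in 0-30.
#' @return factor with levels `PD-CD`, `PD-ND`, `excluded_borderline`,
#'   `excluded_dementia`.
#' @export
#' @examples
#' assign_groups(c(25, 22, 18, 15))
assign_groups <- function(moca) {
  if (!is.numeric(moca) || any(!is.finite(moca)) ||
      any(moca != round(moca)) || any(moca < 0 | moca > 30)) {
    stop("moca must be integer scores in [0, 30]")
  }
  out <- ifelse(moca >= 24, "PD-ND",
         ifelse(moca >= 22, "excluded_borderline",
         ifelse(moca >= 16, "PD-CD", "excluded_dementia")))
  factor(out, levels = c("PD-CD", "PD-ND",
                         "excluded_borderline", "excluded_dementia"))
}

#' Assemble a scenario feature table
#'
#' Builds the subjects-x-features matrix for one of the three analysis
#' scenarios — `"GMV"` (gray-matter volumes + clinical), `"FC"`
#' (connectivity + clinical) or `"GMV+FC"` (all three blocks) — together
#' with binary labels derived from MoCA (`1` = PD-CD, the positive
#' class; `0` = PD-ND). Sex is binary encoded (0 = female, 1 = male)
#' before any normalization; total intracranial volume is carried along
#' as metadata (it is a covariate, not a feature). Subjects whose MoCA
#' falls in an excluded range are rejected.
#'
#' @param clinical clinical data frame (columns `subject_id`, `age`,
#'   `sex`, `hy_stage`, `updrs3`, `ledd`, `duration`, `moca`).
#' @param gmv gray-matter table (`subject_id`, `tiv`, region columns);
#'   required for the GMV scenarios.
#' @param fc wide connectivity table (`subject_id`, one z column per
#'   pair); required for the FC scenarios.
#' @param scenario `"GMV"`, `"FC"` or `"GMV+FC"`.
#' @return an object of class `cohort_table`: list with `subject_ids`,
#'   `features` (numeric matrix), `feature_meta` (data frame `name`,
#'   `modality`), `labels` (0/1 integer), `scenario`, `tiv`.
#' @export
assemble_features <- function(clinical, gmv = NULL, fc = NULL,
                              scenario = c("GMV+FC", "GMV", "FC")) {
  scenario <- match.arg(scenario)
  need_gmv <- scenario %in% c("GMV", "GMV+FC")
  need_fc <- scenario %in% c("FC", "GMV+FC")
  if (need_gmv && is.null(gmv)) stop("scenario ", scenario, " needs a gmv table")
  if (need_fc && is.null(fc)) stop("scenario ", scenario, " needs an fc table")

  ids <- clinical$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject ids in clinical table")
  check_subjects <- function(tab, what) {
    if (!setequal(tab$subject_id, ids)) {
      off <- c(setdiff(ids, tab$subject_id), setdiff(tab$subject_id, ids))
      stop("subject mismatch between clinical and ", what, " tables: ",
           paste(off, collapse = ", "))
    }
    tab[match(ids, tab$subject_id), , drop = FALSE]
  }

  grp <- assign_groups(clinical$moca)
  excluded <- !grp %in% c("PD-CD", "PD-ND")
  if (any(excluded)) {
    stop("excluded subjects present (borderline or dementia-range MoCA): ",
         paste(ids[excluded], collapse = ", "))
  }

  sex_num <- ifelse(clinical$sex %in% c("male", "m", "1", "M"), 1,
             ifelse(clinical$sex %in% c("female", "f", "0", "F"), 0, NA))
  clin_mat <- cbind(age = clinical$age, sex = sex_num,
                    hy_stage = clinical$hy_stage, updrs3 = clinical$updrs3,
                    ledd = clinical$ledd, duration = clinical$duration)

  blocks <- list()
  meta <- list()
  if (need_gmv) {
    gmv <- check_subjects(gmv, "gmv")
    reg <- setdiff(colnames(gmv), c("subject_id", "tiv"))
    blocks$gmv <- as.matrix(gmv[, reg, drop = FALSE])
    meta$gmv <- data.frame(name = reg, modality = "GMV",
                           stringsAsFactors = FALSE)
  }
  if (need_fc) {
    fc <- check_subjects(fc, "fc")
    pr <- setdiff(colnames(fc), "subject_id")
    blocks$fc <- as.matrix(fc[, pr, drop = FALSE])
    meta$fc <- data.frame(name = pr, modality = "FC",
                          stringsAsFactors = FALSE)
  }
  blocks$clinical <- clin_mat
  meta$clinical <- data.frame(name = colnames(clin_mat), modality = "clinical",
                              stringsAsFactors = FALSE)

  features <- do.call(cbind, unname(blocks))
  feature_meta <- do.call(rbind, unname(meta))
  rownames(feature_meta) <- NULL
  colnames(features) <- feature_meta$name
  if (anyDuplicated(feature_meta$name)) {
    stop("duplicate feature names across blocks: ",
         paste(unique(feature_meta$name[duplicated(feature_meta$name)]),
               collapse = ", "))
  }
  if (anyNA(features)) {
    bad <- colnames(features)[colSums(is.na(features)) > 0]
    stop("missing values in features: ", paste(bad, collapse = ", "))
  }
  rownames(features) <- ids

  structure(list(
    subject_ids = ids,
    features = features,
    feature_meta = feature_meta,
    labels = as.integer(grp == "PD-CD"),
    scenario = scenario,
    tiv = if (!is.null(gmv)) gmv$tiv else NULL,
    normalization = "none"
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table '%s': %d subjects (%d PD-CD / %d PD-ND) x %d features; normalization: %s>\n",
              x$scenario, length(x$subject_ids), sum(x$labels),
              sum(1 - x$labels), ncol(x$features), x$normalization))
  invisible(x)
}

#' Fit / apply a per-feature z-score transform
#'
#' `zscore_fit()` estimates per-column means and SDs on training rows;
#' `zscore_apply()` standardizes new rows with those statistics. Used by
#' the leakage-safe `per_training_fold` normalization mode, where test
#' subjects are scaled with training statistics only.
#'
#' @param x numeric matrix.
#' @return `zscore_fit()`: list with `center` and `scale`;
#'   `zscore_apply()`: transformed matrix.
#' @export
zscore_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (any(scale == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[scale == 0], collapse = ", "))
  }
  list(center = center, scale = scale)
}

#' @rdname zscore_fit
#' @param fit result of `zscore_fit()`.
#' @export
zscore_apply <- function(fit, x) {
  sweep(sweep(x, 2L, fit$center, "-"), 2L, fit$scale, "/")
}

#' Z-score normalize a cohort table
#'
#' In `"global"` mode (the default, matching the original analysis)
#' every feature is standardized to zero mean and unit SD over *all*
#' subjects before any cross-validation; this leaks test-set means and
#' variances into training and the mode is reported accordingly. In
#' `"per_training_fold"` mode the table is returned unscaled and tagged,
#' and the downstream evaluators ([evaluate_subset()],
#' [rank_features()]) standardize inside each training fold, applying
#' the training statistics to the test subjects.
#'
#' @param table a [assemble_features()] cohort table.
#' @param mode `"global"` or `"per_training_fold"`.
#' @param warn_leakage message the global-mode leakage caveat once
#'   (default TRUE).
#' @return the table with `normalization` set (features rescaled in
#'   global mode).
#' @export
zscore_normalize <- function(table, mode = c("global", "per_training_fold"),
                             warn_leakage = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  mode <- match.arg(mode)
  if (mode == "global") {
    if (warn_leakage) {
      message("global z-score normalization uses all subjects (including ",
              "future test folds); use mode = 'per_training_fold' for a ",
              "leakage-safe estimate")
    }
    fit <- zscore_fit(table$features)
    table$features <- zscore_apply(fit, table$features)
  }
  table$normalization <- mode
  table
}

#' Write a feature table to CSV (features plus a final `label` column)
#'
#' @param table a cohort table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- data.frame(subject_id = table$subject_ids, table$features,
                   label = table$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV file.
#' @param scenario scenario tag to record.
#' @return a `cohort_table` (feature modalities inferred from names:
#'   clinical names per [clinical_feature_names()], `~` marks FC pairs,
#'   everything else GMV).
#' @export
read_feature_table <- function(path, scenario = "GMV+FC") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "label") %in% colnames(df)))
  fn <- setdiff(colnames(df), c("subject_id", "label"))
  modality <- ifelse(fn %in% clinical_feature_names(), "clinical",
              ifelse(grepl("~", fn, fixed = TRUE), "FC", "GMV"))
  features <- as.matrix(df[, fn, drop = FALSE])
  rownames(features) <- df$subject_id
  structure(list(subject_ids = df$subject_id, features = features,
                 feature_meta = data.frame(name = fn, modality = modality,
                                           stringsAsFactors = FALSE),
                 labels = as.integer(df$label), scenario = scenario,
                 tiv = NULL, normalization = "none"),
            class = "cohort_table")
}
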