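# Shared fixtures, all generated in code.

# Reduced null-generator parameters for fast cohort-level tests.
small_null_params <- function(seed = 1L, ...) {
  generator_params(n_regions = 6L, n_networks = 4L, n_volumes = 80L,
                   gmv_effects = numeric(0), fc_effects = numeric(0),
                   seed = seed, ...)
}

# Clinical targets with identical group distributions (MoCA stays
# group-defining but is never a feature).
equalized_clinical_targets <- function() {
  tg <- default_clinical_targets()
  for (v in c("age", "updrs3", "duration", "ledd")) tg[[v]]$cd <- tg[[v]]$nd
  tg$sex$p_male["cd"] <- tg$sex$p_male["nd"]
  tg$hy_stage$p_cd <- tg$hy_stage$p_nd
  tg$education_gt12y$p["cd"] <- tg$education_gt12y$p["nd"]
  tg
}

# Minimal cohort_table built directly from a feature matrix.
toy_table <- function(features, labels, normalization = "none") {
  structure(list(
    subject_ids = sprintf("s%03d", seq_len(nrow(features))),
    features = features,
    feature_meta = data.frame(name = if (is.null(colnames(features)))
                                character(0) else colnames(features),
                              modality = character(ncol(features)),
                              stringsAsFactors = FALSE),
    labels = as.integer(labels), scenario = "FC", tiv = NULL,
    normalization = normalization
  ), class = "cohort_table")
}

# One strongly separating feature plus noise features.
separable_table <- function(n = 30L, n_noise = 9L, sep_sd = 0.2, seed = 1L) {
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    sep <- 3 * labels + rnorm(n, sd = sep_sd)
    noise <- matrix(rnorm(n * n_noise), n, n_noise)
    features <- cbind(sep = sep, noise)
    colnames(features) <- c("sep", sprintf("noise_%02d", seq_len(n_noise)))
    toy_table(features, labels)
  })
}

planted_params <- function(seed) {
  generator_params(
    gmv_effects = c(region_001 = 0.8, region_002 = -0.8),
    fc_effects = c("DMN-2~VIS-2" = 0.3, "DMN-3~VIS-2" = 0.3),
    seed = seed)
}

planted_feature_names <- function() {
  c("region_001", "region_002", "DMN-2~VIS-2", "DMN-3~VIS-2")
}

# Combined-scenario table of a generated cohort, globally normalized.
cohort_to_table <- function(cohort, scenario = "GMV+FC",
                            normalization = "global") {
  fc <- compute_fc_table(cohort$timeseries)
  tab <- assemble_features(cohort$clinical, cohort$gmv, fc, scenario)
  zscore_normalize(tab, normalization, warn_leakage = FALSE)
}
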