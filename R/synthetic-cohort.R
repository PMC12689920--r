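# Synthetic cohort generation: clinical table, gray-matter volumes and
# parcellated network time series with configurable planted group effects.
#
# The generator emulates the data structure of a 38-patient Parkinson's
# disease cohort split by MoCA score into a cognitively impaired (PD-CD)
# and an unimpaired (PD-ND) group: Table-1-style clinical distributions,
# a 130-region gray-matter-volume table with planted standardized group
# differences, and 17-network resting-state time series whose group
# correlation matrices differ by configurable amounts in chosen network
# pairs.

#' Clinical sampling targets per group
#'
#' Per-variable group means/SDs (with truncation ranges) and category
#' probabilities used by [generate_cohort()]. Defaults reproduce the
#' study cohort's demographics: e.g. age 68.75 (6.56) years in PD-CD vs
#' 65.39 (6.17) in PD-ND, MoCA drawn within 16-21 (impaired) and 24-30
#' (unimpaired) so that [assign_groups()] reproduces the intended group.
#'
#' @return a named list, one element per clinical variable.
#' @export
default_clinical_targets <- function() {
  list(
    age = list(cd = c(mean = 68.75, sd = 6.56), nd = c(mean = 65.39, sd = 6.17),
               range = c(57, 79)),
    sex = list(p_male = c(cd = 9 / 20, nd = 9 / 18)),
    updrs3 = list(cd = c(mean = 18.90, sd = 7.33), nd = c(mean = 20.11, sd = 8.48),
                  range = c(7, 40), integer = TRUE),
    hy_stage = list(levels = c(1, 1.5, 2, 2.5, 3, 4),
                    p_cd = c(1, 2, 4, 2, 7, 4) / 20,
                    p_nd = c(2, 2, 4, 3, 7, 0) / 18),
    duration = list(cd = c(mean = 5.70, sd = 6.58), nd = c(mean = 5.11, sd = 4.14),
                    range = c(1, 19)),
    ledd = list(cd = c(mean = 640.05, sd = 542.97), nd = c(mean = 605.34, sd = 345.94),
                range = c(52, 2282)),
    moca = list(cd = c(mean = 19.30, sd = 1.69), nd = c(mean = 25.83, sd = 1.62),
                range_cd = c(16, 21), range_nd = c(24, 30), integer = TRUE),
    education_gt12y = list(p = c(cd = 18 / 20, nd = 17 / 18))
  )
}

#' Standardized group difference implied by an ANCOVA F statistic
#'
#' For a 1-df group contrast, `F = d^2 * n1 * n2 / (n1 + n2)`, so
#' `d = sqrt(F * (n1 + n2) / (n1 * n2))`.
#' @noRd
es_from_F <- function(F, n_cd, n_nd) sqrt(F * (n_cd + n_nd) / (n_cd * n_nd))

#' Convert a target group F statistic to a correlation difference
#'
#' A planted inter-network correlation difference is observed through each
#' subject's *sample* correlation, whose Fisher-z sampling SD under a
#' band-limited series is approximately `1 / sqrt(Neff - 3)` with
#' `Neff = 2 * (high - low) * duration` effective observations. The
#' correlation difference that yields a given group F at the study's
#' sample sizes is therefore `d * sd_z` (the z and r scales coincide to
#' first order at small baseline correlation).
#'
#' @param F target 1-df group F statistic (sign gives the direction,
#'   positive = higher in the impaired group).
#' @param n_cd,n_nd group sizes.
#' @param n_volumes,n_discard,tr_seconds,low_hz,high_hz acquisition and
#'   band parameters determining the effective sample size.
#' @return signed correlation difference.
#' @export
calibrate_fc_effect <- function(F, n_cd = 20L, n_nd = 18L, n_volumes = 203L,
                                n_discard = 3L, tr_seconds = 1.78,
                                low_hz = 0.01, high_hz = 0.1) {
  neff <- 2 * (high_hz - low_hz) * (n_volumes - n_discard) * tr_seconds
  sd_z <- 1 / sqrt(max(neff - 3, 1))
  sign(F) * es_from_F(abs(F), n_cd, n_nd) * sd_z
}

#' Default planted effects reproducing the reported group differences
#'
#' The default functional-connectivity effects are the five network pairs
#' with reported uncorrected group differences (FP-1~FP-2 F = 5.942,
#' FP-3~FP-4 F = 5.505, DMN-2~VIS-2 F = 4.789, DMN-3~VIS-2 F = 4.166, all
#' higher in PD-CD; FP-2~VIS-1 F = 4.140, lower in PD-CD), converted to
#' correlation differences via [calibrate_fc_effect()]. The default
#' gray-matter effects are two regions at the reported F statistics
#' (F = 4.345 higher in PD-CD, F = 4.215 lower), expressed in SD units of
#' the control (PD-ND) distribution; region labels are synthetic.
#'
#' @param n_cd,n_nd group sizes used in the calibration.
#' @param n_volumes,tr_seconds acquisition constants for the FC
#'   calibration.
#' @return named numeric vector of planted effects.
#' @export
default_fc_effects <- function(n_cd = 20L, n_nd = 18L, n_volumes = 203L,
                               tr_seconds = 1.78) {
  Fs <- c("FP-1~FP-2" = 5.942, "FP-3~FP-4" = 5.505, "DMN-2~VIS-2" = 4.789,
          "DMN-3~VIS-2" = 4.166, "FP-2~VIS-1" = -4.140)
  vapply(Fs, calibrate_fc_effect, numeric(1L), n_cd = n_cd, n_nd = n_nd,
         n_volumes = n_volumes, tr_seconds = tr_seconds)
}

#' @rdname default_fc_effects
#' @export
default_gmv_effects <- function(n_cd = 20L, n_nd = 18L) {
  c(region_001 = es_from_F(4.345, n_cd, n_nd),
    region_002 = -es_from_F(4.215, n_cd, n_nd))
}

#' Baseline inter-network correlation matrix
#'
#' Networks within the same superordinate family (shared label prefix,
#' e.g. `DMN-1`/`DMN-2`) correlate at `within`, networks of different
#' families at `between`; unit diagonal. The default values give a
#' positive-definite, realistically block-structured resting-state
#' correlation matrix.
#'
#' @param network_labels network names; families are label prefixes
#'   before `"-"`.
#' @param within,between baseline correlations (defaults 0.3 and 0.05).
#' @return symmetric correlation matrix.
#' @export
default_fc_base <- function(network_labels = yeo17_labels(),
                            within = 0.3, between = 0.05) {
  fam <- sub("-.*$", "", network_labels)
  R <- ifelse(outer(fam, fam, "=="), within, between)
  diag(R) <- 1
  dimnames(R) <- list(network_labels, network_labels)
  R
}

#' Parameters of the synthetic cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults are
#' the study conditions: 20 impaired + 18 unimpaired subjects, 130
#' gray-matter regions, the 17-network parcellation, 203 volumes at
#' TR = 1.78 s, and planted effects calibrated to the reported group
#' statistics ([default_fc_effects()], [default_gmv_effects()]).
#'
#' @param n_cd,n_nd numbers of impaired (PD-CD) and unimpaired (PD-ND)
#'   subjects.
#' @param clinical_targets see [default_clinical_targets()].
#' @param n_regions number of gray-matter regions.
#' @param region_names region labels (default `region_001`, ...).
#' @param gmv_effects named numeric: region name -> standardized group
#'   mean difference in SD units of the control distribution (positive =
#'   larger in PD-CD). Use `numeric(0)` for a null cohort.
#' @param n_networks,network_labels network count and labels (default the
#'   17-network parcellation).
#' @param fc_base baseline correlation matrix for the PD-ND group.
#' @param fc_effects named numeric: `"A~B"` -> correlation difference
#'   added for the PD-CD group. Use `numeric(0)` for a null cohort.
#' @param n_volumes time points per series (before any discard).
#' @param tr_seconds sampling interval in seconds.
#' @param noise_sd multiplier on the gray-matter residual SD.
#' @param seed master RNG seed; identical parameters and seed give a
#'   bit-identical cohort.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_cd = 20L, n_nd = 18L,
                             clinical_targets = default_clinical_targets(),
                             n_regions = 130L,
                             region_names = sprintf("region_%03d", seq_len(n_regions)),
                             gmv_effects = default_gmv_effects(n_cd, n_nd),
                             n_networks = 17L,
                             network_labels = if (n_networks == 17L) yeo17_labels()
                                              else sprintf("NET-%02d", seq_len(n_networks)),
                             fc_base = default_fc_base(network_labels),
                             fc_effects = default_fc_effects(n_cd, n_nd, n_volumes, tr_seconds),
                             n_volumes = 203L, tr_seconds = 1.78,
                             noise_sd = 1, seed = 1L) {
  if (!is_count(n_cd) || !is_count(n_nd)) stop("n_cd and n_nd must be non-negative integers")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be positive")
  if (!is_count(n_volumes, min = 10L)) stop("n_volumes must be an integer >= 10")
  if (!is_count(n_regions, min = 1L)) stop("n_regions must be a positive integer")
  if (length(region_names) != n_regions || anyDuplicated(region_names)) {
    stop("region_names must be ", n_regions, " unique names")
  }
  n_networks <- as.integer(n_networks)
  if (length(network_labels) != n_networks || anyDuplicated(network_labels)) {
    stop("network_labels must be ", n_networks, " unique names")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  stopifnot(is.matrix(fc_base),
            nrow(fc_base) == n_networks, ncol(fc_base) == n_networks)
  if (max(abs(fc_base - t(fc_base))) > 1e-12 || any(abs(diag(fc_base) - 1) > 1e-12)) {
    stop("fc_base must be symmetric with unit diagonal")
  }
  dimnames(fc_base) <- list(network_labels, network_labels)

  if (length(gmv_effects) && (is.null(names(gmv_effects)) ||
                              !all(names(gmv_effects) %in% region_names))) {
    stop("gmv_effects must be named by regions present in region_names")
  }
  fc_pairs <- parse_fc_pairs(names(fc_effects), network_labels)

  params <- structure(list(
    n_cd = as.integer(n_cd), n_nd = as.integer(n_nd),
    clinical_targets = clinical_targets,
    n_regions = as.integer(n_regions), region_names = region_names,
    gmv_effects = gmv_effects,
    n_networks = n_networks, network_labels = network_labels,
    fc_base = fc_base, fc_effects = fc_effects,
    n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "generator_params")

  # Build both group targets now so infeasible parameterizations fail early.
  params$fc_target_nd <- fc_base
  params$fc_target_cd <- apply_fc_effects(fc_base, fc_pairs, fc_effects)
  check_positive_definite(params$fc_target_nd, "fc_base")
  check_positive_definite(params$fc_target_cd,
                          paste0("fc_base with fc_effects {",
                                 paste(names(fc_effects), collapse = ", "), "}"))
  params
}

#' @noRd
parse_fc_pairs <- function(pair_names, network_labels) {
  if (length(pair_names) == 0L) return(matrix(integer(0), 2L, 0L))
  parts <- strsplit(pair_names, "~", fixed = TRUE)
  bad <- vapply(parts, function(p) {
    length(p) != 2L || p[1L] == p[2L] || !all(p %in% network_labels)
  }, logical(1L))
  if (any(bad)) {
    stop("invalid fc_effects pair(s): ",
         paste(pair_names[bad], collapse = ", "),
         " (need two distinct known networks joined by '~')")
  }
  vapply(parts, function(p) match(p, network_labels), integer(2L))
}

#' @noRd
apply_fc_effects <- function(base, pairs, deltas) {
  R <- base
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    v <- R[i, j] + deltas[[k]]
    if (abs(v) >= 1) {
      stop("fc effect for pair ", names(deltas)[k],
           " implies a correlation of ", signif(v, 4), ", outside (-1, 1)")
    }
    R[i, j] <- R[j, i] <- v
  }
  R
}

#' @noRd
check_positive_definite <- function(R, what) {
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) stop("correlation target is not positive definite: ", what)
  invisible(TRUE)
}

#' Generate a band-limited multivariate time series with a target
#' correlation matrix
#'
#' White Gaussian noise is band-limited column-wise with the same
#' zero-phase 0.01-0.1 Hz Butterworth filter used downstream (so the
#' signal survives the connectivity pipeline's own filtering), columns
#' are standardized, and the target correlation is imposed through the
#' Cholesky factor. The expected sample correlation matrix converges to
#' `corr_target` as `n_volumes` grows.
#'
#' @param corr_target symmetric positive-definite correlation matrix
#'   (unit diagonal).
#' @param n_volumes number of time points.
#' @param tr_seconds sampling interval in seconds.
#' @param seed optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param network_labels optional column labels (defaults to the
#'   dimnames of `corr_target`).
#' @param low_hz,high_hz pass band used to band-limit the draw.
#' @return a [network_timeseries()].
#' @export
generate_network_timeseries <- function(corr_target, n_volumes, tr_seconds,
                                        seed = NULL, network_labels = NULL,
                                        low_hz = 0.01, high_hz = 0.1) {
  corr_target <- as.matrix(corr_target)
  P <- ncol(corr_target)
  stopifnot(nrow(corr_target) == P, P >= 1L)
  if (max(abs(corr_target - t(corr_target))) > 1e-12 ||
      any(abs(diag(corr_target) - 1) > 1e-12)) {
    stop("corr_target must be symmetric with unit diagonal")
  }
  U <- tryCatch(chol(corr_target),
                error = function(e) stop("corr_target is not positive definite",
                                         call. = FALSE))
  if (is.null(network_labels)) network_labels <- colnames(corr_target)
  if (is.null(network_labels)) network_labels <- sprintf("NET-%02d", seq_len(P))

  draw <- function() {
    w <- matrix(stats::rnorm(n_volumes * P), n_volumes, P)
    f <- filter_columns(w, tr_seconds, low_hz, high_hz)
    f <- scale(f)  # exact zero mean, unit variance per column
    f %*% U
  }
  values <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  network_timeseries(values, tr_seconds, network_labels)
}

#' @noRd
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' @noRd
sample_clinical <- function(params) {
  tg <- params$clinical_targets
  n <- params$n_cd + params$n_nd
  grp <- rep(c("cd", "nd"), c(params$n_cd, params$n_nd))

  num_var <- function(spec, integer = isTRUE(spec$integer), digits = 1L) {
    out <- numeric(n)
    for (g in c("cd", "nd")) {
      m <- grp == g
      out[m] <- rtrunc_norm(sum(m), spec[[g]]["mean"], spec[[g]]["sd"],
                            spec$range[1L], spec$range[2L])
    }
    if (integer) pmin(pmax(round(out), spec$range[1L]), spec$range[2L])
    else round(out, digits)
  }

  moca <- integer(n)
  for (g in c("cd", "nd")) {
    m <- grp == g
    rg <- tg$moca[[paste0("range_", g)]]
    v <- rtrunc_norm(sum(m), tg$moca[[g]]["mean"], tg$moca[[g]]["sd"],
                     rg[1L], rg[2L])
    moca[m] <- pmin(pmax(round(v), rg[1L]), rg[2L])
  }

  sex <- character(n)
  edu <- character(n)
  hy <- numeric(n)
  for (g in c("cd", "nd")) {
    m <- grp == g
    sex[m] <- ifelse(stats::runif(sum(m)) < tg$sex$p_male[[g]], "male", "female")
    edu[m] <- ifelse(stats::runif(sum(m)) < tg$education_gt12y$p[[g]],
                     ">12y", "<=12y")
    hy[m] <- sample(tg$hy_stage$levels, sum(m), replace = TRUE,
                    prob = tg$hy_stage[[paste0("p_", g)]])
  }

  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = num_var(tg$age),
    sex = sex,
    hy_stage = hy,
    updrs3 = num_var(tg$updrs3),
    ledd = num_var(tg$ledd),
    duration = num_var(tg$duration),
    moca = moca,
    education = edu,
    stringsAsFactors = FALSE
  )
}

#' @noRd
sample_gmv <- function(params, sex) {
  n <- params$n_cd + params$n_nd
  is_cd <- seq_len(n) <= params$n_cd
  mu <- seq(2, 14, length.out = params$n_regions)      # region baselines, ml
  sdv <- 0.12 * mu * params$noise_sd
  shift <- numeric(params$n_regions)
  shift[match(names(params$gmv_effects), params$region_names)] <-
    params$gmv_effects
  vals <- vapply(seq_len(params$n_regions), function(j) {
    stats::rnorm(n, mu[j] + is_cd * shift[j] * sdv[j], sdv[j])
  }, numeric(n))
  colnames(vals) <- params$region_names
  tiv <- stats::rnorm(n, 1400 + 150 * (sex == "male"), 110)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(n)), tiv = tiv, vals,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Draws the clinical table, the gray-matter-volume table (with total
#' intracranial volume) and one parcellated network time series per
#' subject. MoCA scores are drawn inside the group-defining ranges, so
#' [assign_groups()] recovers the intended groups; PD-CD subjects come
#' first in subject order. Identical parameters and seed reproduce the
#' cohort element for element.
#'
#' @param params a [generator_params()] object.
#' @return an object of class `pd_cohort`: list with elements `clinical`
#'   (data frame), `gmv` (data frame with `tiv` plus one column per
#'   region), `timeseries` (named list of [network_timeseries()]),
#'   `groups` (factor, `"PD-CD"`/`"PD-ND"`), and `params`.
#' @export
#' @examples
#' p <- generator_params(n_regions = 5, n_networks = 4, n_volumes = 60,
#'                       gmv_effects = numeric(0), fc_effects = numeric(0),
#'                       seed = 7)
#' cohort <- generate_cohort(p)
#' table(cohort$groups)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_cd + params$n_nd
  seeds <- derive_seeds(params$seed, 3L)
  clinical <- with_local_seed(seeds[1L], sample_clinical(params))
  gmv <- with_local_seed(seeds[2L], sample_gmv(params, clinical$sex))
  groups <- factor(rep(c("PD-CD", "PD-ND"), c(params$n_cd, params$n_nd)),
                   levels = c("PD-CD", "PD-ND"))
  ts_seeds <- derive_seeds(seeds[3L], n)
  timeseries <- lapply(seq_len(n), function(i) {
    target <- if (groups[i] == "PD-CD") params$fc_target_cd else params$fc_target_nd
    generate_network_timeseries(target, params$n_volumes, params$tr_seconds,
                                seed = ts_seeds[i],
                                network_labels = params$network_labels)
  })
  names(timeseries) <- clinical$subject_id
  structure(list(clinical = clinical, gmv = gmv, timeseries = timeseries,
                 groups = groups, params = params),
            class = "pd_cohort")
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf("<pd_cohort: %d PD-CD + %d PD-ND subjects, %d regions, %d networks, %d volumes>\n",
              x$params$n_cd, x$params$n_nd, x$params$n_regions,
              x$params$n_networks, x$params$n_volumes))
  invisible(x)
}

#' Write a cohort to disk / read it back
#'
#' Writes `clinical.csv` (columns `subject_id,age,sex,hy_stage,updrs3,
#' ledd,duration,moca`), `gmv.csv` (`subject_id`, `tiv`, one column per
#' region), one tab-separated time series per subject under `ts/`, and a
#' `manifest.json` recording the generator parameters and seed.
#'
#' @param cohort a `pd_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  clin <- cohort$clinical[, c("subject_id", "age", "sex", "hy_stage",
                              "updrs3", "ledd", "duration", "moca")]
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$gmv, file.path(dir, "gmv.csv"), row.names = FALSE,
                   quote = FALSE)
  for (id in names(cohort$timeseries)) {
    write_timeseries_tsv(cohort$timeseries[[id]],
                         file.path(dir, "ts", paste0(id, ".tsv")))
  }
  p <- cohort$params
  manifest <- list(
    generator = list(
      n_cd = p$n_cd, n_nd = p$n_nd, n_regions = p$n_regions,
      n_networks = p$n_networks, network_labels = p$network_labels,
      n_volumes = p$n_volumes, tr_seconds = p$tr_seconds,
      noise_sd = p$noise_sd, seed = p$seed,
      gmv_effects = as.list(p$gmv_effects),
      fc_effects = as.list(p$fc_effects)
    ),
    package_version = as.character(utils::packageVersion("pdcog"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_tables <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tr <- manifest$generator$tr_seconds
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  gmv <- utils::read.csv(file.path(dir, "gmv.csv"), check.names = FALSE,
                         stringsAsFactors = FALSE)
  ts_files <- file.path(dir, "ts", paste0(clinical$subject_id, ".tsv"))
  timeseries <- lapply(ts_files, read_timeseries_tsv, tr_seconds = tr)
  names(timeseries) <- clinical$subject_id
  list(clinical = clinical, gmv = gmv, timeseries = timeseries,
       manifest = manifest)
}
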