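# Synthetic cohort generator: determinism, label feasibility, moment
# recovery and planted-effect calibration.

test_that("default parameters give 20 impaired + 18 unimpaired subjects", {
  co <- generate_cohort(generator_params(seed = 2))
  expect_identical(length(co$timeseries), 38L)
  grp <- assign_groups(co$clinical$moca)
  expect_identical(as.vector(table(grp)[c("PD-CD", "PD-ND")]), c(20L, 18L))
  expect_identical(as.character(grp), as.character(co$groups))
  expect_identical(ncol(co$gmv), 2L + 130L)   # subject_id, tiv, 130 regions
  expect_identical(dim(co$timeseries[[1]]$values), c(203L, 17L))
})

test_that("identical parameters and seed reproduce the cohort exactly", {
  a <- generate_cohort(small_null_params(seed = 9))
  b <- generate_cohort(small_null_params(seed = 9))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$gmv, b$gmv)
  expect_identical(lapply(a$timeseries, `[[`, "values"),
                   lapply(b$timeseries, `[[`, "values"))
  c <- generate_cohort(small_null_params(seed = 10))
  expect_false(identical(a$gmv, c$gmv))
})

test_that("MoCA draws always map back to the intended group", {
  for (seed in 1:5) {
    co <- generate_cohort(small_null_params(seed = seed))
    cd <- co$groups == "PD-CD"
    expect_true(all(co$clinical$moca[cd] >= 16 & co$clinical$moca[cd] <= 21))
    expect_true(all(co$clinical$moca[!cd] >= 24 & co$clinical$moca[!cd] <= 30))
    expect_true(all(co$clinical$moca == round(co$clinical$moca)))
    expect_true(all(co$clinical$hy_stage %in% c(1, 1.5, 2, 2.5, 3, 4)))
    expect_true(all(co$clinical$ledd >= 0 & co$clinical$updrs3 >= 0 &
                      co$clinical$duration >= 0))
  }
})

test_that("generated series recover the target correlation matrix", {
  R <- default_fc_base()
  ts <- generate_network_timeseries(R, 30000, 1.78, seed = 5)
  expect_lt(max(abs(cor(ts$values) - R)), 0.05)

  # two networks at r = 0.8, moderate length
  R2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  ts2 <- generate_network_timeseries(R2, 5000, 1.78, seed = 7)
  expect_true(cor(ts2$values)[1, 2] > 0.75 && cor(ts2$values)[1, 2] < 0.85)

  # independent networks stay near zero
  R4 <- diag(4); dimnames(R4) <- list(letters[1:4], letters[1:4])
  ts4 <- generate_network_timeseries(R4, 20000, 1.78, seed = 8)
  expect_lt(max(abs(cor(ts4$values)[upper.tri(R4)])), 0.05)

  # fixed seed reproduces the draw
  expect_identical(generate_network_timeseries(R2, 100, 1.78, seed = 3)$values,
                   generate_network_timeseries(R2, 100, 1.78, seed = 3)$values)
})

test_that("generated series concentrate their spectrum inside the band", {
  ts <- generate_network_timeseries(diag(2), 4000, 1.78, seed = 6)
  x <- ts$values[, 1]
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(spec) - 1) / (length(spec) * 1.78)
  half <- freqs > 0 & freqs <= 1 / (2 * 1.78)
  inband <- freqs >= 0.01 & freqs <= 0.1
  expect_gt(sum(spec[half & inband]) / sum(spec[half]), 0.95)
})

test_that("infeasible correlation targets fail with informative errors", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(generate_network_timeseries(bad, 100, 1.78), "positive definite")
  expect_error(generator_params(fc_effects = c("FP-1~FP-1" = 0.1)), "FP-1~FP-1")
  expect_error(generator_params(fc_effects = c("FP-1~NOPE" = 0.1)), "NOPE")
  expect_error(generator_params(fc_effects = c("FP-1~FP-2" = 0.8)), "outside")
  # a delta set that breaks positive definiteness names the parameterization
  expect_error(generator_params(fc_effects = c("FP-1~FP-2" = 0.69,
                                               "FP-1~FP-3" = -0.95,
                                               "FP-2~FP-3" = 0.6)),
               "positive definite")
})

test_that("with no planted effects all feature-wise group differences vanish at large n", {
  p <- generator_params(n_cd = 1500L, n_nd = 1500L,
                        clinical_targets = equalized_clinical_targets(),
                        n_regions = 6L, n_networks = 4L, n_volumes = 60L,
                        gmv_effects = numeric(0), fc_effects = numeric(0),
                        seed = 1)
  co <- generate_cohort(p)
  tab <- cohort_to_table(co, normalization = "global")
  g <- tab$labels == 1
  d <- apply(tab$features, 2, function(v) mean(v[g]) - mean(v[!g]))
  expect_lt(max(abs(d)), 0.1)   # features are unit-SD after normalization
})

test_that("a planted correlation difference is recovered at large n", {
  p <- generator_params(n_cd = 400L, n_nd = 400L, n_regions = 2L,
                        n_networks = 4L, n_volumes = 203L,
                        gmv_effects = numeric(0),
                        fc_effects = c("NET-01~NET-02" = 0.3), seed = 21)
  co <- generate_cohort(p)
  # oracle: raw sample Pearson correlation of each generated series
  r <- vapply(co$timeseries, function(ts) cor(ts$values)[1, 2], numeric(1))
  gap <- mean(r[co$groups == "PD-CD"]) - mean(r[co$groups == "PD-ND"])
  expect_lt(abs(gap - 0.3), 0.05)
  # and a large-n ANCOVA on the z-values rejects the null decisively
  fc <- compute_fc_table(co$timeseries)
  a <- ancova_feature(fc[["NET-01~NET-02"]], co$groups == "PD-CD",
                      cbind(age = co$clinical$age))
  expect_lt(a$p, 1e-10)
  expect_identical(a$direction, 1)
})

test_that("effect calibration maps F statistics to plausible deltas", {
  # round trip: planted delta implies the requested F in expectation
  d <- calibrate_fc_effect(5.0)
  expect_gt(d, 0); expect_lt(d, 0.2)
  expect_equal(calibrate_fc_effect(-5.0), -d)
  fx <- default_fc_effects()
  expect_identical(names(fx)[1], "FP-1~FP-2")
  expect_true(all(abs(fx) < 0.2) && fx[["FP-2~VIS-1"]] < 0)
  gx <- default_gmv_effects()
  expect_equal(unname(gx[1]), sqrt(4.345 * 38 / 360), tolerance = 1e-10)
})

test_that("cohort files round-trip through the on-disk layout", {
  co <- generate_cohort(small_null_params(seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("clinical.csv", "gmv.csv",
                                               "manifest.json")))))
  back <- read_cohort_tables(dir)
  expect_identical(back$clinical$subject_id, co$clinical$subject_id)
  expect_identical(names(back$clinical),
                   c("subject_id", "age", "sex", "hy_stage", "updrs3",
                     "ledd", "duration", "moca"))
  expect_equal(back$gmv$tiv, co$gmv$tiv, tolerance = 1e-10)
  expect_equal(back$timeseries[[3]]$values, co$timeseries[[3]]$values,
               tolerance = 1e-10)
  expect_identical(back$manifest$generator$seed, co$params$seed)
})
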