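# Connectivity feature construction: volume discard, band-pass filter,
# pairwise Pearson/Fisher-z features.

test_that("initial-volume discard removes exactly the leading volumes", {
  set.seed(1)
  ts <- network_timeseries(matrix(rnorm(203 * 3), 203, 3,
                                  dimnames = list(NULL, c("A", "B", "C"))),
                           tr_seconds = 1.78)
  out <- discard_initial_volumes(ts, 3L)
  expect_equal(nrow(out$values), 200L)
  expect_identical(out$values, ts$values[-(1:3), ])
  expect_identical(out$network_labels, ts$network_labels)
  expect_identical(out$tr_seconds, ts$tr_seconds)

  expect_identical(discard_initial_volumes(ts, 0L), ts)

  short <- network_timeseries(ts$values[1:5, ], 1.78)
  expect_error(discard_initial_volumes(short, 5L), "no data would remain")
})

test_that("band-pass filter passes in-band and rejects out-of-band content", {
  tr <- 1.78
  t <- seq(0, by = tr, length.out = 200)
  mk <- function(f) network_timeseries(
    cbind(sig = sin(2 * pi * f * t), other = sin(2 * pi * 0.04 * t)), tr)

  # constant input maps to (numerically) zero: DC is outside the band
  const <- network_timeseries(cbind(a = rep(5, 100), b = rep(-2, 100)), tr)
  expect_lt(max(abs(bandpass_filter(const)$values)), 1e-6)

  # 0.05 Hz sinusoid survives; oracle: variance ratio and Fourier peak
  inband <- bandpass_filter(mk(0.05))
  sig_in <- mk(0.05)$values[, "sig"]
  sig_out <- inband$values[, "sig"]
  expect_gte(var(sig_out) / var(sig_in), 0.9)
  spec <- Mod(stats::fft(sig_out))^2
  freqs <- (seq_along(spec) - 1) / (length(spec) * tr)
  half <- freqs <= 1 / (2 * tr)
  expect_lt(abs(freqs[half][which.max(spec[half])] - 0.05), 0.01)

  # 0.25 Hz sinusoid is in the stop band
  outband <- bandpass_filter(mk(0.25))
  expect_lte(var(outband$values[, "sig"]) / var(mk(0.25)$values[, "sig"]), 0.1)

  expect_error(bandpass_filter(mk(0.05), high_hz = 0.5), "Nyquist")
})

test_that("refiltering strictly in-band content preserves variance", {
  tr <- 1.78
  set.seed(7)
  white <- network_timeseries(matrix(rnorm(4000 * 2), 4000, 2,
                                     dimnames = list(NULL, c("a", "b"))), tr)
  interior <- bandpass_filter(white, low_hz = 0.02, high_hz = 0.08)
  again <- bandpass_filter(interior)  # 0.01-0.1 Hz
  ratio <- apply(again$values, 2, var) / apply(interior$values, 2, var)
  expect_true(all(abs(ratio - 1) < 0.05))

  t <- seq(0, by = tr, length.out = 400)
  tone <- network_timeseries(cbind(s = sin(2 * pi * 0.05 * t), n = rnorm(400)), tr)
  once <- bandpass_filter(tone)
  twice <- bandpass_filter(once)
  expect_lt(abs(var(twice$values[, "s"]) / var(once$values[, "s"]) - 1), 0.05)
})

test_that("pairwise connectivity matches hand-computed values on a toy series", {
  toy <- network_timeseries(
    cbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8), C = c(1, -1, 1, -1)),
    tr_seconds = 1)
  fc <- pairwise_connectivity(toy)
  expect_identical(fc$pair, c("A~B", "A~C", "B~C"))
  # hand-computed: r(A,B) = 1 (collinear); r(A,C) = -1/sqrt(5)
  expect_equal(fc$r[fc$pair == "A~B"], 1, tolerance = 1e-12)
  expect_equal(fc$z[fc$pair == "A~B"], atanh(1 - 1e-7), tolerance = 1e-9)
  expect_equal(fc$r[fc$pair == "A~C"], -0.4472136, tolerance = 1e-6)
  expect_equal(fc$z[fc$pair == "A~C"], -0.4812118, tolerance = 1e-6)
})

test_that("pair count follows P(P-1)/2 and 17 networks give 136 features", {
  set.seed(2)
  for (P in c(2:8, 12, 17, 20)) {
    ts <- network_timeseries(matrix(rnorm(40 * P), 40, P), 2,
                             network_labels = sprintf("N%02d", seq_len(P)))
    fc <- pairwise_connectivity(ts)
    expect_identical(nrow(fc), as.integer(P * (P - 1) / 2))
    expect_false(anyDuplicated(fc$pair) > 0)
    expect_false(any(fc$label_a == fc$label_b))
  }
  ts17 <- network_timeseries(matrix(rnorm(50 * 17), 50, 17), 1.78)
  expect_identical(nrow(pairwise_connectivity(ts17)), 136L)
})

test_that("connectivity is invariant to a common permutation of time points", {
  set.seed(3)
  v <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, letters[1:4]))
  perm <- sample(60)
  fc1 <- pairwise_connectivity(network_timeseries(v, 2))
  fc2 <- pairwise_connectivity(network_timeseries(v[perm, ], 2))
  expect_equal(fc1$r, fc2$r, tolerance = 1e-12)
})

test_that("zero-variance network is reported by name", {
  v <- cbind(ok = rnorm(30), flat = rep(1, 30))
  expect_error(pairwise_connectivity(network_timeseries(v, 2)), "flat")
})

test_that("fisher z transform is the clipped arctanh and is odd", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(1), 8.406, tolerance = 1e-3)   # arctanh(1 - 1e-7)
  expect_equal(fisher_z(-1), -fisher_z(1))
  r <- seq(-1, 1, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1.2), "within")
  expect_error(fisher_z(NA_real_), "finite")
})

test_that("the per-subject FC table has one z column per pair", {
  co <- generate_cohort(small_null_params(seed = 11))
  fc <- compute_fc_table(co$timeseries)
  expect_identical(nrow(fc), 38L)
  expect_identical(ncol(fc), as.integer(1 + 4 * 3 / 2))
  expect_true(all(vapply(fc[-1], is.numeric, logical(1))))
  # values are Fisher z of the filtered series, recomputed for one subject
  ts <- bandpass_filter(discard_initial_volumes(co$timeseries[[5]], 3L))
  expect_equal(unlist(fc[5, -1]), setNames(pairwise_connectivity(ts)$z, names(fc)[-1]),
               tolerance = 1e-12)
})

test_that("time-series TSV round-trips", {
  co <- generate_cohort(small_null_params(seed = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries_tsv(co$timeseries[[1]], path)
  back <- read_timeseries_tsv(path, co$params$tr_seconds)
  expect_equal(back$values, co$timeseries[[1]]$values, tolerance = 1e-10)
  expect_identical(back$network_labels, co$params$network_labels)
})
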