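# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Deterministic child seeds from a master seed
#'
#' All seeds stay below 2^31 so they are valid R integer seeds.
#' @noRd
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0L)
  if (n == 0L) return(integer(0))
  with_local_seed((as.integer(seed) + as.integer(salt)) %% .Machine$integer.max,
                  sample.int(.Machine$integer.max - 1L, n))
}

#' Rank-based ROC-AUC (Mann-Whitney with midranks for ties)
#' @noRd
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- length(positive) - n1
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment using the current RNG stream
#'
#' Returns an integer vector of fold ids (1..k). Class indices are
#' shuffled and dealt round-robin so fold class counts differ by at
#' most one.
#' @noRd
stratified_fold_ids <- function(y, k) {
  stopifnot(k >= 2L)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Order-4 Butterworth band-pass coefficients for a sampling interval
#' @noRd
butter_bandpass <- function(tr_seconds, low_hz, high_hz, order = 4L) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  }
  if (high_hz > nyquist) {
    stop(sprintf("high_hz = %g Hz exceeds the Nyquist frequency %g Hz for TR = %g s",
                 high_hz, nyquist, tr_seconds), call. = FALSE)
  }
  signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
}

#' Zero-phase band-pass filter of the columns of a numeric matrix
#'
#' Columns are demeaned first so a constant input maps exactly to zero.
#' @noRd
filter_columns <- function(values, tr_seconds, low_hz, high_hz) {
  flt <- butter_bandpass(tr_seconds, low_hz, high_hz)
  out <- apply(values, 2L, function(col) {
    signal::filtfilt(flt, col - mean(col))
  })
  dimnames(out) <- dimnames(values)
  out
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
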