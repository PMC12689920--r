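# Functional-connectivity feature construction from parcellated
# network time series: volume discard, band-pass filtering, pairwise
# Pearson correlation and Fisher r-to-z transformation.

#' Network labels of the 17-network cortical parcellation
#'
#' Ordered labels of the 17 large-scale networks used as the default
#' parcellation: frontoparietal (FP-1..FP-4), default mode (DMN-1..DMN-3),
#' motor (MOT-1..MOT-3), visual (VIS-1, VIS-2), limbic (LIM-1, LIM-2),
#' dorsal attention (DAN-1, DAN-2) and ventral attention (VAN-1). The
#' order is fixed: it defines the feature-pair ordering of
#' [pairwise_connectivity()].
#'
#' @return character vector of length 17.
#' @export
#' @examples
#' yeo17_labels()
yeo17_labels <- function() {
  c("FP-1", "FP-2", "FP-3", "FP-4",
    "DMN-1", "DMN-2", "DMN-3",
    "MOT-1", "MOT-2", "MOT-3",
    "VIS-1", "VIS-2",
    "LIM-1", "LIM-2",
    "DAN-1", "DAN-2",
    "VAN-1")
}

#' Construct a parcellated network time-series object
#'
#' @param values numeric matrix, time points in rows and networks in
#'   columns.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param network_labels unique network names, one per column. Defaults to
#'   the column names of `values`, or to [yeo17_labels()] when `values`
#'   has 17 unnamed columns.
#' @return an object of class `network_timeseries`.
#' @export
network_timeseries <- function(values, tr_seconds, network_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a time series needs at least 2 volumes")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  if (is.null(network_labels)) {
    network_labels <- colnames(values)
    if (is.null(network_labels) && ncol(values) == 17L) {
      network_labels <- yeo17_labels()
    }
  }
  if (is.null(network_labels) || length(network_labels) != ncol(values)) {
    stop("network_labels must name every column")
  }
  if (anyDuplicated(network_labels)) stop("network labels must be unique")
  colnames(values) <- network_labels
  structure(list(values = values, tr_seconds = tr_seconds,
                 network_labels = network_labels),
            class = "network_timeseries")
}

#' @export
print.network_timeseries <- function(x, ...) {
  cat(sprintf("<network_timeseries: %d volumes x %d networks, TR = %g s>\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Discard initial volumes of a time series
#'
#' Removes the first `n_discard` volumes, the standard guard against
#' scanner equilibration effects at the start of an fMRI acquisition.
#'
#' @param ts a [network_timeseries()].
#' @param n_discard number of leading volumes to drop (default 3).
#' @return a `network_timeseries` with `n_discard` fewer volumes.
#' @export
#' @examples
#' ts <- network_timeseries(matrix(rnorm(203 * 2), 203, 2,
#'                                 dimnames = list(NULL, c("A", "B"))), 1.78)
#' nrow(discard_initial_volumes(ts, 3)$values)  # 200
discard_initial_volumes <- function(ts, n_discard = 3L) {
  stopifnot(inherits(ts, "network_timeseries"))
  if (!is_count(n_discard)) stop("n_discard must be a non-negative integer")
  if (n_discard >= nrow(ts$values)) {
    stop(sprintf("cannot discard %d of %d volumes: no data would remain",
                 n_discard, nrow(ts$values)))
  }
  if (n_discard == 0L) return(ts)
  network_timeseries(ts$values[-seq_len(n_discard), , drop = FALSE],
                     ts$tr_seconds, ts$network_labels)
}

#' Zero-phase band-pass filter a network time series
#'
#' Applies an order-4 Butterworth band-pass forwards and backwards
#' (`signal::filtfilt`), so the filter is zero-phase and does not shift
#' signal relative between networks. Columns are demeaned first; the DC
#' component is outside the pass-band by construction.
#'
#' @param ts a [network_timeseries()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1,
#'   the conventional resting-state band). `high_hz` must not exceed the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return a filtered `network_timeseries` of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "network_timeseries"))
  filtered <- filter_columns(ts$values, ts$tr_seconds, low_hz, high_hz)
  network_timeseries(filtered, ts$tr_seconds, ts$network_labels)
}

#' Fisher r-to-z transformation
#'
#' `z = artanh(r)` with `r` clipped to `[-1 + eps, 1 - eps]` so that
#' perfect correlations map to a large finite value instead of infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @param eps clipping constant (default `1e-7`; `fisher_z(1)` is about
#'   8.406).
#' @return numeric vector of z-values.
#' @export
#' @examples
#' fisher_z(c(0, 0.5, 1))
fisher_z <- function(r, eps = 1e-7) {
  if (!is.numeric(r)) stop("r must be numeric")
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("correlations must be finite and within [-1, 1]")
  }
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Pairwise inter-network connectivity features
#'
#' Computes the Pearson correlation for every unordered network pair and
#' its Fisher z transform. Pairs are ordered row-major over the upper
#' triangle of the correlation matrix in atlas label order, so feature
#' names (`"A~B"`, first label earlier in atlas order) are stable across
#' runs. For `P` networks this yields `P * (P - 1) / 2` features — 136
#' for the 17-network parcellation.
#'
#' @param ts a [network_timeseries()] (normally already filtered).
#' @return a data frame of class `connectivity_features` with columns
#'   `pair`, `label_a`, `label_b`, `r`, `z`.
#' @export
pairwise_connectivity <- function(ts) {
  stopifnot(inherits(ts, "network_timeseries"))
  v <- ts$values
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance network signal: ",
         paste(ts$network_labels[sds == 0], collapse = ", "))
  }
  R <- stats::cor(v)
  P <- ncol(v)
  ij <- utils::combn(P, 2L)  # columns (1,2),(1,3),...: row-major upper triangle
  a <- ts$network_labels[ij[1L, ]]
  b <- ts$network_labels[ij[2L, ]]
  r <- R[cbind(ij[1L, ], ij[2L, ])]
  out <- data.frame(pair = paste0(a, "~", b), label_a = a, label_b = b,
                    r = r, z = fisher_z(r), stringsAsFactors = FALSE)
  class(out) <- c("connectivity_features", "data.frame")
  out
}

#' Read / write a parcellated time-series TSV
#'
#' Tab-separated file with a header row of network labels and one row per
#' volume, the on-disk format produced by [write_cohort()].
#'
#' @param path file path.
#' @param tr_seconds sampling interval of the stored series.
#' @return [read_timeseries_tsv()] returns a [network_timeseries()];
#'   [write_timeseries_tsv()] returns `path` invisibly.
#' @export
read_timeseries_tsv <- function(path, tr_seconds) {
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  network_timeseries(values, tr_seconds)
}

#' @rdname read_timeseries_tsv
#' @param ts a [network_timeseries()] to write.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "network_timeseries"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Compute the wide FC feature table for a set of subjects
#'
#' Runs the full connectivity stage per subject — discard initial
#' volumes, band-pass filter, pairwise correlation, Fisher z — and
#' assembles one row per subject with one column per network pair
#' (values are z).
#'
#' @param ts_list named list of [network_timeseries()] objects
#'   (names = subject ids), e.g. the `timeseries` element of a cohort from
#'   [generate_cohort()].
#' @param n_discard initial volumes to discard (default 3).
#' @param low_hz,high_hz pass-band in Hz (defaults 0.01, 0.1).
#' @return data frame: `subject_id`, then one `z` column per pair.
#' @export
compute_fc_table <- function(ts_list, n_discard = 3L,
                             low_hz = 0.01, high_hz = 0.1) {
  if (is.null(names(ts_list)) || anyDuplicated(names(ts_list))) {
    stop("ts_list must be a named list with unique subject ids")
  }
  rows <- lapply(ts_list, function(ts) {
    fc <- pairwise_connectivity(
      bandpass_filter(discard_initial_volumes(ts, n_discard), low_hz, high_hz))
    stats::setNames(fc$z, fc$pair)
  })
  pairs <- names(rows[[1L]])
  bad <- vapply(rows, function(r) !identical(names(r), pairs), logical(1L))
  if (any(bad)) {
    stop("inconsistent network labels for subjects: ",
         paste(names(rows)[bad], collapse = ", "))
  }
  out <- data.frame(subject_id = names(rows),
                    do.call(rbind, rows),
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
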