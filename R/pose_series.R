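#' Construct a pose time series
#'
#' A pose series holds a regularly sampled time series of eigenworm
#' coefficients `a1..aK`. Each row is one video frame; each column is the
#' coefficient of one eigenworm (principal component of body-segment tangent
#' angles). Missing samples — e.g. frames where pose extraction failed — are
#' represented by `NA` in any subset of the coefficients of that row; rows
#' are never deleted, so the time grid stays regular.
#'
#' @param coeffs numeric matrix, T samples x K coefficients (K >= 2). Column
#'   names are set to `a1..aK`.
#' @param dt sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param times optional explicit time vector; must be a regular grid with
#'   spacing `dt` (relative tolerance 1e-9). Overrides `t0`.
#' @param name identifier used in provenance and to decide whether a library
#'   and a query share a source (temporal exclusion in [smap_predict()]).
#'
#' @return An object of class `pose_series`: a list with elements `times`,
#'   `coeffs`, `dt`, `name`.
#' @examples
#' s <- pose_series(cbind(sin(1:100 / 5), cos(1:100 / 5)), dt = 0.05)
#' s
#' @export
pose_series <- function(coeffs, dt, t0 = 0, times = NULL, name = "series") {
  coeffs <- as.matrix(coeffs)
  storage.mode(coeffs) <- "double"
  if (ncol(coeffs) < 2L)
    stop("pose series needs K >= 2 coefficients (a1, a2 drive the classifier)")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  n <- nrow(coeffs)
  if (is.null(times)) {
    times <- t0 + (seq_len(n) - 1) * dt
  } else {
    if (length(times) != n) stop("'times' length must match nrow(coeffs)")
    d <- diff(times)
    if (any(d <= 0)) stop("'times' must be strictly increasing")
    if (any(abs(d - dt) > 1e-9 * max(dt, 1)))
      stop("'times' must be a regular grid with spacing dt (tolerance 1e-9)")
  }
  colnames(coeffs) <- paste0("a", seq_len(ncol(coeffs)))
  structure(list(times = as.numeric(times), coeffs = coeffs,
                 dt = dt, name = as.character(name)[1]),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  n_gap <- sum(!stats::complete.cases(x$coeffs))
  cat(sprintf("<pose_series '%s'>  %d samples x %d coefficients, dt = %g s (%g Hz)\n",
              x$name, nrow(x$coeffs), ncol(x$coeffs), x$dt, 1 / x$dt))
  cat(sprintf("  time range [%g, %g] s; %d sample(s) with missing coefficients\n",
              x$times[1], x$times[length(x$times)], n_gap))
  invisible(x)
}

#' @rdname pose_series
#' @param x object to test.
#' @export
is_pose_series <- function(x) inherits(x, "pose_series")

n_samples <- function(series) nrow(series$coeffs)

# rows where every coefficient is defined
defined_rows <- function(series) stats::complete.cases(series$coeffs)

#' Extract a sample interval of a pose series
#'
#' @param series a [pose_series()].
#' @param first,last 1-based sample indices (inclusive).
#' @return A `pose_series` covering the requested samples, preserving times.
#' @export
window_series <- function(series, first, last) {
  stopifnot(is_pose_series(series))
  n <- n_samples(series)
  if (first < 1L || last > n || first > last)
    stop(sprintf("interval [%d, %d] outside series samples [1, %d]", first, last, n))
  pose_series(series$coeffs[first:last, , drop = FALSE], dt = series$dt,
              times = series$times[first:last], name = series$name)
}
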