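#' Construct a delay embedding object
#'
#' Low-level constructor; most users should call [embed_continuous()] or
#' [embed_discontinuous()]. Each embedding point is the concatenation, in
#' lag-major order, of E successive K-coefficient poses:
#' `[pose(t), pose(t - tau), ..., pose(t - (E-1) tau)]`, giving `K * E`
#' coordinates per point. Its target is the pose `Tp_steps` samples ahead,
#' and its `time_index` is the 1-based sample index of the lag-0 pose.
#'
#' @param points N x (K*E) numeric matrix of lag vectors (no NA).
#' @param targets N x K numeric matrix of poses Tp_steps ahead (no NA).
#' @param time_index strictly increasing integer vector of lag-0 sample
#'   indices.
#' @param E number of lags.
#' @param tau_steps lag spacing in samples.
#' @param Tp_steps prediction horizon in samples.
#' @param source name of the originating series.
#' @param shortfall for discontinuous embeddings, how many requested points
#'   could not be produced before the series ended (0 otherwise).
#' @return An object of class `delay_embedding`.
#' @export
delay_embedding <- function(points, targets, time_index, E, tau_steps = 1L,
                            Tp_steps = 1L, source = "series", shortfall = 0L) {
  points <- as.matrix(points); targets <- as.matrix(targets)
  storage.mode(points) <- "double"; storage.mode(targets) <- "double"
  K <- ncol(targets)
  if (ncol(points) != K * E)
    stop(sprintf("points must have K*E = %d columns, got %d", K * E, ncol(points)))
  if (nrow(points) != nrow(targets) || nrow(points) != length(time_index))
    stop("points, targets and time_index must agree in length")
  if (anyNA(points) || anyNA(targets))
    stop("embedding points and targets must contain no undefined values")
  if (is.unsorted(time_index, strictly = TRUE))
    stop("time_index must be strictly increasing")
  structure(list(points = points, targets = targets,
                 time_index = as.integer(time_index), E = as.integer(E),
                 K = as.integer(K), tau_steps = as.integer(tau_steps),
                 Tp_steps = as.integer(Tp_steps), source = source,
                 shortfall = as.integer(shortfall)),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat(sprintf("<delay_embedding from '%s'>  %d points, E = %d, K = %d (%d dims), tau = %d, Tp = %d\n",
              x$source, nrow(x$points), x$E, x$K, x$K * x$E, x$tau_steps, x$Tp_steps))
  if (x$shortfall > 0L)
    cat(sprintf("  shortfall: %d requested point(s) unavailable\n", x$shortfall))
  invisible(x)
}

# assemble lag-major points for given lag-0 sample indices (all assumed valid)
build_points <- function(series, E, tau_steps, Tp_steps, tvec) {
  K <- ncol(series$coeffs)
  pts <- matrix(NA_real_, length(tvec), K * E)
  for (lag in 0:(E - 1))
    pts[, lag * K + seq_len(K)] <- series$coeffs[tvec - lag * tau_steps, , drop = FALSE]
  tg <- series$coeffs[tvec + Tp_steps, , drop = FALSE]
  list(points = pts, targets = tg)
}

#' Delay embedding of a fixed, gap-free interval
#'
#' Embeds every sample of the stated interval for which all E lag poses and
#' the target pose lie inside the interval; the first `(E-1) * tau_steps`
#' samples of the interval have undefined lag coordinates and produce no
#' point, and the last `Tp_steps` samples have no target. The number of
#' points is therefore
#' `interval length - (E-1) * tau_steps - Tp_steps`. Suitable for data with
#' no missing samples in the interval; use [embed_discontinuous()] otherwise.
#'
#' @param series a [pose_series()].
#' @param E number of lags (>= 1).
#' @param tau_steps lag spacing in samples (>= 1).
#' @param Tp_steps prediction horizon in samples (>= 1).
#' @param interval 1-based inclusive sample pair `c(first, last)`; defaults
#'   to the whole series.
#' @return A [delay_embedding()].
#' @examples
#' s <- generate_series(synthetic_config(duration_s = 5, noise_sd = 0))$series
#' embed_continuous(s, E = 5)
#' @export
embed_continuous <- function(series, E, tau_steps = 1L, Tp_steps = 1L,
                             interval = c(1L, n_samples(series))) {
  stopifnot(is_pose_series(series), E >= 1, tau_steps >= 1, Tp_steps >= 1)
  first <- as.integer(interval[1]); last <- as.integer(interval[2])
  n <- n_samples(series)
  if (first < 1L || last > n || first > last)
    stop(sprintf("interval [%d, %d] outside series samples [1, %d]", first, last, n))
  if (!all(defined_rows(series)[first:last]))
    stop("interval contains undefined samples; use embed_discontinuous()")
  span <- (E - 1L) * tau_steps + Tp_steps
  if (last - first + 1L < span + 1L)
    stop(sprintf("interval of %d samples too short for E = %d, tau = %d, Tp = %d (needs >= %d)",
                 last - first + 1L, E, tau_steps, Tp_steps, span + 1L))
  tvec <- (first + (E - 1L) * tau_steps):(last - Tp_steps)
  b <- build_points(series, E, tau_steps, Tp_steps, tvec)
  delay_embedding(b$points, b$targets, tvec, E, tau_steps, Tp_steps,
                  source = series$name)
}

#' Delay embedding tolerant of missing samples
#'
#' Scans forward from `start_sample`, accepting each sample whose E lag
#' poses and target pose are all defined, until `n_points` points have been
#' accepted or the series ends. Lag coordinates may reach samples before
#' `start_sample`. If the series ends before `n_points` are found, the
#' embedding carries the shortfall in its `shortfall` field (reported, not
#' an error).
#'
#' @inheritParams embed_continuous
#' @param start_sample 1-based sample index at which the scan begins.
#' @param n_points number of points requested (`Inf` for all available).
#' @return A [delay_embedding()].
#' @export
embed_discontinuous <- function(series, E, tau_steps = 1L, Tp_steps = 1L,
                                start_sample = 1L, n_points = Inf) {
  stopifnot(is_pose_series(series), E >= 1, tau_steps >= 1, Tp_steps >= 1,
            n_points >= 1)
  n <- n_samples(series)
  start_sample <- as.integer(start_sample)
  if (start_sample < 1L || start_sample > n)
    stop(sprintf("start_sample %d outside series samples [1, %d]", start_sample, n))
  ok <- defined_rows(series)
  lo <- max(start_sample, (E - 1L) * tau_steps + 1L)
  hi <- n - Tp_steps
  accepted <- integer(0)
  if (lo <= hi) {
    cand <- lo:hi
    good <- ok[cand + Tp_steps]
    for (lag in 0:(E - 1L)) good <- good & ok[cand - lag * tau_steps]
    accepted <- cand[good]
  }
  shortfall <- 0L
  if (is.finite(n_points)) {
    if (length(accepted) < n_points) shortfall <- as.integer(n_points - length(accepted))
    accepted <- utils::head(accepted, n_points)
  }
  if (length(accepted) == 0L)
    stop("no valid embedding points from the requested start sample")
  b <- build_points(series, E, tau_steps, Tp_steps, accepted)
  delay_embedding(b$points, b$targets, accepted, E, tau_steps, Tp_steps,
                  source = series$name, shortfall = shortfall)
}

#' Restrict a master embedding to fewer lags
#'
#' Keeps, for every point of the master embedding, only the lag blocks
#' `0..E_sub-1`, with targets and time indices unchanged. Scanning embedding
#' dimension through subsets of one master embedding keeps the point set
#' identical across E values, so error differences reflect the embedding
#' dimension alone rather than shifting sets of valid points.
#'
#' @param master a [delay_embedding()].
#' @param E_sub number of lags to keep (`1 <= E_sub <= master$E`).
#' @return A [delay_embedding()] with `E = E_sub`.
#' @export
subset_embedding <- function(master, E_sub) {
  stopifnot(inherits(master, "delay_embedding"))
  E_sub <- as.integer(E_sub)
  if (E_sub < 1L || E_sub > master$E)
    stop(sprintf("E_sub must lie in [1, %d]", master$E))
  if (E_sub == master$E) return(master)
  keep <- seq_len(master$K * E_sub)
  delay_embedding(master$points[, keep, drop = FALSE], master$targets,
                  master$time_index, E_sub, master$tau_steps, master$Tp_steps,
                  source = master$source, shortfall = master$shortfall)
}
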